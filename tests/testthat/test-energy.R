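# Scoring model: tether, binding-energy components, hydrogen bonds, the
# S2 distance metric.  Hand-evaluated oracles recompute the documented
# formulas independently of the implementation.

## minimal single-atom "pose" wrapper used for pair-level oracles
atom_pose <- function(atoms) {
  s <- new_structure("probe", "P", atoms)
  structure(list(peptide = peptide("G", "G"), structure = s,
                 receptor = NULL,
                 anchor_idx = integer(0),
                 anchor_reference = matrix(0, 0, 3),
                 torsions = list(), clash = FALSE),
            class = "PeptidePose")
}

## alanine CB: carbon with zero partial charge, no donor/acceptor role
neutral_c_atom <- function(x, y = 0, z = 0, resno = 1L)
  data.frame(resno = resno, resname = "ALA", atomname = "CB",
             element = "C", x = x, y = y, z = z)

test_that("tether_penalty is the harmonic sum over anchor displacements", {
  tc <- toy_complex()
  pose <- suppressWarnings(
    place_peptide(peptide("A", "A"), tc$receptor, tc$template, tc$map))
  expect_equal(tether_penalty(pose), 0)

  ## single anchored atom displaced 1 A at k = 10 -> 10
  p1 <- pose
  i <- p1$anchor_idx[1]
  p1$structure$atoms$x[i] <- p1$structure$atoms$x[i] + 1
  expect_equal(tether_penalty(p1, k = 10), 10, tolerance = 1e-10)

  ## displacements (0.5, 1, 2) A at k = 2 -> 2 * (0.25 + 1 + 4) = 10.5
  p2 <- pose
  ii <- p2$anchor_idx[1:3]
  p2$structure$atoms$x[ii[1]] <- p2$structure$atoms$x[ii[1]] + 0.5
  p2$structure$atoms$y[ii[2]] <- p2$structure$atoms$y[ii[2]] + 1.0
  p2$structure$atoms$z[ii[3]] <- p2$structure$atoms$z[ii[3]] + 2.0
  expect_equal(tether_penalty(p2, k = 2), 10.5, tolerance = 1e-10)
})

test_that("score_energy: separated reference is exactly zero", {
  tc <- toy_complex()
  model <- energy_model()
  pose <- suppressWarnings(
    place_peptide(peptide("A", "A"), tc$receptor, tc$template, tc$map))
  far <- pose
  far$structure$atoms[, c("x", "y", "z")] <-
    far$structure$atoms[, c("x", "y", "z")] + 500
  res <- score_energy(far, tc$receptor, model)
  expect_identical(res$E_bind, 0)
  expect_true(res$separated)
  expect_identical(unname(res$components), rep(0, 5))
})

test_that("score_energy: neutral pair at the LJ minimum scores -epsilon", {
  model <- energy_model()
  ## carbon pair at Rmin = 1.9 + 1.9
  pose <- atom_pose(neutral_c_atom(0))
  rec <- new_structure("rec", "A", neutral_c_atom(3.8))
  res <- score_energy(pose, rec, model)
  expect_equal(res$components[["lj"]], -0.08, tolerance = 1e-12)
  expect_equal(res$components[["coulomb"]], 0)
  expect_equal(res$components[["hbond"]], 0)
  expect_equal(res$E_bind, -0.08, tolerance = 1e-12)
})

test_that("score_energy matches a term-by-term hand evaluation", {
  model <- energy_model()
  ## 3-atom toy: peptide = one Gly CA (q 0.10); receptor = Gly CA + Gly O
  pose <- atom_pose(data.frame(resno = 1L, resname = "GLY",
                               atomname = "CA", element = "C",
                               x = 0, y = 0, z = 0))
  rec <- new_structure("rec", "A", data.frame(
    resno = 1L, resname = "GLY", atomname = c("CA", "O"),
    element = c("C", "O"), x = c(4.2, 2.0), y = c(0, 3.0), z = 0))
  got <- score_energy(pose, rec, model)

  hand_lj <- function(r, rm, eps) eps * ((rm / r)^12 - 2 * (rm / r)^6)
  q_ca <- 0.10; q_o <- -0.45
  r1 <- 4.2
  r2 <- sqrt(2^2 + 3^2)
  expected_lj <- hand_lj(r1, 3.8, 0.08) +
    hand_lj(r2, 1.9 + 1.7, sqrt(0.08 * 0.21))
  expected_coul <- 332.0637 * (q_ca * q_ca) / (4 * r1^2) +
    332.0637 * (q_ca * q_o) / (4 * r2^2)
  expect_equal(got$components[["lj"]], expected_lj, tolerance = 1e-10)
  expect_equal(got$components[["coulomb"]], expected_coul,
               tolerance = 1e-10)
  expect_equal(got$E_bind, expected_lj + expected_coul, tolerance = 1e-10)
})

test_that("sub-clash distances give a large finite energy with a flag", {
  model <- energy_model()
  pose <- atom_pose(neutral_c_atom(0))
  rec <- new_structure("rec", "A", neutral_c_atom(0.3))
  res <- score_energy(pose, rec, model)
  expect_true(res$clash)
  expect_true(is.finite(res$E_bind))
  expect_equal(res$components[["lj"]], model$clash_energy)
})

test_that("count_hbonds applies the distance and angle window", {
  model <- energy_model()
  ## donor backbone N (base CA) vs acceptor backbone O at 2.9 A, 160 deg
  mk_donor <- function() atom_pose(data.frame(
    resno = 1L, resname = "GLY", atomname = c("N", "CA"),
    element = c("N", "C"),
    x = c(0, -1.458), y = 0, z = 0))
  place_acceptor <- function(r, angle_deg) {
    th <- deg2rad <- angle_deg * pi / 180
    ## angle CA-N-O = angle_deg with CA along -x
    new_structure("rec", "A", data.frame(
      resno = 1L, resname = "GLY", atomname = c("C", "O"),
      element = c("C", "O"),
      x = c(50, r * cos(pi - th)), y = c(50, r * sin(pi - th)),
      z = 0))
  }
  expect_equal(count_hbonds(mk_donor(), place_acceptor(2.9, 160), model), 1L)
  expect_equal(count_hbonds(mk_donor(), place_acceptor(2.2, 160), model), 0L)
  expect_equal(count_hbonds(mk_donor(), place_acceptor(3.8, 160), model), 0L)
  expect_equal(count_hbonds(mk_donor(), place_acceptor(2.9, 60), model), 0L)
  ## far apart: zero
  expect_equal(count_hbonds(mk_donor(), place_acceptor(100, 160), model), 0L)
})

test_that("count_hbonds equals a brute-force donor-acceptor scan", {
  tc <- toy_complex()
  model <- energy_model()
  pose <- suppressWarnings(
    place_peptide(peptide("S", "N"), tc$receptor, tc$template, tc$map))
  res <- mc_sample(pose, map = tc$map, model = model,
                   params = test_params(2000, seed = 3))
  best <- res$record$pose
  got <- count_hbonds(best, best$receptor, model)

  ## independent scan over annotated donors/acceptors
  ann_p <- cycloscan:::annotate_atoms(best$structure$atoms)
  ann_r <- cycloscan:::annotate_atoms(best$receptor$atoms)
  P <- structure_coords(best$structure)
  R <- structure_coords(best$receptor)
  brute <- 0L
  chk <- function(xyz_d, ann_d, i, xyz_a, ann_a, j) {
    if (ann_d$don_base[i] < 0 || !ann_a$is_acc[j]) return(FALSE)
    r <- sqrt(sum((xyz_d[i, ] - xyz_a[j, ])^2))
    if (r < model$hb_rmin || r > model$hb_rmax) return(FALSE)
    b <- xyz_d[ann_d$don_base[i] + 1, ]
    v1 <- b - xyz_d[i, ]; v2 <- xyz_a[j, ] - xyz_d[i, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    ang >= model$hb_angle_min
  }
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(R))) {
    if (chk(P, ann_p, i, R, ann_r, j)) brute <- brute + 1L
    if (chk(R, ann_r, j, P, ann_p, i)) brute <- brute + 1L
  }
  expect_identical(got, brute)
})

test_that("s2_distance is the minimum peptide-atom distance to gatekeeper-2 CA", {
  tc <- toy_complex()
  pose <- suppressWarnings(
    place_peptide(peptide("A", "K"), tc$receptor, tc$template, tc$map))
  gk2_resno <- tc$map$target_resno[tc$map$ref_pos == 82]
  ca <- tc$receptor$atoms[tc$receptor$atoms$resno == gk2_resno &
                          tc$receptor$atoms$atomname == "CA", ]
  P <- structure_coords(pose$structure)
  brute <- min(sqrt(rowSums(sweep(P, 2, c(ca$x, ca$y, ca$z))^2)))
  expect_equal(as.numeric(s2_distance(pose, tc$receptor, tc$map)), brute,
               tolerance = 1e-12)

  ## coincident atom -> 0; all atoms far -> flagged non-penetrating
  pose0 <- pose
  pose0$structure$atoms[1, c("x", "y", "z")] <- c(ca$x, ca$y, ca$z)
  expect_equal(as.numeric(s2_distance(pose0, tc$receptor, tc$map)), 0)
  far <- pose
  far$structure$atoms[, c("x", "y", "z")] <-
    far$structure$atoms[, c("x", "y", "z")] + 300
  d <- s2_distance(far, tc$receptor, tc$map)
  expect_gte(as.numeric(d), 15)
  expect_true(attr(d, "non_penetrating"))

  ## unmapped gatekeeper-2 errors
  m2 <- tc$map
  m2$mapped[m2$ref_pos == 82] <- FALSE
  expect_error(s2_distance(pose, tc$receptor, m2), "unmapped")
})
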