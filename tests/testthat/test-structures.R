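# structures module: IO, alignment, superposition, reference mapping,
# loop taxonomy.

test_that("read_structure parses PDB text, resolves altlocs, reports errors", {
  s <- read_structure(two_residue_pdb(), chain = "A")
  expect_s3_class(s, "Structure")
  expect_equal(nrow(structure_residues(s)), 2L)
  expect_equal(nrow(s$atoms), 9L)  # altloc pair collapsed to one atom
  ## highest-occupancy conformer retained
  ca2 <- s$atoms[s$atoms$resno == 2 & s$atoms$atomname == "CA", ]
  expect_equal(ca2$x, 13.601)
  expect_error(read_structure(two_residue_pdb(), chain = "Z"),
               "chain not found")
  bad <- sub("11.104", "xx.xxx", two_residue_pdb())
  expect_error(read_structure(bad, chain = "A"), "line")
})

test_that("read_structure parses mmCIF and honours residue_range", {
  s <- read_structure(two_residue_mmcif())
  expect_equal(nrow(structure_residues(s)), 2L)
  expect_equal(structure_sequence(s), "AG")
  s1 <- read_structure(two_residue_pdb(), chain = "A",
                       residue_range = c(1, 1))
  expect_equal(structure_residues(s1)$resname, "ALA")
})

test_that("align_sequences: identity, truncation coverage, mismatch count", {
  a <- build_chain("ACDEFGHIKL")
  al <- align_sequences(a, a)
  expect_equal(al$identity_fraction, 1)
  expect_equal(al$coverage, 1)
  expect_equal(nrow(al$pairs), 10L)

  b <- build_chain("ACDE")
  al2 <- align_sequences(build_chain("ACDEF"), b)
  expect_equal(al2$coverage, 0.8)
  expect_equal(al2$identity_fraction, 1)

  ## 20-mers differing at 4 positions: brute-force column count
  sa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sb <- sa; sb[c(3, 7, 12, 18)] <- c("A", "A", "A", "A")
  al3 <- align_sequences(build_chain(sa), build_chain(sb))
  brute <- mean(sa == sb)
  expect_equal(al3$identity_fraction, brute)
  expect_equal(al3$identity_fraction, 0.8)

  ## pairs strictly increasing in both columns (no crossing)
  for (al_k in list(al, al2, al3)) {
    expect_true(all(diff(al_k$pairs[, 1]) > 0))
    expect_true(all(diff(al_k$pairs[, 2]) > 0))
  }
  expect_error(align_sequences(a, structure(list(atoms = data.frame()),
                                            class = "Structure")),
               "empty")
})

test_that("kabsch_superpose matches the independent SVD oracle", {
  set.seed(7)
  a <- matrix(rnorm(12), 4, 3)
  expect_equal(kabsch_superpose(a, a)$rmsd, 0)

  ## rigid-motion invariance: rotation 90 deg about z + translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  b <- sweep(a %*% t(Rz), 2, c(1, 2, 3), `+`)
  sup <- kabsch_superpose(a, b)
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)

  ## non-congruent sets: equality with the oracle to 1e-8 over many sizes
  for (n in c(4, 7, 13, 26, 50)) {
    A <- matrix(rnorm(3 * n), n, 3)
    B <- matrix(rnorm(3 * n), n, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, svd_superpose_oracle(A, B),
                 tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(a, a[1:3, ]), "length")
})

test_that("kabsch RMSD is invariant under proper rigid motions", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:40, 1)
    A <- matrix(rnorm(3 * n), n, 3)
    B <- matrix(rnorm(3 * n), n, 3)
    base <- kabsch_superpose(A, B)$rmsd
    R <- random_rotation(); t1 <- rnorm(3, sd = 5)
    expect_equal(kabsch_superpose(A, sweep(B %*% t(R), 2, t1, `+`))$rmsd,
                 base, tolerance = 1e-9)
    R2 <- random_rotation()
    expect_equal(kabsch_superpose(sweep(A %*% t(R2), 2, t1, `+`), B)$rmsd,
                 base, tolerance = 1e-9)
  }
})

test_that("superpose_domains: identity, atom intersection, noise, symmetry", {
  ref <- ref_domain()
  idal <- identity_alignment(ref)
  expect_equal(superpose_domains(ref, ref, idal)$rmsd, 0)

  ## deleting one residue's sidechain atoms only shrinks the matched set
  b <- ref
  drop <- b$atoms$resno == 80 & !(b$atoms$atomname %in% c("N", "CA", "C", "O"))
  b$atoms <- b$atoms[!drop, , drop = FALSE]
  sup_b <- superpose_domains(ref, b, idal)
  expect_equal(sup_b$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup_b$n_atoms,
               superpose_domains(ref, ref, idal)$n_atoms - sum(drop))

  ## Gaussian noise: RMSD near sigma * sqrt(3), and equal to a direct
  ## recomputation from the matched atom list
  pn <- perturb_structure(ref, "noise", sigma = 0.5, seed = 4)
  sup <- superpose_domains(ref, pn, idal)
  expect_lt(abs(sup$rmsd - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.10)
  A <- as.matrix(ref$atoms[, c("x", "y", "z")])
  B <- as.matrix(pn$atoms[, c("x", "y", "z")])
  expect_equal(sup$rmsd, svd_superpose_oracle(A, B), tolerance = 1e-10)

  ## swapping a and b inverts the transform, RMSD unchanged
  sup_ab <- superpose_domains(ref, pn, idal)
  sup_ba <- superpose_domains(pn, ref, idal)
  expect_equal(sup_ab$rmsd, sup_ba$rmsd, tolerance = 1e-8)
  expect_equal(sup_ba$rotation, t(sup_ab$rotation), tolerance = 1e-8)
  ## CA-only mode uses one atom per residue
  expect_equal(superpose_domains(ref, ref, idal, atom_set = "ca")$n_atoms,
               nrow(structure_residues(ref)))
})

test_that("map_active_site maps the 16 reference positions", {
  ref <- ref_domain()
  al <- align_sequences(ref, ref)
  m <- map_active_site(ref, ref, al)
  expect_equal(nrow(m), 16L)
  expect_true(all(m$mapped))
  expect_equal(m$target_resname[m$ref_pos == 55], "ARG")
  expect_equal(m$target_resname[m$ref_pos == 121], "TRP")
  expect_equal(m$target_resname[m$ref_pos == 103], "ALA")
  ## idempotent and total on the reference positions
  expect_identical(map_active_site(ref, ref, al), m)

  ## a gap at position 73 propagates to "unmapped"
  tgt <- ref
  tgt$atoms <- tgt$atoms[tgt$atoms$resno != 73, , drop = FALSE]
  m2 <- map_active_site(tgt, ref, align_sequences(ref, tgt))
  expect_false(m2$mapped[m2$ref_pos == 73])
  expect_true(all(m2$mapped[m2$ref_pos != 73]))

  ## divergent identity carried through: His at the 121-equivalent
  tgt3 <- ref
  i121 <- tgt3$atoms$resno == 121
  tgt3$atoms <- tgt3$atoms[!(i121 & !(tgt3$atoms$atomname %in%
                                        c("N", "CA", "C", "O", "CB"))), ]
  tgt3$atoms$resname[tgt3$atoms$resno == 121] <- "HIS"
  m3 <- map_active_site(tgt3, ref, align_sequences(ref, tgt3))
  expect_equal(m3$target_resname[m3$ref_pos == 121], "HIS")

  ## reference lacking a reference-position residue errors by name
  ref_bad <- ref
  ref_bad$atoms <- ref_bad$atoms[ref_bad$atoms$resno != 55, , drop = FALSE]
  expect_error(map_active_site(ref, ref_bad, align_sequences(ref_bad, ref)),
               "55")
})

test_that("classify_position121 follows the Trp/His-permissive rule", {
  mk <- function(res) {
    m <- data.frame(ref_pos = 121L, ref_resname = "TRP",
                    target_resname = res, target_resno = 121L,
                    mapped = TRUE)
    class(m) <- c("ActiveSiteMap", "data.frame")
    m
  }
  expect_equal(classify_position121(mk("TRP"))$label, "permissive")
  expect_equal(classify_position121(mk("HIS"))$label, "permissive")
  expect_equal(classify_position121(mk("TYR"))$label, "non-permissive")
  expect_equal(classify_position121(mk("GLU"))$label, "non-permissive")
  novel <- classify_position121(mk("LYS"))
  expect_equal(novel$label, "non-permissive")
  expect_equal(novel$note, "novel residue")
  un <- mk("TRP"); un$mapped <- FALSE
  expect_error(classify_position121(un), "unmapped")
})

test_that("classify_loops reproduces the three-loop taxonomy", {
  ref <- ref_domain()
  self <- classify_loops(ref, ref, align_sequences(ref, ref))
  expect_equal(self, list(b1b2 = "full-length", a1b3 = "PPIA-class",
                          a2b8 = "standard"))

  ## target built from the reference with residues 12-15 removed
  del <- ref
  del$atoms <- del$atoms[!(del$atoms$resno %in% 12:15), , drop = FALSE]
  expect_equal(classify_loops(del, ref, align_sequences(ref, del))$b1b2,
               "deleted")

  ## shorter / longer alpha1-beta3 loop
  shrt <- ref
  shrt$atoms <- shrt$atoms[!(shrt$atoms$resno %in% 44:45), , drop = FALSE]
  expect_equal(classify_loops(shrt, ref, align_sequences(ref, shrt))$a1b3,
               "short")

  ## displaced alpha2-beta8 loop -> alternate
  alt <- ref
  loop <- alt$atoms$resno %in% 146:155
  alt$atoms[loop, c("x", "y", "z")] <-
    alt$atoms[loop, c("x", "y", "z")] + 3.0
  expect_equal(classify_loops(alt, ref, align_sequences(ref, alt))$a2b8,
               "alternate")
})
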