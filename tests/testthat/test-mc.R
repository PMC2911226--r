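# Metropolis sampler: determinism, monotonicity, greediness, oracle
# equivalence on a discretised flexible space.

test_that("mc_params validates its move set", {
  expect_error(mc_params(iterations = -1), "iterations")
  expect_error(mc_params(weights = c(sidechain = 0, backbone = 0,
                                     gatekeeper = 0)), "not all zero")
  expect_error(mc_params(weights = c(sidechain = -1, backbone = 1,
                                     gatekeeper = 1)), "non-negative")
})

test_that("zero iterations returns the initial pose and scores unchanged", {
  tc <- toy_complex()
  model <- energy_model()
  pose <- suppressWarnings(
    place_peptide(peptide("A", "S"), tc$receptor, tc$template, tc$map))
  res <- mc_sample(pose, map = tc$map, model = model,
                   params = mc_params(iterations = 0, seed = 5))
  expect_equal(unname(structure_coords(res$record$pose$structure)),
               unname(structure_coords(pose$structure)), tolerance = 1e-12)
  ## no receptor sidechain was moved, so the reported E_bind matches the
  ## pure-R scorer (the dual-route check of the energy model)
  expect_equal(res$record$E_bind,
               score_energy(pose, pose$receptor, model)$E_bind,
               tolerance = 1e-8)
  expect_equal(res$record$accepted_moves, 0L)
})

test_that("identical seeds give bit-identical results; seeds matter", {
  tc <- toy_complex()
  pose <- suppressWarnings(
    place_peptide(peptide("D", "W"), tc$receptor, tc$template, tc$map))
  r1 <- mc_sample(pose, map = tc$map, params = test_params(1500, seed = 42))
  r2 <- mc_sample(pose, map = tc$map, params = test_params(1500, seed = 42))
  expect_identical(r1$record$E_bind, r2$record$E_bind)
  expect_identical(structure_coords(r1$record$pose$structure),
                   structure_coords(r2$record$pose$structure))
  expect_identical(r1$trace, r2$trace)
  r3 <- mc_sample(pose, map = tc$map, params = test_params(1500, seed = 43))
  expect_false(identical(r1$record$E_bind, r3$record$E_bind))
})

test_that("best-so-far energy is non-increasing along the trace", {
  tc <- toy_complex()
  for (seqs in list(c("W", "W"), c("E", "F"), c("G", "G"))) {
    pose <- suppressWarnings(
      place_peptide(peptide(seqs[1], seqs[2]), tc$receptor, tc$template,
                    tc$map))
    ## single stage: the raw kernel trace, exact monotonicity
    res <- mc_sample(pose, map = tc$map,
                     params = mc_params(iterations = 4000, seed = 7,
                                        temperature = 600, max_step = 60,
                                        trace_interval = 100L))
    expect_true(all(diff(res$trace$best_energy) <= 0))
    ## stitched annealing stages
    res2 <- mc_sample(pose, map = tc$map,
                      params = test_params(4000, seed = 7,
                                           trace_interval = 100L))
    expect_true(all(diff(res2$trace$best_energy) <= 0))
  }
})

test_that("the sampler is greedy at zero temperature", {
  tc <- toy_complex()
  pose <- suppressWarnings(
    place_peptide(peptide("K", "F"), tc$receptor, tc$template, tc$map))
  res <- mc_sample(pose, map = tc$map,
                   params = mc_params(iterations = 4000, seed = 13,
                                      temperature = 0, max_step = 40))
  expect_identical(res$record$uphill_accepted, 0L)
  ## while at a hot temperature uphill moves are accepted
  hot <- mc_sample(pose, map = tc$map,
                   params = mc_params(iterations = 4000, seed = 13,
                                      temperature = 5000, max_step = 40))
  expect_gt(hot$record$uphill_accepted, 0L)
})

test_that("MC finds the exhaustive minimum of a discretised torsion space", {
  ## two flexible sidechains (P3 Ser, P2 Cys: one chi each), rotamer grid
  ## {-60, 60, 180}^2 -> 9 states; the continuous sampler must do at
  ## least as well as exhaustive enumeration over the grid
  tc <- toy_complex()
  model <- energy_model()
  pep <- peptide("S", "C")
  pose <- suppressWarnings(
    place_peptide(pep, tc$receptor, tc$template, tc$map))

  grid <- c(-60, 60, 180)
  enum_best <- Inf
  for (c1 in grid) for (c2 in grid) {
    p <- pose
    xyz <- structure_coords(p$structure)
    for (tor in p$torsions) {
      target <- if (tor$name == "chi1_P3") c1
                else if (tor$name == "chi1_P2") c2 else NA
      if (is.na(target)) next
      cur <- cycloscan:::dihedral_angle(xyz[tor$ref_d, ], xyz[tor$ai, ],
                                        xyz[tor$aj, ], xyz[tor$ref_x, ])
      xyz <- cycloscan:::rotate_about_bond(xyz, tor$moving, xyz[tor$ai, ],
                                           xyz[tor$aj, ],
                                           -(target - cur))
    }
    p$structure$atoms[, c("x", "y", "z")] <- xyz
    e <- score_energy(p, p$receptor, model)$E_bind + tether_penalty(p)
    enum_best <- min(enum_best, e)
  }

  ## sample only the sidechain chis so the spaces match
  res <- mc_sample(pose, map = tc$map, model = model,
                   params = mc_params(iterations = 6000, seed = 3,
                                      temperature = 600,
                                      anneal_factor = 0.2,
                                      anneal_stages = 4,
                                      weights = c(sidechain = 1,
                                                  backbone = 0,
                                                  gatekeeper = 0),
                                      max_step = 90))
  mc_total <- res$record$E_bind + tether_penalty(res$record$pose)
  expect_lte(mc_total, enum_best + 1e-6)
})

test_that("rotating a chi by the measured offset reproduces the target", {
  ## sanity of the test-side rotation helper used in the oracle above
  s <- build_chain("C", chis = list(180))
  expect_equal(measure_chis <- cycloscan:::measure_chis(s, 1L), 180)
})
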