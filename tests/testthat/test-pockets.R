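# pockets module: gatekeeper gap geometry, rim charge, surface classes.

test_that("gatekeeper_gap reproduces a constructed gap and is rigid-invariant", {
  toy <- make_toy_receptor(scenario_config(gap_width = 4.0))
  map <- toy_active_site_map(toy$structure)
  expect_equal(gatekeeper_gap(toy$structure, map), 4.0, tolerance = 0.1)

  moved <- perturb_structure(toy$structure, "rigid", seed = 9)
  expect_equal(gatekeeper_gap(moved, map),
               gatekeeper_gap(toy$structure, map), tolerance = 1e-8)
})

test_that("gatekeeper_gap equals the brute-force all-pairs minimum", {
  ## hand-built 3-atom-per-sidechain case at PPIA positions 73 and 103
  mk <- function(resno, base) {
    data.frame(resno = resno, resname = "LYS",
               atomname = c("N", "CA", "C", "CB", "CG", "CD"),
               element = c("N", "C", "C", "C", "C", "C"),
               x = base[1] + c(0, 1, 2, 1.2, 1.8, 2.9),
               y = base[2] + c(0, 0.5, 0, 1.5, 2.6, 3.1),
               z = base[3] + c(0, 0, 0.3, 0.2, 0.9, 0.4))
  }
  atoms <- rbind(mk(73L, c(0, 0, 0)), mk(103L, c(7, 2, 1)))
  s <- new_structure("hand", "A", atoms)
  map <- data.frame(ref_pos = c(73L, 103L), ref_resname = "LYS",
                    target_resname = "LYS", target_resno = c(73L, 103L),
                    mapped = TRUE)
  class(map) <- c("ActiveSiteMap", "data.frame")
  sc1 <- atoms[atoms$resno == 73 & atoms$atomname %in% c("CB", "CG", "CD"),
               c("x", "y", "z")]
  sc3 <- atoms[atoms$resno == 103 & atoms$atomname %in% c("CB", "CG", "CD"),
               c("x", "y", "z")]
  brute <- Inf
  for (i in 1:3) for (j in 1:3)
    brute <- min(brute, sqrt(sum((sc1[i, ] - sc3[j, ])^2)))
  expect_equal(gatekeeper_gap(s, map), brute, tolerance = 1e-12)
})

test_that("rim_formal_charge sums sidechain formal charges", {
  ## PPIA rim: Thr Glu Lys Ala Thr Ser Gln -> -1 + 1 = 0
  toy <- make_toy_receptor(scenario_config())
  map <- toy_active_site_map(toy$structure)
  expect_identical(rim_formal_charge(map), 0L)

  ## all-Asp rim: -7
  asp <- make_toy_receptor(scenario_preset("all-asp-rim"))
  expect_identical(rim_formal_charge(toy_active_site_map(asp$structure)), -7L)

  ## 2 Lys + 1 Arg + 1 Glu among the rim: hand sum +2
  mixed <- make_toy_receptor(scenario_config(
    rim = c("K", "E", "K", "R", "A", "S", "T"), favored_p2_class = "none"))
  expect_identical(rim_formal_charge(toy_active_site_map(mixed$structure)),
                   2L)

  ## unmapped rim position counts 0 with a warning
  m2 <- map
  m2$mapped[m2$ref_pos == 81] <- FALSE
  expect_warning(ch <- rim_formal_charge(m2), "counted as charge 0")
  expect_identical(ch, 1L)  # loses the Glu at 81
})

test_that("classify_surface applies occlusion-first precedence", {
  thresholds <- cycloscan_thresholds()
  open <- make_toy_receptor(scenario_config())          # gap 9, charge 0
  m_open <- toy_active_site_map(open$structure)
  expect_equal(classify_surface(open$structure, m_open)$label,
               "mixed-neutral")

  acidic <- make_toy_receptor(scenario_config(
    rim = c("T", "D", "E", "A", "T", "S", "Q"),  # net charge -2
    favored_p2_class = "none"))
  expect_equal(classify_surface(acidic$structure,
                                toy_active_site_map(acidic$structure))$label,
               "acidic")

  ## occlusion overrides charge: gap 3 with a basic rim is still occluded
  occl <- make_toy_receptor(scenario_config(
    gap_width = 3.0, rim = c("K", "K", "K", "R", "T", "S", "Q"),
    favored_p2_class = "none"))
  cls <- classify_surface(occl$structure, toy_active_site_map(occl$structure))
  expect_equal(cls$label, "occluded")
  expect_gt(cls$net_formal_charge, 0)
  expect_lt(cls$gap_width, thresholds$occlusion_gap)

  ## toy ground truth agrees with the classifier for every preset
  for (preset in c("aromatic-S2", "occluded", "acidic-P3", "all-asp-rim")) {
    toy <- make_toy_receptor(scenario_preset(preset))
    got <- classify_surface(toy$structure,
                            toy_active_site_map(toy$structure))
    expect_equal(got$label, toy$truth$surface_class, label = preset)
  }
})

test_that("classify_surface is invariant under atom-order permutation", {
  toy <- make_toy_receptor(scenario_config(gap_width = 4.5,
                                           favored_p2_class = "none"))
  map <- toy_active_site_map(toy$structure)
  base <- classify_surface(toy$structure, map)
  set.seed(2)
  for (rep in 1:3) {
    perm <- toy$structure
    ## shuffle atoms within each residue (residue order must stay sorted)
    idx <- unlist(lapply(split(seq_len(nrow(perm$atoms)),
                               perm$atoms$resno),
                         sample), use.names = FALSE)
    perm$atoms <- perm$atoms[idx, , drop = FALSE]
    got <- classify_surface(perm, map)
    expect_equal(got$label, base$label)
    expect_equal(got$gap_width, base$gap_width, tolerance = 1e-10)
  }
})
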