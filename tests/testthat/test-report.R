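# Reporting: specificity arrays, rankings, chemistry-class summaries.

test_that("chemistry classes partition the 20 amino acids", {
  cls <- chemistry_classes()
  all20 <- unlist(cls, use.names = FALSE)
  expect_length(all20, 20L)
  expect_equal(anyDuplicated(all20), 0L)
})

test_that("build_array fills all cells and records extremes", {
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  rec <- fake_records(ab, E = 0:399)
  arr <- build_array(rec)
  expect_equal(dim(arr$E_bind), c(20L, 20L))
  expect_false(anyNA(arr$E_bind))
  expect_equal(arr$E_range, c(0, 399))
  ## flattening returns the input multiset
  flat <- flatten_array(arr)
  expect_equal(sort(flat$E_bind), sort(rec$E_bind))
  m <- merge(flat, rec, by = c("p3", "p2"))
  expect_equal(m$E_bind.x, m$E_bind.y)

  ## missing / duplicate combinations error and name the cells
  expect_error(build_array(rec[-17, ]), "missing .*combinations")
  expect_error(build_array(rbind(rec, rec[1, ])), "duplicate")

  ## 2-letter alphabet: cells echo the inputs
  rec2 <- fake_records(c("D", "F"), E = c(1, 2, 3, 4))
  arr2 <- build_array(rec2)
  expect_equal(arr2$E_bind["D", "F"],
               rec2$E_bind[rec2$p3 == "D" & rec2$p2 == "F"])
  expect_equal(as.vector(arr2$E_bind), c(1, 3, 2, 4))
})

test_that("rank_top orders ascending with lexicographic tie-break", {
  rec <- data.frame(peptide = c("AAGP", "BBGP", "CCGP"),
                    p3 = c("A", "B", "C"), p2 = c("A", "B", "C"),
                    E_bind = c(-3, -1, -5), d_S2 = 1, n_hb = 0,
                    accepted_moves = 0, status = "ok")
  expect_equal(rank_top(rec, 2)$peptide, c("CCGP", "AAGP"))
  tie <- rec; tie$E_bind <- c(-1, -1, -5)
  expect_equal(rank_top(tie, 3)$peptide, c("CCGP", "AAGP", "BBGP"))
  expect_error(rank_top(rec, 4), "exceeds")
  ## full ranking is a total order consistent with pairwise comparison
  rr <- fake_records(c("A", "D", "W"), seed = 8)
  full <- rank_top(rr, nrow(rr))
  expect_true(all(diff(full$E_bind) >= 0))
})

test_that("classify_preferences flags classes against the overall median", {
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  ## aromatic-P2 rows set lowest -> aromatics favored at P2
  rec <- fake_records(ab, E = 5)
  rec$E_bind[rec$p2 %in% c("F", "W", "Y")] <- -5
  prefs <- classify_preferences(build_array(rec))
  expect_equal(prefs$flag[prefs$position == "P2" &
                          prefs$class == "aromatic"], "favored")
  ## no other class may be flagged favored
  expect_false(any(prefs$flag[prefs$position == "P2" &
                              prefs$class != "aromatic"] == "favored"))

  ## uniform array: nothing flagged either way
  uni <- classify_preferences(build_array(fake_records(ab, E = 1)))
  expect_true(all(uni$flag == "neutral"))

  ## invariant under record order permutation
  set.seed(31)
  rec3 <- fake_records(ab, seed = 3)
  p1 <- classify_preferences(build_array(rec3))
  p2 <- classify_preferences(build_array(rec3[sample(nrow(rec3)), ]))
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("acidic-P3 scenario recovers the generator's ground truth", {
  ## basic patch at the P3 subsite -> acidic P3 favored, basic disfavored
  tc <- toy_complex("acidic-P3")
  ab <- c("A", "D", "E", "K", "R")
  res <- run_screen(tc$receptor, tc$map, mini_library(ab, ab),
                    tc$template, params = test_params(2500, seed = 11))
  arr <- build_array(res)
  prefs <- classify_preferences(arr)
  acid <- prefs[prefs$position == "P3" & prefs$class == "acidic", ]
  basic <- prefs[prefs$position == "P3" & prefs$class == "basic", ]
  expect_equal(acid$flag, "favored")
  expect_equal(basic$flag, "disfavored")
  expect_lt(acid$median_E, basic$median_E)
})

test_that("write_report emits the documented bundle", {
  rec <- fake_records(c("A", "D", "W"), seed = 5)
  dir <- tempfile()
  paths <- write_report(rec, dir, top_n = 3)
  expect_true(all(file.exists(paths)))
  qc <- jsonlite::read_json(paths[["qc"]], simplifyVector = TRUE)
  expect_length(qc$top, 3L)
  expect_equal(qc$top, rank_top(rec, 3)$peptide)
  arr_json <- jsonlite::read_json(paths[["array_json"]],
                                  simplifyVector = TRUE)
  expect_equal(dim(arr_json$E_bind), c(3L, 3L))
  scatter <- read.delim(paths[["scatter"]])
  expect_equal(nrow(scatter), nrow(rec))
})
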