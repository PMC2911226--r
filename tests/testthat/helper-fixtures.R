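# Shared fixtures and independent oracles.  Everything is generated in
# code; expensive objects are built once per test run and memoised here.

# --- hand-written coordinate files -----------------------------------

two_residue_pdb <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.697   7.155  -4.974  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.560   7.331  -5.840  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      10.521   6.277  -4.120  1.00  0.00           C",
    "ATOM      6  N   GLY A   2      12.640   7.879  -3.856  1.00  0.00           N",
    "ATOM      7  CA AGLY A   2      13.601   8.952  -3.602  0.60  0.00           C",
    "ATOM      8  CA BGLY A   2      13.701   8.952  -3.602  0.40  0.00           C",
    "ATOM      9  C   GLY A   2      14.993   8.420  -3.296  1.00  0.00           C",
    "ATOM     10  O   GLY A   2      15.260   7.233  -3.467  1.00  0.00           O"),
    collapse = "\n")
}

two_residue_mmcif <- function() {
  paste(c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "ATOM 1 N N . ALA A 1 11.104 6.134 -6.504 1.00",
    "ATOM 2 C CA . ALA A 1 11.639 6.071 -5.147 1.00",
    "ATOM 3 C C . ALA A 1 12.697 7.155 -4.974 1.00",
    "ATOM 4 O O . ALA A 1 13.560 7.331 -5.840 1.00",
    "ATOM 5 N N . GLY A 2 12.640 7.879 -3.856 1.00",
    "ATOM 6 C CA . GLY A 2 13.601 8.952 -3.602 1.00",
    "#"), collapse = "\n")
}

# --- independent superposition oracle --------------------------------
# Written before the main implementation and kept deliberately separate
# from it: centroid removal, SVD of the covariance, reflection fix, then
# direct RMSD of the transformed set.

svd_superpose_oracle <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(A0) %*% B0)           # covariance of A on B (note the order)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Bfit <- B0 %*% t(R)
  sqrt(mean(rowSums((A0 - Bfit)^2)))
}

# random proper rotation from a seeded RNG
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# --- memoised expensive fixtures -------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

ref_domain <- function() cached("ref_domain", make_reference_domain(seed = 42))

toy_complex <- function(preset = "aromatic-S2") {
  cached(paste0("toy_", preset), make_template_complex(scenario_preset(preset)))
}

# small peptide library over a restricted alphabet
mini_library <- function(p3s, p2s) {
  out <- list()
  for (p3 in p3s) for (p2 in p2s) out[[length(out) + 1L]] <- peptide(p3, p2)
  out
}

# fast Monte-Carlo parameters for module tests
test_params <- function(iterations = 2000L, seed = 1L, ...)
  screen_params(iterations = iterations, seed = seed, ...)

# fabricated screen-result table covering a full alphabet
fake_records <- function(alphabet, E = NULL, seed = 1) {
  grid <- expand.grid(p2 = alphabet, p3 = alphabet,
                      stringsAsFactors = FALSE)[, c("p3", "p2")]
  n <- nrow(grid)
  set.seed(seed)
  data.frame(peptide = paste0(grid$p3, grid$p2, "GP"),
             p3 = grid$p3, p2 = grid$p2,
             E_bind = if (is.null(E)) rnorm(n) else rep_len(E, n),
             d_S2 = runif(n, 2, 12), n_hb = sample(0:8, n, TRUE),
             accepted_moves = sample(100:1000, n, TRUE),
             status = "ok", stringsAsFactors = FALSE)
}
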