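## Turning screen results into the reporting artefacts: 20x20 P3xP2
## specificity arrays, top-N rankings and chemistry-class summaries.

#' Default chemistry-class partition of the 20 amino acids
#'
#' Groups are disjoint and cover all 20 residues.  Borderline choices
#' (His with basic, Cys and Met with aliphatic-small) are deliberate and
#' documented in the vignette.
#'
#' @return named list of one-letter code vectors.
#' @export
chemistry_classes <- function() {
  cls <- list(
    acidic = c("D", "E"),
    basic = c("K", "R", "H"),
    aromatic = c("F", "W", "Y"),
    `aliphatic-small` = c("G", "A", "V", "L", "I", "P", "C", "M"),
    polar = c("S", "T", "N", "Q")
  )
  stopifnot(identical(sort(unlist(cls, use.names = FALSE)),
                      sort(unname(AA1))))
  cls
}

#' Build the P3 x P2 specificity array
#'
#' @param records a `ScreenResults` data.frame (or compatible) with one row
#'   per (P3, P2) combination over a common alphabet.
#' @return a `SpecificityArray`: list of matrices `E_bind`, `d_S2`, `n_hb`
#'   (P3 on rows/x, P2 on columns/y) plus `E_range` for colour scaling and
#'   `cell_size` metadata (larger = deeper S2 penetration, i.e. smaller
#'   distance).
#' @export
build_array <- function(records) {
  df <- as.data.frame(records)
  alphabet <- sort(unique(c(df$p3, df$p2)))
  expected <- paste0(rep(alphabet, each = length(alphabet)), alphabet)
  got <- paste0(df$p3, df$p2)
  dup <- unique(got[duplicated(got)])
  if (length(dup))
    stop("duplicate (P3,P2) combinations: ", paste(dup, collapse = ", "))
  missing <- setdiff(expected, got)
  if (length(missing))
    stop("missing (P3,P2) combinations: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)",
                                           length(missing) - 10) else "")
  n <- length(alphabet)
  mk <- function(col) {
    m <- matrix(NA_real_, n, n, dimnames = list(P3 = alphabet,
                                                P2 = alphabet))
    m[cbind(match(df$p3, alphabet), match(df$p2, alphabet))] <- df[[col]]
    m
  }
  E <- mk("E_bind"); D <- mk("d_S2"); H <- mk("n_hb")
  rng <- range(E, na.rm = TRUE)
  ## cell size metadata: inverse-distance scaled to (0, 1]
  cs <- 1 / (1 + D)
  structure(list(E_bind = E, d_S2 = D, n_hb = H,
                 E_range = rng, cell_size = cs, alphabet = alphabet),
            class = "SpecificityArray")
}

#' Flatten a SpecificityArray back to records
#' @param array a `SpecificityArray`.
#' @return data.frame with columns p3, p2, E_bind, d_S2, n_hb.
#' @export
flatten_array <- function(array) {
  ab <- array$alphabet
  grid <- expand.grid(p2 = ab, p3 = ab, stringsAsFactors = FALSE)
  grid <- grid[, c("p3", "p2")]
  idx <- cbind(match(grid$p3, ab), match(grid$p2, ab))
  data.frame(p3 = grid$p3, p2 = grid$p2,
             E_bind = array$E_bind[idx], d_S2 = array$d_S2[idx],
             n_hb = array$n_hb[idx], stringsAsFactors = FALSE)
}

#' Rank peptides by the energy metric
#'
#' Ascending by `E_bind` (lower = more favourable); ties broken
#' lexicographically by peptide sequence.
#'
#' @param records `ScreenResults` data.frame.
#' @param n number of top peptides to return.
#' @param key ranking key (only `"energy"` is defined).
#' @return the top-n rows, ordered.
#' @export
rank_top <- function(records, n, key = c("energy")) {
  key <- match.arg(key)
  df <- as.data.frame(records)
  if (n > nrow(df)) stop("n exceeds the number of records")
  df <- df[order(df$E_bind, df$peptide), , drop = FALSE]
  rownames(df) <- NULL
  df[seq_len(n), , drop = FALSE]
}

#' Summarise favoured/disfavoured chemistry classes per position
#'
#' For each substrate position (P2, P3) and chemistry class, the median
#' `E_bind` and median `d_S2` over the array; a class is flagged
#' `favored` when its median energy is below the overall median,
#' `disfavored` when above (ties unflagged).
#'
#' @param array a `SpecificityArray`.
#' @param classes a [chemistry_classes()] partition.
#' @return data.frame with columns `position`, `class`, `median_E`,
#'   `median_d`, `flag`.
#' @export
classify_preferences <- function(array, classes = chemistry_classes()) {
  df <- flatten_array(array)
  overall <- stats::median(df$E_bind, na.rm = TRUE)
  rows <- list()
  for (posn in c("P2", "P3")) {
    col <- if (posn == "P2") df$p2 else df$p3
    for (cl in names(classes)) {
      sel <- col %in% classes[[cl]]
      if (!any(sel)) next
      mE <- stats::median(df$E_bind[sel], na.rm = TRUE)
      mD <- stats::median(df$d_S2[sel], na.rm = TRUE)
      flag <- if (isTRUE(mE < overall)) "favored"
              else if (isTRUE(mE > overall)) "disfavored" else "neutral"
      rows[[length(rows) + 1L]] <- data.frame(
        position = posn, class = cl, median_E = mE, median_d = mD,
        flag = flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "overall_median_E") <- overall
  out
}

#' Write the reporting bundle for a screen
#'
#' Emits the array as JSON and TSV, the energy-vs-distance scatter data as
#' TSV, and a QC report (JSON) with the top-N list and class summaries.
#'
#' @param records `ScreenResults` data.frame.
#' @param out_dir output directory (created if needed).
#' @param top_n size of the ranking in the QC report.
#' @return invisibly, the paths written.
#' @export
write_report <- function(records, out_dir, top_n = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arr <- build_array(records)
  paths <- c(
    array_json = file.path(out_dir, "specificity_array.json"),
    array_tsv = file.path(out_dir, "specificity_array.tsv"),
    scatter = file.path(out_dir, "scatter.tsv"),
    qc = file.path(out_dir, "qc_report.json"))
  jsonlite::write_json(
    list(alphabet = arr$alphabet, E_bind = arr$E_bind, d_S2 = arr$d_S2,
         n_hb = arr$n_hb, E_range = arr$E_range,
         encoding = list(color = "E_bind (low = favourable)",
                         size = "1/(1+d_S2) (large = deep S2 penetration)",
                         hue = "n_hb")),
    paths["array_json"], digits = NA, matrix = "rowmajor")
  utils::write.table(flatten_array(arr), paths["array_tsv"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  df <- as.data.frame(records)
  utils::write.table(df[, c("peptide", "E_bind", "d_S2", "n_hb")],
                     paths["scatter"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  top <- rank_top(df, min(top_n, nrow(df)))
  prefs <- classify_preferences(arr)
  jsonlite::write_json(
    list(top = top$peptide, top_E = top$E_bind,
         preferences = prefs,
         overall_median_E = attr(prefs, "overall_median_E")),
    paths["qc"], digits = NA, auto_unbox = FALSE)
  invisible(paths)
}
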