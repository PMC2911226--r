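## Retrieval of deposited structures.  Entries are looked up in a local
## cache first (the `CYCLOSCAN_PDB_DIR` directory, then any files shipped
## under inst/extdata/pdb), and downloaded from RCSB only as a last
## resort, so accession-dependent analyses are reproducible offline once
## the files are present.

#' Locate or download a PDB entry
#'
#' @param accession 4-character PDB identifier.
#' @param dir download/cache directory (defaults to `CYCLOSCAN_PDB_DIR`
#'   or a temporary directory).
#' @return path to the `.pdb` file.
#' @export
fetch_pdb <- function(accession,
                      dir = Sys.getenv("CYCLOSCAN_PDB_DIR", unset = "")) {
  accession <- toupper(accession)
  fname <- paste0(accession, ".pdb")
  candidates <- character()
  if (nzchar(dir)) candidates <- c(candidates, file.path(dir, fname),
                                   file.path(dir, tolower(fname)))
  pkg_file <- system.file("extdata", "pdb", fname, package = "cycloscan")
  if (nzchar(pkg_file)) candidates <- c(candidates, pkg_file)
  for (f in candidates) if (file.exists(f)) return(f)

  dest_dir <- if (nzchar(dir)) dir else file.path(tempdir(), "cycloscan-pdb")
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dest_dir, fname)
  url <- paste0("https://files.rcsb.org/download/", fname)
  ok <- tryCatch({
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
    file.exists(dest) && file.size(dest) > 1000
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    unlink(dest)
    stop("PDB entry ", accession, " unavailable: not in the local cache (",
         "set CYCLOSCAN_PDB_DIR or place ", fname, " under inst/extdata/pdb)",
         " and download from RCSB failed (offline?)")
  }
  dest
}

#' PDB accessions of the cyclophilin PPIase-domain structures
#'
#' Named character vector mapping isoform names to the deposited entries
#' used in the family-wide comparison; `ppia_docking` is the
#' PPIA structure used as the docking receptor and `template` the
#' PPWD1 complex that provides the bound Gly-Pro pose.
#' @export
CYCLOPHILIN_ACCESSIONS <- c(
  PPIA = "2CPL", PPIB = "1CYN", PPIC = "2ESL", PPIE = "2R99",
  PPIF = "2BIT", PPIG = "2GW2", PPIH = "1QOI", PPIL1 = "1XWN",
  PPIL2 = "1ZKC", PPIL3 = "2OK3", `SDCCAG-10` = "2HQ6",
  PPWD1 = "2A2N", NKTR = "2HE9",
  ppia_docking = "1AK4", template = "2A2N")
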