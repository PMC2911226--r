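## Coordinate-file input.  Hand-rolled fixed-width PDB and minimal mmCIF
## atom_site readers: the pre-installed stack has no PDB parser, and the
## subset needed here (one chain, heavy atoms, altloc and model handling)
## is small and fully specified.

#' Read one chain of a PDB or mmCIF file
#'
#' Parses ATOM (and optionally HETATM) records of the requested chain.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by altloc identifier order); for multi-model files (NMR
#' ensembles) a single model is kept, model 1 by default.
#'
#' @param source path to a file, or a character vector of file lines.
#' @param chain chain identifier; if `NULL` the first chain found is used.
#' @param residue_range optional inclusive `c(lo, hi)` span of author
#'   residue numbers.
#' @param keep_hetero if `TRUE`, heteroresidues (ligands; never waters) are
#'   retained and flagged `het`.
#' @param model model number to keep for multi-model files.
#' @param id label for the returned Structure (defaults to the file name).
#' @return a [new_structure()] object.
#' @export
read_structure <- function(source, chain = NULL, residue_range = NULL,
                           keep_hetero = FALSE, model = 1L, id = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent|cif|mmcif)$", "",
                               basename(source), ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- "structure"
  }
  is_cif <- any(startsWith(lines, "data_")) || any(grepl("^_atom_site\\.", lines))
  atoms <- if (is_cif) parse_mmcif_atoms(lines) else parse_pdb_atoms(lines)
  if (!nrow(atoms)) stop("no atom records found")

  ## model selection
  if (length(unique(atoms$model)) > 1L) {
    atoms <- atoms[atoms$model == model, , drop = FALSE]
    if (!nrow(atoms)) stop("model ", model, " not found")
  }
  ## chain selection
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!(chain %in% chains))
    stop("chain not found: '", chain, "' (present: ",
         paste(chains, collapse = ", "), ")")
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]

  ## water / hetero handling
  atoms <- atoms[atoms$resname != "HOH" & atoms$resname != "WAT", , drop = FALSE]
  atoms$het <- !(atoms$resname %in% AA3)
  if (!keep_hetero) atoms <- atoms[!atoms$het, , drop = FALSE]
  if (!nrow(atoms)) stop("no atoms left after filtering in chain ", chain)

  ## altloc resolution: per (residue, atom name) keep highest occupancy,
  ## ties broken by altloc identifier order.
  ord <- order(atoms$resno, atoms$atomname, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  dup <- duplicated(atoms[, c("resno", "atomname")])
  atoms <- atoms[!dup, , drop = FALSE]
  atoms <- atoms[order(atoms$resno, atoms$serial), , drop = FALSE]

  if (!is.null(residue_range)) {
    atoms <- atoms[atoms$resno >= residue_range[1] &
                   atoms$resno <= residue_range[2], , drop = FALSE]
    if (!nrow(atoms)) stop("no residues in requested range")
  }
  new_structure(id, chain,
                atoms[, c("resno", "resname", "atomname", "element",
                          "x", "y", "z", "het")])
}

parse_pdb_atoms <- function(lines) {
  model <- 1L
  cur_model <- 1L
  rec <- substr(lines, 1, 6)
  out <- vector("list", length(lines))
  models <- integer(length(lines))
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  ## track MODEL records
  model_ids <- rep(1L, length(lines))
  m <- 1L
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "MODEL")) {
      mm <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      m <- if (is.na(mm)) m + 1L else mm
    }
    model_ids[i] <- m
  }
  keep <- which(is_atom)
  if (!length(keep)) return(empty_atom_table())
  ln <- lines[keep]
  parse_num <- function(s, what, pos) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      bad <- keep[which(is.na(v))[1]]
      stop("malformed PDB ", what, " field at line ", bad)
    }
    v
  }
  df <- data.frame(
    serial   = seq_along(ln),
    atomname = trimws(substr(ln, 13, 16)),
    altloc   = substr(ln, 17, 17),
    resname  = trimws(substr(ln, 18, 20)),
    chain    = substr(ln, 22, 22),
    resno    = as.integer(parse_num(trimws(substr(ln, 23, 26)), "residue number")),
    x = parse_num(trimws(substr(ln, 31, 38)), "x"),
    y = parse_num(trimws(substr(ln, 39, 46)), "y"),
    z = parse_num(trimws(substr(ln, 47, 54)), "z"),
    occupancy = {
      o <- suppressWarnings(as.numeric(trimws(substr(ln, 55, 60))))
      o[is.na(o)] <- 1
      o
    },
    element  = trimws(substr(ln, 77, 78)),
    model    = model_ids[keep],
    stringsAsFactors = FALSE
  )
  df$altloc[df$altloc == " "] <- ""
  no_elem <- df$element == ""
  df$element[no_elem] <- guess_element(df$atomname[no_elem])
  df
}

parse_mmcif_atoms <- function(lines) {
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) stop("mmCIF file lacks an _atom_site loop")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  start <- max(hdr_idx) + 1L
  rows <- character(0)
  for (i in start:length(lines)) {
    l <- lines[i]
    if (startsWith(l, "#") || startsWith(l, "loop_") || startsWith(l, "_")) break
    if (nzchar(trimws(l))) rows <- c(rows, l)
  }
  if (!length(rows)) stop("empty _atom_site loop")
  toks <- strsplit(trimws(rows), "[[:space:]]+")
  nf <- length(fields)
  bad <- which(vapply(toks, length, 1L) != nf)
  if (length(bad))
    stop("malformed mmCIF atom_site row at line ", start + bad[1] - 1L)
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  g <- function(f, default = NA) if (f %in% fields) m[, f] else rep(default, nrow(m))
  df <- data.frame(
    serial   = seq_len(nrow(m)),
    atomname = gsub('"', "", g("label_atom_id")),
    altloc   = g("label_alt_id", "."),
    resname  = g("label_comp_id"),
    chain    = g("auth_asym_id", g("label_asym_id", "A")),
    resno    = as.integer(g("auth_seq_id", g("label_seq_id"))),
    x = as.numeric(g("Cartn_x")),
    y = as.numeric(g("Cartn_y")),
    z = as.numeric(g("Cartn_z")),
    occupancy = {
      o <- suppressWarnings(as.numeric(g("occupancy", "1")))
      o[is.na(o)] <- 1
      o
    },
    element  = g("type_symbol", ""),
    model    = {
      mo <- suppressWarnings(as.integer(g("pdbx_PDB_model_num", "1")))
      mo[is.na(mo)] <- 1L
      mo
    },
    stringsAsFactors = FALSE
  )
  df$altloc[df$altloc %in% c(".", "?")] <- ""
  df <- df[g("group_PDB", "ATOM") %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) || anyNA(df$resno))
    stop("malformed mmCIF coordinate or residue-number field")
  no_elem <- df$element == ""
  df$element[no_elem] <- guess_element(df$atomname[no_elem])
  df
}

guess_element <- function(atomname) {
  e <- substr(gsub("[0-9']", "", atomname), 1, 1)
  e[e == ""] <- "C"
  e
}

empty_atom_table <- function() {
  data.frame(serial = integer(), atomname = character(), altloc = character(),
             resname = character(), chain = character(), resno = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), element = character(), model = integer(),
             stringsAsFactors = FALSE)
}

#' Write a Structure (or list of Structures as models) to PDB text
#'
#' @param s a `Structure` or list of them (written as MODEL blocks).
#' @param path output file; if `NULL` the lines are returned invisibly.
#' @return character vector of PDB lines, invisibly.
#' @export
write_structure_pdb <- function(s, path = NULL) {
  one <- function(st) {
    a <- st$atoms
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
            ifelse(nchar(a$atomname) < 4, paste0(" ", a$atomname), a$atomname),
            a$resname, st$chain, a$resno, a$x, a$y, a$z, 1, 0, a$element)
  }
  if (inherits(s, "Structure")) {
    lines <- c(one(s), "END")
  } else {
    lines <- unlist(lapply(seq_along(s), function(i)
      c(sprintf("MODEL     %4d", i), one(s[[i]]), "ENDMDL")))
    lines <- c(lines, "END")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
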