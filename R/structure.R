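## The Structure container: one polypeptide chain (or domain slice) as a
## flat atom table.  All higher-level code goes through the accessors below
## rather than poking at the data frame directly.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- stats::setNames(AA3, AA1)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a Structure from an atom table
#'
#' @param id accession or label.
#' @param chain chain identifier.
#' @param atoms data.frame with columns `resno` (integer), `resname`
#'   (3-letter code), `atomname`, `element`, `x`, `y`, `z` and optionally
#'   `het` (logical flag for non-standard residues).
#' @return object of class `Structure`.
#' @export
new_structure <- function(id, chain, atoms) {
  required <- c("resno", "resname", "atomname", "element", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (!nrow(atoms)) stop("empty atom table")
  if (is.null(atoms$het))
    atoms$het <- !(atoms$resname %in% AA3)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  rn <- unique(atoms$resno)
  if (is.unsorted(rn, strictly = TRUE))
    stop("residue numbers must be strictly increasing within the chain")
  rownames(atoms) <- NULL
  structure(list(id = id, chain = chain, atoms = atoms), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure %s chain %s: %d residues, %d atoms\n",
              x$id, x$chain, nrow(structure_residues(x)), nrow(x$atoms)))
  invisible(x)
}

#' Residue table of a Structure
#'
#' @param s a `Structure`.
#' @return data.frame with one row per residue: `resno`, `resname`, `het`.
#' @export
structure_residues <- function(s) {
  a <- s$atoms
  keep <- !duplicated(a$resno)
  data.frame(resno = a$resno[keep], resname = a$resname[keep],
             het = a$het[keep], stringsAsFactors = FALSE)
}

#' One-letter amino-acid sequence of a Structure
#'
#' Heteroresidues are rendered as "X".
#'
#' @param s a `Structure`.
#' @return single character string.
#' @export
structure_sequence <- function(s) {
  r <- structure_residues(s)
  letters1 <- AA1[r$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

## Coordinate matrix of selected atoms (all atoms by default).
structure_coords <- function(s, sel = NULL) {
  a <- s$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

## Atom rows of one residue (by author residue number).
residue_atoms <- function(s, resno) {
  s$atoms[s$atoms$resno == resno, , drop = FALSE]
}

## Heavy (non-hydrogen) atom subset.
heavy_atoms <- function(atoms) {
  atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
}

## Sidechain heavy atoms of a residue; for glycine the CA is returned so a
## distance to "the sidechain" is always defined.
sidechain_atoms <- function(s, resno) {
  at <- heavy_atoms(residue_atoms(s, resno))
  sc <- at[!(at$atomname %in% BACKBONE_ATOMS), , drop = FALSE]
  if (!nrow(sc)) sc <- at[at$atomname == "CA", , drop = FALSE]
  sc
}

## Replace the coordinates of one residue's named atoms.
set_residue_coords <- function(s, resno, atomnames, xyz) {
  idx <- which(s$atoms$resno == resno)
  m <- match(atomnames, s$atoms$atomname[idx])
  if (anyNA(m)) stop("atom(s) not present in residue ", resno)
  s$atoms[idx[m], c("x", "y", "z")] <- xyz
  s
}

## Apply a rigid transform to a whole Structure.
transform_structure <- function(s, rotation, translation) {
  xyz <- apply_transform(structure_coords(s), rotation, translation)
  s$atoms[, c("x", "y", "z")] <- xyz
  s
}
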