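## Sequence alignment, domain superposition and PPIA-reference residue
## mapping.  Cross-isoform semantics always go through an ActiveSiteMap;
## raw author residue numbers are never compared between structures.

#' PPIA reference positions of the active surface
#'
#' The 16 PPIA positions used as the family-wide reference frame: the
#' catalytic arginine (55), the S1' pocket (60, 61, 113, 122, 126), the
#' cyclosporin-discriminating position 121, and the S2-pocket rim with its
#' gatekeepers 1/2/3 at 73, 82 and 103.
#' @export
PPIA_REFERENCE_POSITIONS <- c(55L, 60L, 61L, 63L, 73L, 81L, 82L, 101L,
                              103L, 107L, 110L, 111L, 113L, 121L, 122L, 126L)

#' @rdname PPIA_REFERENCE_POSITIONS
#' @export
GATEKEEPER_POSITIONS <- c(gatekeeper1 = 73L, gatekeeper2 = 82L,
                          gatekeeper3 = 103L)

S1PRIME_POSITIONS <- c(60L, 61L, 113L, 122L, 126L)
S2_RIM_POSITIONS <- c(73L, 81L, 82L, 103L, 107L, 110L, 111L)

#' Globally align the sequences of two structures
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (BLOSUM62), returning the residue-index pairing and summary identities.
#'
#' @param a,b `Structure` objects.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return a `DomainAlignment`: list with `pairs` (two-column matrix of
#'   residue indices into a and b, strictly increasing in both columns),
#'   `identity_fraction` (over aligned non-gap columns) and `coverage`
#'   (fraction of a's residues aligned).
#' @export
align_sequences <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  if (!nrow(a$atoms) || !nrow(b$atoms)) stop("empty structure")
  sa <- structure_sequence(a)
  sb <- structure_sequence(b)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "global", substitutionMatrix = data_env$BLOSUM62,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  pairs <- matrix(integer(0), ncol = 2)
  n_id <- 0L; n_col <- 0L
  pl <- vector("list", length(pat))
  for (k in seq_along(pat)) {
    ga <- pat[k] == "-"; gb <- sub[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      pl[[k]] <- c(ia, ib)
      n_col <- n_col + 1L
      if (pat[k] == sub[k]) n_id <- n_id + 1L
    }
  }
  pairs <- do.call(rbind, pl[!vapply(pl, is.null, TRUE)])
  structure(list(
    pairs = pairs,
    identity_fraction = if (n_col) n_id / n_col else 0,
    coverage = n_col / nchar(sa)
  ), class = "DomainAlignment")
}

#' Identity alignment of a structure with itself
#' @param s a `Structure`.
#' @return a `DomainAlignment` pairing every residue with itself.
#' @export
identity_alignment <- function(s) {
  n <- nrow(structure_residues(s))
  structure(list(pairs = cbind(seq_len(n), seq_len(n)),
                 identity_fraction = 1, coverage = 1),
            class = "DomainAlignment")
}

#' Superpose two domains over aligned residues
#'
#' Matches atoms shared by both residues of every aligned pair (by atom
#' name; heavy atoms only) and delegates to [kabsch_superpose()].
#'
#' @param a,b `Structure` objects.
#' @param alignment a `DomainAlignment` of a vs b.
#' @param atom_set `"all"` for all shared heavy atoms, `"ca"` for CA only.
#' @return a `Superposition` (transform of b onto a).
#' @export
superpose_domains <- function(a, b, alignment, atom_set = c("all", "ca")) {
  atom_set <- match.arg(atom_set)
  if (is.null(alignment$pairs) || !nrow(alignment$pairs))
    stop("empty alignment")
  ra <- structure_residues(a)$resno
  rb <- structure_residues(b)$resno
  ca_list <- list(); cb_list <- list()
  for (k in seq_len(nrow(alignment$pairs))) {
    ia <- alignment$pairs[k, 1]; ib <- alignment$pairs[k, 2]
    at_a <- heavy_atoms(residue_atoms(a, ra[ia]))
    at_b <- heavy_atoms(residue_atoms(b, rb[ib]))
    if (atom_set == "ca") {
      at_a <- at_a[at_a$atomname == "CA", , drop = FALSE]
      at_b <- at_b[at_b$atomname == "CA", , drop = FALSE]
    }
    shared <- intersect(at_a$atomname, at_b$atomname)
    if (!length(shared)) next
    ma <- at_a[match(shared, at_a$atomname), , drop = FALSE]
    mb <- at_b[match(shared, at_b$atomname), , drop = FALSE]
    ca_list[[k]] <- as.matrix(ma[, c("x", "y", "z")])
    cb_list[[k]] <- as.matrix(mb[, c("x", "y", "z")])
  }
  ca <- do.call(rbind, ca_list)
  cb <- do.call(rbind, cb_list)
  if (is.null(ca) || nrow(ca) < 3L)
    stop("fewer than 3 matchable atoms across the alignment")
  kabsch_superpose(ca, cb)
}

#' Map PPIA reference positions onto a target structure
#'
#' Every reference position of PPIA is carried through the alignment to the
#' corresponding target residue; positions falling on alignment gaps are
#' flagged `"unmapped"`.
#'
#' @param target target `Structure`.
#' @param ref PPIA-numbered reference `Structure`.
#' @param alignment `DomainAlignment` of ref vs target.
#' @param positions reference positions (default the 16 active-surface
#'   positions).
#' @return an `ActiveSiteMap`: data.frame with columns `ref_pos`,
#'   `ref_resname`, `target_resname`, `target_resno`, `mapped`.
#' @export
map_active_site <- function(target, ref, alignment,
                            positions = PPIA_REFERENCE_POSITIONS) {
  rr <- structure_residues(ref)
  rt <- structure_residues(target)
  out <- data.frame(ref_pos = positions,
                    ref_resname = NA_character_,
                    target_resname = NA_character_,
                    target_resno = NA_integer_,
                    mapped = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(positions)) {
    i_ref <- which(rr$resno == positions[k])
    if (!length(i_ref))
      stop("reference structure lacks residue at PPIA position ",
           positions[k])
    out$ref_resname[k] <- rr$resname[i_ref]
    hit <- which(alignment$pairs[, 1] == i_ref)
    if (length(hit)) {
      i_tgt <- alignment$pairs[hit[1], 2]
      out$target_resname[k] <- rt$resname[i_tgt]
      out$target_resno[k] <- rt$resno[i_tgt]
      out$mapped[k] <- TRUE
    }
  }
  class(out) <- c("ActiveSiteMap", "data.frame")
  out
}

## Look up one mapped position; errors or returns NULL if unmapped.
map_lookup <- function(map, ref_pos, required = TRUE) {
  row <- map[map$ref_pos == ref_pos, , drop = FALSE]
  if (!nrow(row) || !row$mapped[1]) {
    if (required) stop("PPIA reference position ", ref_pos,
                       " is unmapped in the target")
    return(NULL)
  }
  row[1, ]
}

#' Classify cyclosporin-binding competence from position 121
#'
#' Tryptophan or histidine at the PPIA-121-equivalent position is
#' permissive for cyclosporin binding; tyrosine or glutamate (and, by
#' default, any other residue) is non-permissive.
#'
#' @param map an `ActiveSiteMap`.
#' @return list with `label` (`"permissive"`/`"non-permissive"`), `residue`
#'   and `note` (`"novel residue"` when outside the four known identities).
#' @export
classify_position121 <- function(map) {
  row <- map_lookup(map, 121L)
  res <- row$target_resname
  known_perm <- c("TRP", "HIS")
  known_nonperm <- c("TYR", "GLU")
  list(
    label = if (res %in% known_perm) "permissive" else "non-permissive",
    residue = res,
    note = if (res %in% c(known_perm, known_nonperm)) NA_character_
           else "novel residue"
  )
}

## PPIA loop windows (author numbering).
LOOP_WINDOWS <- list(b1b2 = c(11L, 16L), a1b3 = c(41L, 50L),
                     a2b8 = c(146L, 155L))

#' Classify the three structurally diverse loops of a cyclophilin domain
#'
#' beta1-beta2 (PPIA Ala11-Pro16): `"deleted"` iff >= 2 reference residues
#' in the window are unaligned.  alpha1-beta3 (Thr41-Gly50): target loop
#' length vs PPIA gives `"PPIA-class"`/`"short"`/`"long"`.  alpha2-beta8
#' (Gly146-Lys155): backbone RMSD of the loop after whole-domain
#' superposition, `"standard"` iff <= `rmsd_threshold`.
#'
#' @param target,ref `Structure`s (ref PPIA-numbered).
#' @param alignment `DomainAlignment` of ref vs target.
#' @param rmsd_threshold alpha2-beta8 cutoff in Angstrom (default 1.5).
#' @return list with `b1b2`, `a1b3`, `a2b8` labels (a loop window entirely
#'   unaligned yields `"unclassifiable"`).
#' @export
classify_loops <- function(target, ref, alignment, rmsd_threshold = 1.5) {
  rr <- structure_residues(ref)
  rt <- structure_residues(target)
  win_idx <- function(w) which(rr$resno >= w[1] & rr$resno <= w[2])
  aligned_b <- function(idx_a) {
    m <- match(idx_a, alignment$pairs[, 1])
    alignment$pairs[m[!is.na(m)], 2]
  }

  ## beta1-beta2: deletion
  ia <- win_idx(LOOP_WINDOWS$b1b2)
  n_gap <- sum(!(ia %in% alignment$pairs[, 1]))
  b1b2 <- if (length(ia) == 0) "unclassifiable"
          else if (n_gap >= 2) "deleted" else "full-length"

  ## alpha1-beta3: loop length relative to PPIA
  ia <- win_idx(LOOP_WINDOWS$a1b3)
  ib <- aligned_b(ia)
  a1b3 <- if (!length(ib)) "unclassifiable" else {
    ## target residues spanned between the outermost aligned columns,
    ## counting insertions within the window
    len_ref <- length(ia)
    flank_lo <- suppressWarnings(
      max(which(rr$resno < LOOP_WINDOWS$a1b3[1] &
                seq_len(nrow(rr)) %in% alignment$pairs[, 1])))
    flank_hi_set <- which(rr$resno > LOOP_WINDOWS$a1b3[2] &
                          seq_len(nrow(rr)) %in% alignment$pairs[, 1])
    if (!is.finite(flank_lo) || !length(flank_hi_set)) "unclassifiable"
    else {
      flank_hi <- min(flank_hi_set)
      tb_lo <- alignment$pairs[match(flank_lo, alignment$pairs[, 1]), 2]
      tb_hi <- alignment$pairs[match(flank_hi, alignment$pairs[, 1]), 2]
      len_tgt <- tb_hi - tb_lo - 1L
      if (len_tgt == len_ref) "PPIA-class"
      else if (len_tgt < len_ref) "short" else "long"
    }
  }

  ## alpha2-beta8: conformational class after whole-domain superposition
  ia <- win_idx(LOOP_WINDOWS$a2b8)
  ib <- aligned_b(ia)
  a2b8 <- if (!length(ib)) "unclassifiable" else {
    sup <- superpose_domains(ref, target, alignment, atom_set = "all")
    bb <- c("N", "CA", "C", "O")
    pa <- list(); pb <- list()
    for (k in seq_along(ia)) {
      m <- match(ia[k], alignment$pairs[, 1])
      if (is.na(m)) next
      at_a <- residue_atoms(ref, rr$resno[ia[k]])
      at_b <- residue_atoms(target, rt$resno[alignment$pairs[m, 2]])
      shared <- intersect(intersect(at_a$atomname, bb), at_b$atomname)
      if (!length(shared)) next
      pa[[k]] <- as.matrix(at_a[match(shared, at_a$atomname),
                                c("x", "y", "z")])
      pb[[k]] <- as.matrix(at_b[match(shared, at_b$atomname),
                                c("x", "y", "z")])
    }
    A <- do.call(rbind, pa); B <- do.call(rbind, pb)
    if (is.null(A) || !nrow(A)) "unclassifiable" else {
      Bt <- apply_transform(B, sup$rotation, sup$translation)
      rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
      if (rmsd <= rmsd_threshold) "standard" else "alternate"
    }
  }

  list(b1b2 = b1b2, a1b3 = a1b3, a2b8 = a2b8)
}
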