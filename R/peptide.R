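## Tetrapeptide library and pose construction.  Test peptides have the
## general form P3-P2-Gly-Pro: the Gly-Pro dipeptide is the anchored
## isomerase recognition element, and P2/P3 probe the S2 pocket.

#' Construct one test peptide
#'
#' @param p3,p2 one-letter amino-acid codes for the P3 and P2 positions.
#' @return a `Peptide`: list with `p3`, `p2`, `p1` ("G"), `p1prime` ("P")
#'   and `sequence` (e.g. `"EFGP"`).
#' @export
peptide <- function(p3, p2) {
  p3 <- toupper(p3); p2 <- toupper(p2)
  if (!(p3 %in% AA1) || !(p2 %in% AA1))
    stop("P3 and P2 must be standard one-letter amino-acid codes")
  structure(list(p3 = p3, p2 = p2, p1 = "G", p1prime = "P",
                 sequence = paste0(p3, p2, "G", "P")),
            class = "Peptide")
}

#' Generate the X-Z-Gly-Pro peptide library
#'
#' Every (P3, P2) combination over the alphabet exactly once, in
#' deterministic lexicographic order (P3 outer, P2 inner).  The standard
#' 20-letter alphabet yields the full 400-peptide library.
#'
#' @param alphabet character vector of one-letter codes.
#' @return list of [peptide()] objects of length `length(alphabet)^2`.
#' @export
generate_library <- function(alphabet = sort(unname(AA1))) {
  alphabet <- toupper(alphabet)
  if (!length(alphabet)) stop("empty amino-acid alphabet")
  if (!all(alphabet %in% AA1))
    stop("non-standard letters in alphabet: ",
         paste(setdiff(alphabet, AA1), collapse = ", "))
  alphabet <- sort(unique(alphabet))
  out <- vector("list", length(alphabet)^2)
  k <- 0L
  for (p3 in alphabet) for (p2 in alphabet) {
    k <- k + 1L
    out[[k]] <- peptide(p3, p2)
  }
  out
}

#' Bundle a receptor with its bound Gly-Pro template ligand
#'
#' @param receptor template receptor `Structure`.
#' @param ligand `Structure` holding the bound dipeptide; must contain
#'   consecutive Gly and Pro residues.
#' @param map `ActiveSiteMap` of the template receptor.
#' @return a `TemplateComplex`.
#' @export
template_complex <- function(receptor, ligand, map) {
  res <- structure_residues(ligand)
  ok <- FALSE
  if (nrow(res) >= 2) {
    for (i in seq_len(nrow(res) - 1L))
      if (res$resname[i] == "GLY" && res$resname[i + 1] == "PRO") ok <- TRUE
  }
  if (!ok) stop("template lacks Gly-Pro ligand")
  structure(list(receptor = receptor, ligand = ligand, map = map),
            class = "TemplateComplex")
}

## Gly-Pro residue numbers within a template ligand.
template_glypro <- function(ligand) {
  res <- structure_residues(ligand)
  for (i in seq_len(nrow(res) - 1L))
    if (res$resname[i] == "GLY" && res$resname[i + 1] == "PRO")
      return(res$resno[c(i, i + 1L)])
  stop("template lacks Gly-Pro ligand")
}

#' Place a tetrapeptide into a receptor from the bound-dipeptide template
#'
#' Builds the tetrapeptide with ideal internal geometry (P2/P3 extended),
#' rigid-superposes its Gly-Pro onto the template's bound Gly-Pro after
#' bringing the template into the receptor frame (superposition over the CA
#' atoms of commonly mapped active-site positions), records the anchor
#' reference coordinates for the tether, and sets the receptor's catalytic
#' arginine to the template-aligned rotamer.
#'
#' @param pep a [peptide()].
#' @param receptor receptor `Structure`.
#' @param template a [template_complex()].
#' @param map `ActiveSiteMap` of the receptor.
#' @return a `PeptidePose`: list with `peptide`, `structure` (tetrapeptide
#'   coordinates), `receptor` (with repositioned catalytic arginine),
#'   `anchor_idx`, `anchor_reference`, `torsions` (flexible torsion set)
#'   and `clash` flag.
#' @export
place_peptide <- function(pep, receptor, template, map) {
  if (!inherits(template, "TemplateComplex"))
    stop("template must be a TemplateComplex")
  gp <- template_glypro(template$ligand)

  ## bring template into the receptor frame via shared active-site CAs
  shared <- merge(map[map$mapped, c("ref_pos", "target_resno")],
                  template$map[template$map$mapped,
                               c("ref_pos", "target_resno")],
                  by = "ref_pos", suffixes = c("_rec", "_tpl"))
  ca_of <- function(s, resno) {
    at <- s$atoms[s$atoms$resno == resno & s$atoms$atomname == "CA", ]
    if (!nrow(at)) return(NULL)
    c(at$x[1], at$y[1], at$z[1])
  }
  pr <- list(); pt <- list()
  for (k in seq_len(nrow(shared))) {
    a <- ca_of(receptor, shared$target_resno_rec[k])
    b <- ca_of(template$receptor, shared$target_resno_tpl[k])
    if (!is.null(a) && !is.null(b)) { pr[[k]] <- a; pt[[k]] <- b }
  }
  pr <- do.call(rbind, pr); pt <- do.call(rbind, pt)
  if (is.null(pr) || nrow(pr) < 3)
    stop("fewer than 3 shared mapped active-site positions ",
         "between receptor and template")
  sup <- kabsch_superpose(pr, pt)
  lig <- transform_structure(template$ligand, sup$rotation, sup$translation)

  ## build the tetrapeptide, extended at P2/P3
  pepstr <- build_chain(c(pep$p3, pep$p2, "G", "P"),
                        phi = -139, psi = 135,
                        id = pep$sequence, chain = "P")

  ## superpose the built Gly-Pro onto the template's
  lig_gly <- heavy_atoms(residue_atoms(lig, gp[1]))
  lig_pro <- heavy_atoms(residue_atoms(lig, gp[2]))
  pp_gly <- heavy_atoms(residue_atoms(pepstr, 3L))
  pp_pro <- heavy_atoms(residue_atoms(pepstr, 4L))
  m_gly <- intersect(pp_gly$atomname, lig_gly$atomname)
  m_pro <- intersect(pp_pro$atomname, lig_pro$atomname)
  A <- rbind(as.matrix(lig_gly[match(m_gly, lig_gly$atomname),
                               c("x", "y", "z")]),
             as.matrix(lig_pro[match(m_pro, lig_pro$atomname),
                               c("x", "y", "z")]))
  B <- rbind(as.matrix(pp_gly[match(m_gly, pp_gly$atomname),
                              c("x", "y", "z")]),
             as.matrix(pp_pro[match(m_pro, pp_pro$atomname),
                              c("x", "y", "z")]))
  if (nrow(A) < 3) stop("too few matchable Gly-Pro anchor atoms")
  sup2 <- kabsch_superpose(A, B)
  pepstr <- transform_structure(pepstr, sup2$rotation, sup2$translation)

  ## anchor: Gly-Pro heavy atoms, tethered to their placed position
  anchor_idx <- which(pepstr$atoms$resno %in% c(3L, 4L) &
                      pepstr$atoms$element != "H")
  anchor_reference <- structure_coords(pepstr, anchor_idx)

  ## catalytic arginine onto the template rotamer
  rec <- receptor
  r55 <- map_lookup(map, 55L, required = FALSE)
  t55 <- map_lookup(template$map, 55L, required = FALSE)
  if (!is.null(r55) && !is.null(t55) && r55$target_resname == "ARG" &&
      t55$target_resname == "ARG") {
    chis <- measure_chis(template$receptor, t55$target_resno)
    if (!anyNA(chis)) rec <- rebuild_sidechain(rec, r55$target_resno, chis)
  }

  ## flexible torsion set of the peptide
  torsions <- peptide_torsions(pepstr, anchor_idx)

  ## initial-clash warning (MC resolves soft clashes)
  p23 <- structure_coords(pepstr,
                          which(pepstr$atoms$resno %in% c(1L, 2L)))
  rc <- structure_coords(rec)
  d2 <- outer(rowSums(p23^2), rowSums(rc^2), `+`) - 2 * (p23 %*% t(rc))
  clash <- min(d2) < 1.5^2
  if (clash)
    warning("initial P2/P3 placement clashes with the receptor for ",
            pep$sequence, " (Monte Carlo will resolve)")

  structure(list(peptide = pep, structure = pepstr, receptor = rec,
                 anchor_idx = anchor_idx,
                 anchor_reference = anchor_reference,
                 torsions = torsions, clash = clash),
            class = "PeptidePose")
}

## Flexible torsions of a placed tetrapeptide: sidechain chis of P3 (res 1)
## and P2 (res 2), plus backbone psi(P3), phi(P2), psi(P2).  The moving
## side of each rotation is the side that does not contain the anchored
## Gly-Pro atoms.
peptide_torsions <- function(pepstr, anchor_idx) {
  a <- pepstr$atoms
  bonds <- structure_bonds(pepstr)
  adj <- bond_adjacency(bonds, nrow(a))
  gi <- function(resno, an) {
    i <- which(a$resno == resno & a$atomname == an)
    if (!length(i)) NA_integer_ else i[1]
  }
  out <- list()
  add <- function(name, class, quad_idx) {
    if (anyNA(quad_idx)) return()
    moving <- torsion_moving_set(adj, quad_idx[2], quad_idx[3],
                                 keep_fixed = anchor_idx)
    if (!length(moving)) return()
    chi0 <- dihedral_angle(
      as.numeric(a[quad_idx[1], c("x", "y", "z")]),
      as.numeric(a[quad_idx[2], c("x", "y", "z")]),
      as.numeric(a[quad_idx[3], c("x", "y", "z")]),
      as.numeric(a[quad_idx[4], c("x", "y", "z")]))
    out[[length(out) + 1L]] <<- list(name = name, class = class,
                                     ai = quad_idx[2], aj = quad_idx[3],
                                     ref_d = quad_idx[1], ref_x = quad_idx[4],
                                     moving = moving, chi0 = chi0)
  }
  for (resno in c(1L, 2L)) {
    rn <- a$resname[a$resno == resno][1]
    quads <- chi_quadruples(rn)
    for (k in seq_along(quads)) {
      q <- vapply(quads[[k]], function(an) gi(resno, an), 1L)
      add(sprintf("chi%d_P%d", k, 4L - resno), "sidechain", q)
    }
  }
  add("psi_P3", "backbone",
      c(gi(1L, "N"), gi(1L, "CA"), gi(1L, "C"), gi(2L, "N")))
  add("phi_P2", "backbone",
      c(gi(1L, "C"), gi(2L, "N"), gi(2L, "CA"), gi(2L, "C")))
  add("psi_P2", "backbone",
      c(gi(2L, "N"), gi(2L, "CA"), gi(2L, "C"), gi(3L, "N")))
  out
}

#' @export
print.PeptidePose <- function(x, ...) {
  cat(sprintf("PeptidePose %s: %d atoms, %d flexible torsions%s\n",
              x$peptide$sequence, nrow(x$structure$atoms),
              length(x$torsions),
              if (isTRUE(x$clash)) " (initial clash)" else ""))
  invisible(x)
}
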