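## Idealised amino-acid geometry and the coarse physical typing used by the
## scoring model.  Sidechains are described in internal coordinates: each
## atom is placed from (parent, angle-ref, dihedral-ref) with a bond length,
## bond angle and a dihedral that is either fixed or tied to a chi angle
## (dihedral = chi_k + offset).  Bond lengths/angles are standard idealised
## values; ring geometries are near-planar approximations, which is adequate
## for a model potential on an internal energy scale.

sc_row <- function(name, parent, angref, dihref, bond, angle,
                   chi = NA_integer_, dih = 180) {
  data.frame(name = name, parent = parent, angref = angref, dihref = dihref,
             bond = bond, angle = angle, chi = chi, dih = dih,
             stringsAsFactors = FALSE)
}

## First sidechain atom: torsion C-N-CA-CB fixed for L-amino acids.
cb_row <- function(angle = 110.5)
  sc_row("CB", "CA", "N", "C", 1.53, angle, NA, 122.6)

SIDECHAIN_TEMPLATES <- list(
  GLY = NULL,
  ALA = cb_row(),
  SER = rbind(cb_row(),
              sc_row("OG",  "CB", "CA", "N", 1.42, 110.8, 1L, 0)),
  CYS = rbind(cb_row(),
              sc_row("SG",  "CB", "CA", "N", 1.81, 113.8, 1L, 0)),
  THR = rbind(cb_row(),
              sc_row("OG1", "CB", "CA", "N", 1.43, 109.6, 1L, 0),
              sc_row("CG2", "CB", "CA", "N", 1.52, 110.5, 1L, -120)),
  VAL = rbind(cb_row(),
              sc_row("CG1", "CB", "CA", "N", 1.52, 110.5, 1L, 0),
              sc_row("CG2", "CB", "CA", "N", 1.52, 110.5, 1L, 120)),
  LEU = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.53, 116.3, 1L, 0),
              sc_row("CD1", "CG", "CB", "CA", 1.52, 110.7, 2L, 0),
              sc_row("CD2", "CG", "CB", "CA", 1.52, 110.7, 2L, 120)),
  ILE = rbind(cb_row(),
              sc_row("CG1", "CB", "CA", "N",  1.53, 110.4, 1L, 0),
              sc_row("CG2", "CB", "CA", "N",  1.52, 110.5, 1L, -120),
              sc_row("CD1", "CG1", "CB", "CA", 1.51, 113.8, 2L, 0)),
  MET = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1L, 0),
              sc_row("SD",  "CG", "CB", "CA", 1.81, 112.7, 2L, 0),
              sc_row("CE",  "SD", "CG", "CB", 1.79, 100.2, 3L, 0)),
  PRO = rbind(sc_row("CB", "CA", "N", "C", 1.54, 104.7, NA, 118.8),
              sc_row("CG", "CB", "CA", "N",  1.54, 105.1, NA, 23.8),
              sc_row("CD", "CG", "CB", "CA", 1.54, 105.1, NA, 0)),
  PHE = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.50, 113.9, 1L, 0),
              sc_row("CD1", "CG", "CB", "CA", 1.39, 120.8, 2L, 0),
              sc_row("CD2", "CG", "CB", "CA", 1.39, 120.8, 2L, 180),
              sc_row("CE1", "CD1", "CG", "CB", 1.39, 120.8, NA, 180),
              sc_row("CE2", "CD2", "CG", "CB", 1.39, 120.8, NA, 180),
              sc_row("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, NA, 0)),
  TYR = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.51, 113.9, 1L, 0),
              sc_row("CD1", "CG", "CB", "CA", 1.39, 120.8, 2L, 0),
              sc_row("CD2", "CG", "CB", "CA", 1.39, 120.8, 2L, 180),
              sc_row("CE1", "CD1", "CG", "CB", 1.39, 121.2, NA, 180),
              sc_row("CE2", "CD2", "CG", "CB", 1.39, 121.2, NA, 180),
              sc_row("CZ",  "CE1", "CD1", "CG", 1.38, 119.6, NA, 0),
              sc_row("OH",  "CZ", "CE1", "CD1", 1.38, 119.9, NA, 180)),
  TRP = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.50, 113.6, 1L, 0),
              sc_row("CD1", "CG", "CB", "CA", 1.37, 126.9, 2L, 0),
              sc_row("CD2", "CG", "CB", "CA", 1.43, 126.6, 2L, 180),
              sc_row("NE1", "CD1", "CG", "CB", 1.38, 110.2, NA, 180),
              sc_row("CE2", "CD2", "CG", "CB", 1.41, 107.2, NA, 180),
              sc_row("CE3", "CD2", "CG", "CB", 1.40, 133.9, NA, 0),
              sc_row("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, NA, 180),
              sc_row("CZ3", "CE3", "CD2", "CG", 1.39, 118.6, NA, 180),
              sc_row("CH2", "CZ2", "CE2", "CD2", 1.38, 119.8, NA, 0)),
  HIS = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.50, 113.8, 1L, 0),
              sc_row("ND1", "CG", "CB", "CA", 1.38, 122.7, 2L, 0),
              sc_row("CD2", "CG", "CB", "CA", 1.36, 131.2, 2L, 180),
              sc_row("CE1", "ND1", "CG", "CB", 1.32, 109.3, NA, 180),
              sc_row("NE2", "CD2", "CG", "CB", 1.37, 107.2, NA, 180)),
  ASP = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.52, 112.6, 1L, 0),
              sc_row("OD1", "CG", "CB", "CA", 1.25, 118.4, 2L, 0),
              sc_row("OD2", "CG", "CB", "CA", 1.25, 118.4, 2L, 180)),
  ASN = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.52, 112.7, 1L, 0),
              sc_row("OD1", "CG", "CB", "CA", 1.23, 120.8, 2L, 0),
              sc_row("ND2", "CG", "CB", "CA", 1.33, 116.5, 2L, 180)),
  GLU = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1L, 0),
              sc_row("CD",  "CG", "CB", "CA", 1.52, 112.6, 2L, 0),
              sc_row("OE1", "CD", "CG", "CB", 1.25, 118.4, 3L, 0),
              sc_row("OE2", "CD", "CG", "CB", 1.25, 118.4, 3L, 180)),
  GLN = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1L, 0),
              sc_row("CD",  "CG", "CB", "CA", 1.52, 112.7, 2L, 0),
              sc_row("OE1", "CD", "CG", "CB", 1.23, 120.8, 3L, 0),
              sc_row("NE2", "CD", "CG", "CB", 1.33, 116.5, 3L, 180)),
  LYS = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1L, 0),
              sc_row("CD",  "CG", "CB", "CA", 1.52, 111.3, 2L, 0),
              sc_row("CE",  "CD", "CG", "CB", 1.52, 111.3, 3L, 0),
              sc_row("NZ",  "CE", "CD", "CG", 1.49, 111.9, 4L, 0)),
  ARG = rbind(cb_row(),
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1L, 0),
              sc_row("CD",  "CG", "CB", "CA", 1.52, 111.3, 2L, 0),
              sc_row("NE",  "CD", "CG", "CB", 1.46, 112.0, 3L, 0),
              sc_row("CZ",  "NE", "CD", "CG", 1.33, 124.2, 4L, 0),
              sc_row("NH1", "CZ", "NE", "CD", 1.33, 120.0, NA, 0),
              sc_row("NH2", "CZ", "NE", "CD", 1.33, 120.0, NA, 180))
)

## Number of sampled chi angles per residue (Pro's ring is kept rigid).
N_CHI <- c(GLY = 0L, ALA = 0L, SER = 1L, CYS = 1L, THR = 1L, VAL = 1L,
           LEU = 2L, ILE = 2L, MET = 3L, PRO = 0L, PHE = 2L, TYR = 2L,
           TRP = 2L, HIS = 2L, ASP = 2L, ASN = 2L, GLU = 3L, GLN = 3L,
           LYS = 4L, ARG = 4L)

## chi-angle atom quadruples (torsion a-b-c-d; axis is b-c).
chi_quadruples <- function(resname) {
  tpl <- SIDECHAIN_TEMPLATES[[resname]]
  n <- N_CHI[[resname]]
  if (is.null(tpl) || n == 0L) return(list())
  out <- vector("list", n)
  for (k in seq_len(n)) {
    row <- tpl[!is.na(tpl$chi) & tpl$chi == k & tpl$dih == 0, ][1, ]
    out[[k]] <- c(row$dihref, row$angref, row$parent, row$name)
  }
  out
}

## Formal sidechain charge at pH 7 (His treated as neutral).
FORMAL_CHARGE <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L, HIS = 0L)

formal_charge <- function(resname) {
  ch <- FORMAL_CHARGE[resname]
  ch[is.na(ch)] <- 0L
  unname(ch)
}

## Coarse partial charges for the Coulomb term, keyed "RES:ATOM" with a
## backbone default.  Ionisable groups carry their formal charge spread
## over the terminal heavy atoms; polar groups carry a local dipole.
BACKBONE_CHARGE <- c(N = -0.35, CA = 0.10, C = 0.45, O = -0.45, OXT = -0.45)

SIDECHAIN_CHARGE <- c(
  "ASP:CG" = 0.50, "ASP:OD1" = -0.75, "ASP:OD2" = -0.75,
  "GLU:CD" = 0.50, "GLU:OE1" = -0.75, "GLU:OE2" = -0.75,
  "LYS:CE" = 0.30, "LYS:NZ" = 0.70,
  "ARG:NE" = -0.10, "ARG:CZ" = 0.40, "ARG:NH1" = 0.35, "ARG:NH2" = 0.35,
  "HIS:CG" = 0.10, "HIS:ND1" = -0.30, "HIS:CD2" = 0.20,
  "HIS:CE1" = 0.30, "HIS:NE2" = -0.30,
  "SER:CB" = 0.35, "SER:OG" = -0.35,
  "THR:CB" = 0.35, "THR:OG1" = -0.35,
  "TYR:CZ" = 0.35, "TYR:OH" = -0.35,
  "CYS:CB" = 0.20, "CYS:SG" = -0.20,
  "ASN:CB" = 0.30, "ASN:CG" = 0.50, "ASN:OD1" = -0.50, "ASN:ND2" = -0.30,
  "GLN:CG" = 0.30, "GLN:CD" = 0.50, "GLN:OE1" = -0.50, "GLN:NE2" = -0.30,
  "TRP:CD1" = 0.15, "TRP:CE2" = 0.15, "TRP:NE1" = -0.30,
  "MET:CG" = 0.05, "MET:CE" = 0.05, "MET:SD" = -0.10
)

atom_charge <- function(resname, atomname) {
  q <- BACKBONE_CHARGE[atomname]
  key <- paste0(resname, ":", atomname)
  qs <- SIDECHAIN_CHARGE[key]
  q[!is.na(qs)] <- qs[!is.na(qs)]
  q[is.na(q)] <- 0
  unname(q)
}

## Hydrogen-bond donor heavy atoms (value = supporting "base" atom used for
## the donor angle; structures lack hydrogens) and acceptor atoms.
HB_DONORS <- list(
  backbone = c(N = "CA"),          # except proline, handled by caller
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  CYS = c(SG = "CB"), TRP = c(NE1 = "CD1"), HIS = c(NE2 = "CD2"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  LYS = c(NZ = "CE"), ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ")
)

HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = "ND1"
)

## Lennard-Jones parameters per element: Rmin/2 (Angstrom) and well depth
## epsilon (kcal/mol); pairs combine as Rmin_ij = r1+r2, eps = sqrt(e1*e2).
LJ_PARAMS <- list(
  C = c(rmin_half = 1.90, eps = 0.08),
  N = c(rmin_half = 1.80, eps = 0.17),
  O = c(rmin_half = 1.70, eps = 0.21),
  S = c(rmin_half = 2.00, eps = 0.25)
)

lj_for_element <- function(element) {
  e <- ifelse(element %in% names(LJ_PARAMS), element, "C")
  m <- do.call(rbind, LJ_PARAMS[e])
  list(rmin_half = unname(m[, "rmin_half"]), eps = unname(m[, "eps"]))
}

## Per-atom physics annotation for a Structure's atom table: LJ parameters,
## partial charge, donor base index (-1 if not a donor) and acceptor flag.
## Indices are 0-based row indices into `atoms` (for the C++ kernel).
annotate_atoms <- function(atoms) {
  lj <- lj_for_element(atoms$element)
  q <- atom_charge(atoms$resname, atoms$atomname)
  n <- nrow(atoms)
  don_base <- rep(-1L, n)
  is_acc <- logical(n)
  for (i in seq_len(n)) {
    rn <- atoms$resname[i]; an <- atoms$atomname[i]
    base <- NA_character_
    if (an == "N" && rn != "PRO") base <- "CA"
    sc <- HB_DONORS[[rn]]
    if (!is.null(sc) && an %in% names(sc)) base <- sc[[an]]
    if (!is.na(base)) {
      j <- which(atoms$resno == atoms$resno[i] & atoms$atomname == base)
      if (length(j)) don_base[i] <- j[1] - 1L
    }
    if (an %in% HB_ACCEPTORS$backbone) is_acc[i] <- TRUE
    acc <- HB_ACCEPTORS[[rn]]
    if (!is.null(acc) && an %in% acc) is_acc[i] <- TRUE
  }
  list(rmin_half = lj$rmin_half, eps = lj$eps, q = q,
       don_base = don_base, is_acc = as.integer(is_acc))
}
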