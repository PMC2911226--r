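## Building polypeptides with ideal internal geometry, measuring and
## setting torsions, and deriving bond graphs (needed for nonbonded
## exclusions and for deciding which atoms a torsion rotation moves).

## Standard backbone internal coordinates.
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
           ang_ca_c_o = 120.5, omega = 180)

#' Build a polypeptide chain with ideal geometry
#'
#' Constructs backbone and sidechain heavy atoms residue by residue from
#' idealised internal coordinates.  Backbone conformation is set by the
#' `phi`/`psi` vectors; sidechain chi angles default to 180 (extended).
#'
#' @param sequence one-letter string or character vector of residues.
#' @param phi,psi backbone torsions in degrees, recycled to length(sequence).
#'   `phi[1]` is unused (no preceding carbonyl).
#' @param chis optional list (one numeric vector per residue) of chi angles.
#' @param resno residue numbers (default `start + 0:(n-1)`).
#' @param start first residue number.
#' @param id,chain labels for the returned Structure.
#' @return a `Structure`.
#' @export
build_chain <- function(sequence, phi = -139, psi = 135, chis = NULL,
                        resno = NULL, start = 1L, id = "built", chain = "A") {
  seq1 <- if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    strsplit(sequence, "")[[1]] else sequence
  n <- length(seq1)
  if (!n) stop("empty sequence")
  res3 <- AA3_FROM_1[toupper(seq1)]
  if (anyNA(res3)) stop("unknown residue letter(s): ",
                        paste(unique(seq1[is.na(res3)]), collapse = ", "))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  ## the pyrrolidine ring (built with fixed internal torsions) constrains
  ## proline's backbone: force the canonical phi
  phi[res3 == "PRO"] <- -65
  if (is.null(resno)) resno <- start + seq_len(n) - 1L
  rows <- list()
  add <- function(resno, resname, atomname, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno, resname = resname, atomname = atomname,
      element = substr(gsub("[0-9]", "", atomname), 1, 1),
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  prev <- NULL  # list(N, CA, C) of previous residue
  for (i in seq_len(n)) {
    rn <- res3[[i]]
    if (is.null(prev)) {
      N <- c(0, 0, 0)
      CA <- c(BB$n_ca, 0, 0)
      th <- deg2rad(180 - BB$ang_n_ca_c)
      C <- CA + BB$ca_c * c(cos(th), sin(th), 0)
    } else {
      N <- place_atom(prev$N, prev$CA, prev$C, BB$c_n, BB$ang_ca_c_n, psi[i - 1])
      CA <- place_atom(prev$CA, prev$C, N, BB$n_ca, BB$ang_c_n_ca, BB$omega)
      C <- place_atom(prev$C, N, CA, BB$ca_c, BB$ang_n_ca_c, phi[i])
      ## carbonyl O of the previous residue, anti to this N
      O_prev <- place_atom(N, prev$CA, prev$C, BB$c_o, BB$ang_ca_c_o, 180)
      rows[[prev$o_slot]]$x <- O_prev[1]
      rows[[prev$o_slot]]$y <- O_prev[2]
      rows[[prev$o_slot]]$z <- O_prev[3]
    }
    add(resno[i], rn, "N", N)
    add(resno[i], rn, "CA", CA)
    add(resno[i], rn, "C", C)
    ## provisional O (overwritten once the next N exists)
    O <- place_atom(N, CA, C, BB$c_o, BB$ang_ca_c_o, wrap_angle(psi[i] + 180))
    add(resno[i], rn, "O", O)
    o_slot <- length(rows)
    ## sidechain
    tpl <- SIDECHAIN_TEMPLATES[[rn]]
    if (!is.null(tpl)) {
      pos <- list(N = N, CA = CA, C = C)
      chiv <- if (!is.null(chis) && length(chis) >= i && !is.null(chis[[i]]))
        chis[[i]] else rep(180, max(N_CHI[[rn]], 1L))
      for (k in seq_len(nrow(tpl))) {
        row <- tpl[k, ]
        dih <- if (is.na(row$chi)) row$dih else {
          if (length(chiv) < row$chi) stop("too few chi angles for ", rn)
          wrap_angle(chiv[row$chi] + row$dih)
        }
        xyz <- place_atom(pos[[row$dihref]], pos[[row$angref]],
                          pos[[row$parent]], row$bond, row$angle, dih)
        pos[[row$name]] <- xyz
        add(resno[i], rn, row$name, xyz)
      }
    }
    prev <- list(N = N, CA = CA, C = C, o_slot = o_slot)
  }
  new_structure(id, chain, do.call(rbind, rows))
}

## Bond list (pairs of 1-based atom row indices) for a built Structure,
## derived from backbone connectivity plus the sidechain templates.
structure_bonds <- function(s) {
  a <- s$atoms
  key <- paste(a$resno, a$atomname)
  idx <- stats::setNames(seq_len(nrow(a)), key)
  bonds <- list()
  bond <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)
  resnos <- unique(a$resno)
  for (ri in seq_along(resnos)) {
    r <- resnos[ri]
    rn <- a$resname[a$resno == r][1]
    gi <- function(an) idx[paste(r, an)]
    if (!is.na(gi("CA"))) {
      if (!is.na(gi("N"))) bond(gi("N"), gi("CA"))
      if (!is.na(gi("C"))) bond(gi("CA"), gi("C"))
    }
    if (!is.na(gi("C")) && !is.na(gi("O"))) bond(gi("C"), gi("O"))
    if (!is.na(gi("C")) && !is.na(gi("OXT"))) bond(gi("C"), gi("OXT"))
    tpl <- SIDECHAIN_TEMPLATES[[rn]]
    if (!is.null(tpl)) {
      for (k in seq_len(nrow(tpl))) {
        i1 <- gi(tpl$name[k]); i2 <- gi(tpl$parent[k])
        if (!is.na(i1) && !is.na(i2)) bond(i1, i2)
      }
    }
    ## ring-closure bonds (the templates only carry the build-tree edges)
    closures <- switch(rn,
      PRO = list(c("CD", "N")),
      PHE = , TYR = list(c("CZ", "CE2")),
      TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
      HIS = list(c("CE1", "NE2")),
      NULL)
    for (cl in closures) {
      i1 <- gi(cl[1]); i2 <- gi(cl[2])
      if (!is.na(i1) && !is.na(i2)) bond(i1, i2)
    }
    if (ri < length(resnos)) {
      r2 <- resnos[ri + 1]
      j <- idx[paste(r2, "N")]
      if (!is.na(gi("C")) && !is.na(j)) bond(gi("C"), j)
    }
  }
  if (!length(bonds)) matrix(integer(0), ncol = 2)
  else do.call(rbind, bonds)
}

## Adjacency list from a bond matrix.
bond_adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

## Pairs of atoms within `depth` bonds of each other (1-2, 1-3, 1-4 for
## depth 3): excluded from nonbonded terms.
bonded_exclusions <- function(bonds, n, depth = 3L) {
  adj <- bond_adjacency(bonds, n)
  out <- list()
  for (i in seq_len(n)) {
    dist <- rep(Inf, n); dist[i] <- 0
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (dist[v] >= depth) next
      for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    nb <- which(dist <= depth & seq_len(n) > i)
    if (length(nb)) out[[length(out) + 1L]] <- cbind(i, nb)
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

## The atoms moved by rotating about bond (b, c): the connected component,
## after deleting that bond, that does NOT contain any `keep_fixed` atom.
## Falls back to the component containing `d_side` when no anchor given.
torsion_moving_set <- function(adj, b, c, keep_fixed = integer(), d_side = c) {
  n <- length(adj)
  comp <- rep(NA_integer_, n)
  for (seed in c(b, c)) {
    lab <- if (seed == b) 1L else 2L
    if (!is.na(comp[seed])) next
    comp[seed] <- lab
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == b && w == c) || (v == c && w == b)) next
        if (is.na(comp[w])) { comp[w] <- lab; queue <- c(queue, w) }
      }
    }
  }
  side_b <- which(comp == 1L); side_c <- which(comp == 2L)
  if (length(keep_fixed)) {
    if (any(keep_fixed %in% side_c)) moving <- side_b else moving <- side_c
  } else {
    moving <- if (d_side %in% side_c) side_c else side_b
  }
  setdiff(moving, c(b, c))
}

## Current chi angles of one residue, measured from coordinates.
measure_chis <- function(s, resno) {
  rn <- residue_atoms(s, resno)$resname[1]
  quads <- chi_quadruples(rn)
  if (!length(quads)) return(numeric(0))
  vapply(quads, function(q) {
    p <- lapply(q, function(an) {
      at <- s$atoms[s$atoms$resno == resno & s$atoms$atomname == an, ]
      if (!nrow(at)) return(NULL)
      c(at$x[1], at$y[1], at$z[1])
    })
    if (any(vapply(p, is.null, TRUE))) return(NA_real_)
    dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
  }, 0)
}

## Rebuild one residue's sidechain from its backbone with the given chi
## angles (used to reposition the catalytic arginine onto a template
## rotamer).  Atoms not present in the structure are ignored.
rebuild_sidechain <- function(s, resno, chis) {
  at <- residue_atoms(s, resno)
  rn <- at$resname[1]
  tpl <- SIDECHAIN_TEMPLATES[[rn]]
  if (is.null(tpl)) return(s)
  pos <- list()
  for (an in c("N", "CA", "C")) {
    row <- at[at$atomname == an, ]
    if (!nrow(row)) stop("residue ", resno, " lacks backbone atom ", an)
    pos[[an]] <- c(row$x[1], row$y[1], row$z[1])
  }
  for (k in seq_len(nrow(tpl))) {
    row <- tpl[k, ]
    dih <- if (is.na(row$chi)) row$dih else {
      if (length(chis) < row$chi) 180 else wrap_angle(chis[row$chi] + row$dih)
    }
    xyz <- place_atom(pos[[row$dihref]], pos[[row$angref]],
                      pos[[row$parent]], row$bond, row$angle, dih)
    pos[[row$name]] <- xyz
    if (any(at$atomname == row$name))
      s <- set_residue_coords(s, resno, row$name, matrix(xyz, 1))
  }
  s
}
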