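## S2-pocket quantification: gatekeeper gap geometry, rim formal charge,
## and the three-way surface classification (mixed-neutral / acidic /
## occluded).

#' Default classification thresholds
#'
#' The occlusion and acidity cutoffs are not physical constants; they are
#' calibrated so the documented class memberships (PPIA mixed-neutral,
#' SDCCAG-10/PPIC/PPWD1 acidic, NKTR occluded) are reproduced, and are
#' exposed here for adjustment.
#'
#' @return list with `occlusion_gap` (Angstrom; gap below this is
#'   occluded), `acidic_charge` (net rim formal charge at or below this is
#'   acidic) and `a2b8_rmsd` (loop-class cutoff, Angstrom).
#' @export
cycloscan_thresholds <- function() {
  list(occlusion_gap = 5.5, acidic_charge = -2L, a2b8_rmsd = 1.5)
}

#' Gatekeeper 1-3 gap width
#'
#' Minimum heavy-atom distance between the sidechains of the gatekeeper-1
#' (PPIA 73) and gatekeeper-3 (PPIA 103) residues; for glycine the CA
#' stands in for the sidechain.
#'
#' @param target a `Structure`.
#' @param map its `ActiveSiteMap`.
#' @return gap width in Angstrom.
#' @export
gatekeeper_gap <- function(target, map) {
  r1 <- map_lookup(map, GATEKEEPER_POSITIONS[["gatekeeper1"]])
  r3 <- map_lookup(map, GATEKEEPER_POSITIONS[["gatekeeper3"]])
  sc1 <- sidechain_atoms(target, r1$target_resno)
  sc3 <- sidechain_atoms(target, r3$target_resno)
  if (!nrow(sc1) || !nrow(sc3)) {
    missing <- c(if (!nrow(sc1)) paste0("gatekeeper-1 (residue ",
                                        r1$target_resno, ")"),
                 if (!nrow(sc3)) paste0("gatekeeper-3 (residue ",
                                        r3$target_resno, ")"))
    stop("missing sidechain atoms for: ", paste(missing, collapse = "; "))
  }
  c1 <- as.matrix(sc1[, c("x", "y", "z")])
  c3 <- as.matrix(sc3[, c("x", "y", "z")])
  d2 <- outer(rowSums(c1^2), rowSums(c3^2), `+`) - 2 * (c1 %*% t(c3))
  sqrt(max(min(d2), 0))
}

#' Net formal charge of the S2 rim
#'
#' Sum of sidechain formal charges at pH 7 (Asp/Glu -1, Lys/Arg +1, His 0)
#' over the seven rim positions (PPIA 73, 81, 82, 103, 107, 110, 111).
#' Unmapped rim positions count as 0 with a warning.
#'
#' @param map an `ActiveSiteMap`.
#' @return signed integer.
#' @export
rim_formal_charge <- function(map) {
  total <- 0L
  for (pos in S2_RIM_POSITIONS) {
    row <- map_lookup(map, pos, required = FALSE)
    if (is.null(row)) {
      warning("rim position ", pos, " unmapped; counted as charge 0")
      next
    }
    total <- total + formal_charge(row$target_resname)
  }
  total
}

#' Classify an isoform's S2-rim surface
#'
#' Occlusion is a geometric override and is tested first: a gatekeeper
#' 1-3 gap below the occlusion threshold gives `"occluded"` regardless of
#' charge.  Otherwise a rim formal charge at or below the acidity
#' threshold gives `"acidic"`, else `"mixed-neutral"`.
#'
#' @param target a `Structure`.
#' @param map its `ActiveSiteMap`.
#' @param thresholds see [cycloscan_thresholds()].
#' @return a `SurfaceClass`: list with `label`, `net_formal_charge` and
#'   `gap_width`.
#' @export
classify_surface <- function(target, map,
                             thresholds = cycloscan_thresholds()) {
  gap <- gatekeeper_gap(target, map)
  charge <- rim_formal_charge(map)
  label <- if (gap < thresholds$occlusion_gap) "occluded"
           else if (charge <= thresholds$acidic_charge) "acidic"
           else "mixed-neutral"
  structure(list(label = label, net_formal_charge = charge,
                 gap_width = gap), class = "SurfaceClass")
}

#' @export
print.SurfaceClass <- function(x, ...) {
  cat(sprintf("S2 surface: %s (gap %.2f A, net rim charge %+d)\n",
              x$label, x$gap_width, x$net_formal_charge))
  invisible(x)
}
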