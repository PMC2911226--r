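## The documented scoring model.  The binding-energy estimate is
##   E_bind = E_inter + E_strain
## with
##   E_inter  : peptide<->receptor 6-12 Lennard-Jones + Coulomb with
##              distance-dependent dielectric eps(r) = 4r + a 10-12
##              hydrogen-bond term with cos^2 angular weight, within a
##              nonbonded cutoff;
##   E_strain : torsion strain (rotamer-deviation penalty relative to the
##              initial template-placed state) + repulsive-only (WCA)
##              intra-peptide sterics + repulsive-only sterics of moved
##              receptor sidechains against the rest of the receptor.
##              All strain terms are >= 0: internal relaxation can never
##              masquerade as binding energy.
## A pose with no peptide-receptor pair inside the cutoff is the separated
## reference and scores exactly 0.  The tether is a separate harmonic term,
## included in Monte-Carlo acceptance but excluded from the reported E_bind.
## All values are on an internal kcal/mol-like scale.

#' Construct the energy model
#'
#' @param cutoff nonbonded cutoff in Angstrom (must exceed the largest
#'   Lennard-Jones Rmin sum).
#' @param coulomb_k Coulomb constant in kcal*A/(mol*e^2).
#' @param dielectric_factor distance-dependent dielectric eps(r) =
#'   `dielectric_factor * r`.
#' @param hb_r0,hb_eps,hb_rmin,hb_rmax,hb_angle_min 10-12 hydrogen-bond
#'   term: optimum distance, well depth, distance window, minimum
#'   base-donor-acceptor angle (degrees).
#' @param k_tor torsion strain constant (kcal/mol per unit 1-cos).
#' @param k_tether tether force constant (kcal/mol/A^2).
#' @param clash_dist,clash_energy pairs closer than `clash_dist` add the
#'   large finite `clash_energy` and set the clash flag; per-pair LJ energy
#'   is also capped at `clash_energy` (never infinite).
#' @param temperature Monte-Carlo temperature in Kelvin.
#' @return an `EnergyModel` list.
#' @export
energy_model <- function(cutoff = 8.0, coulomb_k = 332.0637,
                         dielectric_factor = 4, hb_r0 = 2.9, hb_eps = 2.0,
                         hb_rmin = 2.5, hb_rmax = 3.5, hb_angle_min = 90,
                         k_tor = 0.5, k_tether = 10,
                         clash_dist = 0.5, clash_energy = 1000,
                         temperature = 300) {
  max_rmin_sum <- 2 * max(vapply(LJ_PARAMS, `[[`, 0, "rmin_half"))
  if (cutoff <= max_rmin_sum)
    stop("cutoff must exceed the largest Lennard-Jones Rmin sum (",
         max_rmin_sum, " A)")
  structure(list(cutoff = cutoff, coulomb_k = coulomb_k,
                 dielectric_factor = dielectric_factor,
                 hb_r0 = hb_r0, hb_eps = hb_eps, hb_rmin = hb_rmin,
                 hb_rmax = hb_rmax, hb_angle_min = hb_angle_min,
                 k_tor = k_tor, k_tether = k_tether,
                 clash_dist = clash_dist, clash_energy = clash_energy,
                 temperature = temperature),
            class = "EnergyModel")
}

## Pairwise nonbonded energy between two annotated atom sets (R reference
## implementation; the Monte-Carlo kernel reimplements this in C++ and is
## checked against it).  Returns LJ, Coulomb, H-bond sums and clash flag.
pairwise_energy <- function(xyz1, ann1, xyz2, ann2, model) {
  lj <- 0; coul <- 0; hb <- 0; clash <- FALSE
  n_within <- 0L
  for (i in seq_len(nrow(xyz1))) {
    for (j in seq_len(nrow(xyz2))) {
      dv <- xyz1[i, ] - xyz2[j, ]
      r <- sqrt(sum(dv * dv))
      if (r >= model$cutoff) next
      n_within <- n_within + 1L
      if (r < model$clash_dist) {
        clash <- TRUE
        lj <- lj + model$clash_energy
        next
      }
      rmin <- ann1$rmin_half[i] + ann2$rmin_half[j]
      eps <- sqrt(ann1$eps[i] * ann2$eps[j])
      sr6 <- (rmin / r)^6
      e_lj <- eps * (sr6 * sr6 - 2 * sr6)
      lj <- lj + min(e_lj, model$clash_energy)
      q12 <- ann1$q[i] * ann2$q[j]
      if (q12 != 0)
        coul <- coul + model$coulomb_k * q12 /
          (model$dielectric_factor * r * r)
      ## hydrogen bond: donor in one set, acceptor in the other
      hb <- hb + hb_pair_energy(i, j, xyz1, ann1, xyz2, ann2, r, model) +
                 hb_pair_energy(j, i, xyz2, ann2, xyz1, ann1, r, model)
    }
  }
  list(lj = lj, coulomb = coul, hbond = hb, clash = clash,
       n_within = n_within)
}

## 10-12 H-bond energy for donor atom i (set 1) vs acceptor atom j (set 2).
hb_pair_energy <- function(i, j, xyz1, ann1, xyz2, ann2, r, model) {
  if (ann1$don_base[i] < 0L || !ann2$is_acc[j]) return(0)
  if (r < model$hb_rmin || r > model$hb_rmax) return(0)
  base <- xyz1[ann1$don_base[i] + 1L, ]
  v1 <- base - xyz1[i, ]
  v2 <- xyz2[j, ] - xyz1[i, ]
  ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  ang <- rad2deg(acos(pmin(pmax(ct, -1), 1)))
  if (ang < model$hb_angle_min) return(0)
  x10 <- (model$hb_r0 / r)^10
  x12 <- x10 * (model$hb_r0 / r)^2
  model$hb_eps * (5 * x12 - 6 * x10) * ct * ct
}

## Intra-peptide steric energy: repulsive-only (WCA-shifted LJ, >= 0)
## over non-excluded pairs.  Purely a self-avoidance term.
intra_energy <- function(xyz, ann, excl, model) {
  n <- nrow(xyz)
  if (n < 2) return(0)
  exmat <- matrix(FALSE, n, n)
  if (nrow(excl)) exmat[excl] <- TRUE
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (exmat[i, j] || exmat[j, i]) next
      dv <- xyz[i, ] - xyz[j, ]
      r <- sqrt(sum(dv * dv))
      rmin <- ann$rmin_half[i] + ann$rmin_half[j]
      if (r >= rmin) next
      if (r < model$clash_dist) { e <- e + model$clash_energy; next }
      eps <- sqrt(ann$eps[i] * ann$eps[j])
      sr6 <- (rmin / r)^6
      e <- e + min(eps * (sr6 * sr6 - 2 * sr6) + eps, model$clash_energy)
    }
  }
  e
}

## Annotation + exclusion tables for a pose, cached on first use.
pose_physics <- function(pose, model) {
  if (!is.null(pose$physics)) return(pose$physics)
  ann <- annotate_atoms(pose$structure$atoms)
  bonds <- structure_bonds(pose$structure)
  excl <- bonded_exclusions(bonds, nrow(pose$structure$atoms))
  list(ann = ann, excl = excl)
}

#' Score a peptide pose against a receptor
#'
#' Reference (pure R) evaluation of the documented binding-energy model;
#' see the package vignette for the functional form.  `receptor_strain`
#' lets the sampler pass the gatekeeper rotamer-deviation strain so that
#' reported energies match Monte-Carlo bookkeeping.
#'
#' @param pose a `PeptidePose`.
#' @param receptor receptor `Structure` (pose$receptor if omitted).
#' @param model an [energy_model()].
#' @param receptor_strain extra strain energy from moved receptor
#'   sidechains (default 0).
#' @return list with `E_bind`, `components` (lj, coulomb, hbond, strain,
#'   intra), `clash` and `separated` flags.
#' @export
score_energy <- function(pose, receptor = pose$receptor,
                         model = energy_model(), receptor_strain = 0) {
  phys <- pose_physics(pose, model)
  ann_r <- annotate_atoms(receptor$atoms)
  xyz_p <- structure_coords(pose$structure)
  xyz_r <- structure_coords(receptor)
  inter <- pairwise_energy(xyz_p, phys$ann, xyz_r, ann_r, model)
  if (inter$n_within == 0L) {
    return(list(E_bind = 0,
                components = c(lj = 0, coulomb = 0, hbond = 0,
                               strain = 0, intra = 0),
                clash = FALSE, separated = TRUE))
  }
  strain_tor <- 0
  for (tor in pose$torsions) {
    chi_now <- dihedral_angle(xyz_p[tor$ref_d, ], xyz_p[tor$ai, ],
                              xyz_p[tor$aj, ], xyz_p[tor$ref_x, ])
    strain_tor <- strain_tor +
      model$k_tor * (1 - cos(deg2rad(chi_now - tor$chi0)))
  }
  e_intra <- intra_energy(xyz_p, phys$ann, phys$excl, model)
  strain <- strain_tor + receptor_strain
  e_bind <- inter$lj + inter$coulomb + inter$hbond + strain + e_intra
  list(E_bind = e_bind,
       components = c(lj = inter$lj, coulomb = inter$coulomb,
                      hbond = inter$hbond, strain = strain,
                      intra = e_intra),
       clash = inter$clash, separated = FALSE)
}

#' Harmonic tether penalty of a pose
#'
#' `k * sum_i d_i^2` over the anchored Gly-Pro heavy atoms, where `d_i` is
#' the displacement from the anchor reference; zero iff the anchor atoms
#' coincide with their reference positions.
#'
#' @param pose a `PeptidePose`.
#' @param k force constant in kcal/mol/A^2.
#' @return penalty energy (>= 0).
#' @export
tether_penalty <- function(pose, k = energy_model()$k_tether) {
  if (is.null(pose$anchor_reference)) stop("pose lacks anchor reference")
  xyz <- structure_coords(pose$structure, pose$anchor_idx)
  k * sum((xyz - pose$anchor_reference)^2)
}

#' Count peptide-receptor hydrogen bonds
#'
#' Donor-acceptor pairs (heavy atoms; donors carry implicit hydrogens)
#' within the model's distance window whose base-donor-acceptor angle
#' meets the angular criterion.  Each donor-acceptor pair counts once.
#'
#' @inheritParams score_energy
#' @return integer count.
#' @export
count_hbonds <- function(pose, receptor = pose$receptor,
                         model = energy_model()) {
  ann_p <- annotate_atoms(pose$structure$atoms)
  ann_r <- annotate_atoms(receptor$atoms)
  xyz_p <- structure_coords(pose$structure)
  xyz_r <- structure_coords(receptor)
  count <- 0L
  ok_pair <- function(i, j, xyz1, ann1, xyz2, ann2) {
    if (ann1$don_base[i] < 0L || !ann2$is_acc[j]) return(FALSE)
    dv <- xyz1[i, ] - xyz2[j, ]
    r <- sqrt(sum(dv * dv))
    if (r < model$hb_rmin || r > model$hb_rmax) return(FALSE)
    base <- xyz1[ann1$don_base[i] + 1L, ]
    v1 <- base - xyz1[i, ]
    v2 <- xyz2[j, ] - xyz1[i, ]
    ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    rad2deg(acos(pmin(pmax(ct, -1), 1))) >= model$hb_angle_min
  }
  for (i in seq_len(nrow(xyz_p))) for (j in seq_len(nrow(xyz_r))) {
    if (ok_pair(i, j, xyz_p, ann_p, xyz_r, ann_r)) count <- count + 1L
    if (ok_pair(j, i, xyz_r, ann_r, xyz_p, ann_p)) count <- count + 1L
  }
  count
}

#' S2-penetration distance metric
#'
#' Minimum distance from any peptide heavy atom to the CA of the
#' gatekeeper-2 residue (PPIA Lys82 equivalent), which sits at the far end
#' of the S2 pocket: small values mean the peptide fills the pocket.
#'
#' @param pose a `PeptidePose`.
#' @param receptor receptor `Structure`.
#' @param map the receptor's `ActiveSiteMap`.
#' @return distance in Angstrom, with attribute `non_penetrating` set when
#'   all peptide atoms are 15 A or farther.
#' @export
s2_distance <- function(pose, receptor = pose$receptor, map) {
  gk2 <- map_lookup(map, GATEKEEPER_POSITIONS[["gatekeeper2"]])
  ca <- receptor$atoms[receptor$atoms$resno == gk2$target_resno &
                       receptor$atoms$atomname == "CA", ]
  if (!nrow(ca)) stop("gatekeeper-2 residue lacks a CA atom")
  p <- structure_coords(pose$structure)
  d <- sqrt(rowSums(sweep(p, 2, c(ca$x[1], ca$y[1], ca$z[1]))^2))
  out <- min(d)
  attr(out, "non_penetrating") <- out >= 15
  out
}
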