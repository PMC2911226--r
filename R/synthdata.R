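## Synthetic structures with known ground truth.  The toy receptor is not
## a protein fold: it is a scaffold of idealised residues and short
## strand fragments arranged to present (a) a proline-binding S1' cavity
## with a catalytic-arginine stand-in, (b) an adjacent S2 groove of
## configurable depth whose rim carries the seven gatekeeper positions
## with configurable identities, and (c) a gatekeeper-1/3 closest-approach
## gap calibrated to the configured width.  All screen operations depend
## only on this local pocket geometry, so the scaffold suffices to test
## every pipeline stage without downloading any structure.
##
## Geometry (receptor frame): the template Gly-Pro sits near the origin
## with the peptide N-terminal direction along -y, so P2/P3 of a placed
## tetrapeptide extend into the S2 groove, which runs along -y; walls sit
## at x = +/- half the groove width, the floor below, and gatekeeper 2
## (the d_S2 reference) at the far end of the groove.

#' Scenario configuration for the synthetic receptor
#'
#' @param pocket_depth distance (Angstrom) from the anchored proline CA to
#'   the gatekeeper-2 CA at the far end of the S2 groove (default 15: the
#'   pocket extends a few Angstrom beyond the reach of an extended P3).
#' @param gap_width target closest heavy-atom approach between the
#'   gatekeeper-1 and gatekeeper-3 sidechains (Angstrom); ~9 leaves the
#'   groove open, below ~5 occludes it.
#' @param groove_width wall-to-wall width of the S2 groove (Angstrom).
#' @param rim one-letter identities of the seven rim positions, in PPIA
#'   order (73, 81, 82, 103, 107, 110, 111); default is the PPIA rim
#'   Thr, Glu, Lys, Ala, Thr, Ser, Gln.
#' @param wall_residue residue lining the groove walls and floor; leucine
#'   (the default) gives the hydrophobic, contact-rich lining that favours
#'   bulky aromatic P2 sidechains.
#' @param p3_site_residues optional residues flanking the P3 subsite
#'   (e.g. `c("K", "R")` creates a basic patch that favours acidic P3).
#' @param pocket_plug if `TRUE`, rigid bulky residues fill the deep S2
#'   pocket, emulating the packed gatekeeper bulk of occluded isoforms
#'   (flexible gatekeeper copies alone cannot block the pocket, since
#'   sidechain rotation moves them aside).
#' @param favored_p2_class ground-truth label for the class the scenario
#'   is built to favour at P2 (`"aromatic"` or `"none"`).
#' @param seed stored for provenance; generation is fully deterministic.
#' @return a `ScenarioConfig` list.
#' @export
scenario_config <- function(pocket_depth = 15, gap_width = 9,
                            groove_width = 10,
                            rim = c("T", "E", "K", "A", "T", "S", "Q"),
                            wall_residue = "L",
                            p3_site_residues = NULL,
                            pocket_plug = FALSE,
                            favored_p2_class = "aromatic",
                            seed = 1L) {
  if (gap_width <= 0) stop("gap_width must be positive")
  if (length(rim) != 7L) stop("rim must give 7 residue identities")
  if (!all(toupper(rim) %in% AA1)) stop("rim identities must be standard")
  if (pocket_depth > 20) stop("infeasible geometry: depth exceeds scaffold")
  structure(list(pocket_depth = pocket_depth, gap_width = gap_width,
                 groove_width = groove_width, rim = toupper(rim),
                 wall_residue = toupper(wall_residue),
                 p3_site_residues = p3_site_residues,
                 pocket_plug = isTRUE(pocket_plug),
                 favored_p2_class = favored_p2_class,
                 seed = as.integer(seed)),
            class = "ScenarioConfig")
}

## Named preset scenarios.
#' @rdname scenario_config
#' @param name preset name: `"aromatic-S2"` (open hydrophobic groove),
#'   `"occluded"` (narrow gatekeeper gap), `"acidic-P3"` (basic patch at
#'   the P3 subsite), `"all-asp-rim"` (maximally acidic rim).
#' @export
scenario_preset <- function(name, seed = 1L) {
  switch(name,
    "aromatic-S2" = scenario_config(seed = seed),
    "occluded" = scenario_config(gap_width = 3.5, groove_width = 5,
                                 rim = c("W", "E", "K", "R", "T", "S", "Q"),
                                 pocket_plug = TRUE,
                                 favored_p2_class = "none", seed = seed),
    ## a basic patch flanking the P3 subsite (plus lysines on the rim)
    ## attracts acidic P3 sidechains and repels basic ones
    ## a groove lined with arginine (walls and P3-subsite patch): the
    ## positive potential attracts acidic sidechains everywhere the P3
    ## can reach and repels basic ones
    "acidic-P3" = scenario_config(wall_residue = "R",
                                  p3_site_residues = c("R", "R", "R"),
                                  rim = c("T", "R", "K", "A", "T", "S", "Q"),
                                  favored_p2_class = "aromatic", seed = seed),
    "all-asp-rim" = scenario_config(rim = rep("D", 7),
                                    favored_p2_class = "none", seed = seed),
    stop("unknown scenario preset: ", name))
}

## Build a single residue and place it with CA at `ca` and the CA->CB
## direction along `dir` (ignored for glycine).
place_residue_at <- function(letter, ca, dir = c(0, 0, 1)) {
  s <- build_chain(letter, phi = -139, psi = 135)
  xyz <- structure_coords(s)
  ca0 <- xyz[s$atoms$atomname == "CA", , drop = FALSE][1, ]
  if (letter != "G") {
    cb0 <- xyz[s$atoms$atomname == "CB", , drop = FALSE][1, ]
    v1 <- unit(cb0 - ca0); v2 <- unit(dir)
    ax <- pracma_cross(v1, v2)
    if (vnorm(ax) < 1e-8) {
      R <- if (sum(v1 * v2) > 0) diag(3) else axis_rotation(
        if (abs(v1[1]) < 0.9) pracma_cross(v1, c(1, 0, 0))
        else pracma_cross(v1, c(0, 1, 0)), 180)
    } else {
      ang <- rad2deg(atan2(vnorm(ax), sum(v1 * v2)))
      R <- axis_rotation(ax, ang)
    }
  } else R <- diag(3)
  xyz <- sweep(xyz, 2, ca0)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, ca, `+`)
  s$atoms[, c("x", "y", "z")] <- xyz
  s$atoms
}

## Place a short extended strand with first CA at `start`, chain direction
## `along`, sidechains toward `sc_dir`.
place_strand_at <- function(letters, start, along, sc_dir) {
  s <- build_chain(paste(letters, collapse = ""), phi = -139, psi = 135)
  xyz <- structure_coords(s)
  cas <- xyz[s$atoms$atomname == "CA", , drop = FALSE]
  v1 <- unit(cas[nrow(cas), ] - cas[1, ])
  v2 <- unit(along)
  ax <- pracma_cross(v1, v2)
  R1 <- if (vnorm(ax) < 1e-8) diag(3) else
    axis_rotation(ax, rad2deg(atan2(vnorm(ax), sum(v1 * v2))))
  xyz <- sweep(xyz, 2, cas[1, ]) %*% t(R1)
  ## spin about the chain axis so mean sidechain direction matches sc_dir
  sc <- xyz[!(s$atoms$atomname %in% BACKBONE_ATOMS), , drop = FALSE]
  if (nrow(sc)) {
    m <- colMeans(sc)
    m_perp <- m - sum(m * v2) * v2
    t_perp <- sc_dir - sum(sc_dir * v2) * v2
    if (vnorm(m_perp) > 1e-8 && vnorm(t_perp) > 1e-8) {
      a1 <- unit(m_perp); a2 <- unit(t_perp)
      ang <- rad2deg(atan2(sum(pracma_cross(a1, a2) * v2), sum(a1 * a2)))
      xyz <- xyz %*% t(axis_rotation(v2, ang))
    }
  }
  xyz <- sweep(xyz, 2, start, `+`)
  s$atoms[, c("x", "y", "z")] <- xyz
  s$atoms
}

## Place a residue so that its sidechain TIP (farthest heavy atom along
## the pointing direction) sits at `tip`, pointing along `dir`.
place_tip_at <- function(letter, tip, dir) {
  dir <- unit(dir)
  at <- place_residue_at(letter, c(0, 0, 0), dir)
  sc <- at[!(at$atomname %in% BACKBONE_ATOMS), , drop = FALSE]
  if (!nrow(sc)) sc <- at[at$atomname == "CA", , drop = FALSE]
  ext <- max(as.matrix(sc[, c("x", "y", "z")]) %*% dir)
  ca <- tip - dir * ext
  at[, c("x", "y", "z")] <- sweep(as.matrix(at[, c("x", "y", "z")]),
                                  2, ca, `+`)
  at
}

## Minimum distance between two coordinate matrices.
min_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqrt(max(min(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)), 0))
}

## Pull a placed residue (or strand) back along `dir` until every atom is
## at least `clearance` away from `path` (the anchored-peptide region).
retract_clear <- function(atoms, dir, path, clearance = 3.0) {
  dir <- unit(dir)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (i in 1:40) {
    d <- min_dist(xyz, path)
    if (d >= clearance) break
    xyz <- sweep(xyz, 2, dir * (clearance - d + 0.05), `+`)
  }
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

## The posed template Gly-Pro ligand (deterministic; shared between the
## receptor builder, which keeps the pocket clear of it, and
## make_template_complex).
toy_ligand <- function() {
  lig <- build_chain("GP", phi = -139, psi = 135, id = "glypro-template",
                     chain = "P")
  xyz <- structure_coords(lig)
  cas <- xyz[lig$atoms$atomname == "CA", , drop = FALSE]
  v1 <- unit(cas[2, ] - cas[1, ])      # Gly CA -> Pro CA
  v2 <- c(0, 1, 0)                     # chain axis toward +y
  ax <- pracma_cross(v1, v2)
  R <- if (vnorm(ax) < 1e-8) diag(3) else
    axis_rotation(ax, rad2deg(atan2(vnorm(ax), sum(v1 * v2))))
  xyz <- sweep(xyz, 2, cas[2, ]) %*% t(R)          # Pro CA at origin
  xyz <- sweep(xyz, 2, c(0, 3, 0.5), `+`)          # ... into the S1' site
  lig$atoms[, c("x", "y", "z")] <- xyz
  lig
}

## Reference path of an anchored tetrapeptide: the ligand plus an
## extended A-A-Gly-Pro probe superposed onto it.  The `path` used for
## scaffold clearance covers only the region a docked peptide cannot
## move out of (the tethered Gly-Pro and the P2 backbone); P3 is mobile,
## so scenarios are free to obstruct its initial position.
toy_reference_path <- function(lig) {
  probe <- build_chain("AAGP", phi = -139, psi = 135)
  sel_probe <- probe$atoms$resno %in% c(3L, 4L)
  sel_lig <- rep(TRUE, nrow(lig$atoms))
  key_p <- paste(probe$atoms$resno[sel_probe] - 2L,
                 probe$atoms$atomname[sel_probe])
  key_l <- paste(lig$atoms$resno, lig$atoms$atomname)
  m <- match(key_l, key_p)
  A <- structure_coords(lig)[!is.na(m), , drop = FALSE]
  B <- structure_coords(probe, which(sel_probe)[m[!is.na(m)]])
  sup <- kabsch_superpose(A, B)
  probe_xyz <- apply_transform(structure_coords(probe), sup$rotation,
                               sup$translation)
  fixed_sel <- probe$atoms$resno >= 2L &
    !(probe$atoms$resno == 2L & probe$atoms$atomname == "CB")
  list(path = rbind(structure_coords(lig),
                    probe_xyz[fixed_sel, , drop = FALSE]),
       p2_ca = probe_xyz[probe$atoms$resno == 2L &
                         probe$atoms$atomname == "CA", , drop = FALSE][1, ],
       p3_ca = probe_xyz[probe$atoms$resno == 1L &
                         probe$atoms$atomname == "CA", , drop = FALSE][1, ],
       pro_ca = structure_coords(lig)[lig$atoms$resno == 2L &
                                      lig$atoms$atomname == "CA",
                                      , drop = FALSE][1, ])
}

#' Generate a synthetic receptor with known ground truth
#'
#' See the package vignette for the scaffold geometry.  The returned
#' ground truth is derived from the configuration by the same documented
#' rules the classifier uses (it is a statement of construction, not a
#' re-run of the classifier on coordinates).
#'
#' @param config a [scenario_config()].
#' @return list with `structure` (the toy receptor, PPIA-style numbering
#'   at the 16 reference positions) and `truth` (a `GroundTruth` list:
#'   `surface_class`, `favored_p2_class`, `gap_width`, `net_charge`).
#' @export
make_toy_receptor <- function(config = scenario_config()) {
  stopifnot(inherits(config, "ScenarioConfig"))
  rim <- config$rim
  hw <- config$groove_width / 2
  lig <- toy_ligand()
  ref <- toy_reference_path(lig)
  path <- ref$path
  cx <- ref$p2_ca[1]        # the anchored-peptide path runs near x = cx
  ## each part: atoms + the direction it may retract along (NULL for the
  ## gatekeepers, whose geometry IS the configuration)
  parts <- list()
  add <- function(resno, atoms, retract = NULL) {
    atoms$resno <- resno
    parts[[length(parts) + 1L]] <<- list(atoms = atoms, retract = retract)
  }
  ## place with the tip toward `tip`, then back off until the whole
  ## residue clears the anchored-peptide path
  add_clear <- function(resno, letter, tip, dir, clearance = 3.0) {
    at <- place_tip_at(letter, tip, dir)
    add(resno, retract_clear(at, -unit(dir), path, clearance),
        retract = -unit(dir))
  }

  ## --- S1' site around the anchored Pro (CA at ref$pro_ca) ------------
  pc <- ref$pro_ca
  add_clear(55L, "R", pc + c(0, 2.5, 3.5), c(0, -0.4, -0.9))
  add_clear(60L, "F", pc + c(-3.2, 0.5, -0.5), c(1, 0, 0.15))
  add_clear(61L, "M", pc + c(3.2, 0.5, -0.5), c(-1, 0, 0.15))
  add_clear(63L, "Q", pc + c(-3.5, 3.5, 1.5), c(1, -0.4, -0.3))
  add_clear(101L, "A", pc + c(4.0, 2.5, -2.5), c(-0.8, -0.3, 0.5))
  add_clear(113L, "F", pc + c(0, -0.5, -3.4), c(0, -0.1, 1))
  add_clear(121L, "W", pc + c(-4.5, 3.0, -2.5), c(0.8, -0.3, 0.5))
  add_clear(122L, "L", pc + c(-3.0, -0.5, -2.8), c(0.7, 0, 0.7))
  add_clear(126L, "H", pc + c(3.0, -0.5, -2.8), c(-0.7, 0, 0.7))

  ## --- gatekeepers 1 and 3 across the groove mouth --------------------
  ## tips face each other along x, centred on the peptide path; the
  ## half-gap is then calibrated so the closest heavy-atom approach
  ## equals the configured width
  gk_y <- -6.0; gk_z <- -0.3
  half <- config$gap_width / 2
  mk_gk <- function(h) {
    list(gk1 = place_tip_at(rim[1], c(cx - h, gk_y, gk_z), c(1, 0, 0)),
         gk3 = place_tip_at(rim[4], c(cx + h, gk_y, gk_z), c(-1, 0, 0)))
  }
  sc_of <- function(at) {
    sc <- at[!(at$atomname %in% BACKBONE_ATOMS), , drop = FALSE]
    if (!nrow(sc)) sc <- at[at$atomname == "CA", , drop = FALSE]
    as.matrix(sc[, c("x", "y", "z")])
  }
  g <- mk_gk(half)
  for (it in 1:4) {
    d0 <- min_dist(sc_of(g$gk1), sc_of(g$gk3))
    if (abs(d0 - config$gap_width) < 0.02) break
    half <- half - (d0 - config$gap_width) / 2
    g <- mk_gk(half)
  }
  add(73L, g$gk1)
  add(103L, g$gk3)

  ## --- remaining rim; gatekeeper 2 at the far end of the groove -------
  yfar <- pc[2] - config$pocket_depth
  gk2 <- place_residue_at(rim[3], c(cx, yfar, -1), c(0, -1, -0.2))
  if (min_dist(gk2[gk2$atomname == "CA", c("x", "y", "z")], path) < 2.5)
    stop("infeasible geometry: pocket too shallow for the anchored peptide")
  add(82L, gk2)
  add_clear(81L, rim[2], c(cx - 3.8, -10, 0), c(1, 0.1, 0))
  add_clear(107L, rim[5], c(cx + 3.8, -10, 0), c(-1, 0.1, 0))
  add_clear(110L, rim[6], c(cx - 3.5, -13, 0.5), c(1, 0.2, 0))
  add_clear(111L, rim[7], c(cx + 3.5, -13, 0.5), c(-1, 0.2, 0))

  ## rigid pocket plug for occluded scenarios: bulky residues filling the
  ## deep groove between the gate and gatekeeper 2
  if (config$pocket_plug) {
    plug <- place_strand_at(rep("W", 3L), c(cx - 3.5, -9.8, -0.8),
                            c(1, 0, 0), c(0, 1, 0.3))
    plug$resno <- 134L + match(plug$resno, unique(plug$resno))
    parts[[length(parts) + 1L]] <- list(atoms = plug, retract = NULL)
  }

  ## optional P3-subsite residues (e.g. a basic patch favouring acidic
  ## P3); tips converge on the subsite from the sides and from above so
  ## their own backbones stay out of reach
  nextno <- 130L
  if (!is.null(config$p3_site_residues)) {
    sites <- list(list(c(cx - 3.5, -7, 3), c(1, 0, -0.4)),
                  list(c(cx + 3.5, -7, 3), c(-1, 0, -0.4)),
                  list(c(cx, -7.5, 4.8), c(0, 0.1, -1)),
                  list(c(cx, -10, 3.5), c(0, -0.4, -1)))
    for (i in seq_along(config$p3_site_residues)) {
      st <- sites[[((i - 1L) %% length(sites)) + 1L]]
      add_clear(nextno, config$p3_site_residues[i], st[[1]], st[[2]])
      nextno <- nextno + 1L
    }
  }

  ## --- groove walls and floor -----------------------------------------
  wl <- config$wall_residue
  wall_len <- 5L
  wall_parts <- list(
    list(at = place_strand_at(rep(wl, wall_len), c(cx - hw - 3, -3, -1),
                              c(0, -1, 0), c(1, 0, 0.2)),
         dir = c(-1, 0, -0.2)),
    list(at = place_strand_at(rep(wl, wall_len), c(cx + hw + 3, -3, -1),
                              c(0, -1, 0), c(-1, 0, 0.2)),
         dir = c(1, 0, -0.2)),
    list(at = place_strand_at(rep(wl, wall_len), c(cx - 2.5, -2.5, -6.8),
                              c(0, -1, 0), c(0, 0, 1)),
         dir = c(0, 0, -1)),
    list(at = place_strand_at(rep(wl, wall_len), c(cx + 2.5, -2.5, -6.8),
                              c(0, -1, 0), c(0, 0, 1)),
         dir = c(0, 0, -1)),
    ## backing slab under the S1' site
    list(at = place_strand_at(rep("A", 4L), pc + c(-4, 4, -6),
                              c(1, 0, 0), c(0, -0.3, 1)),
         dir = c(0, 0.3, -1))
  )
  no <- 140L
  for (w in wall_parts) {
    at <- retract_clear(w$at, w$dir, path, 3.0)
    at$resno <- no + match(at$resno, unique(at$resno)) - 1L
    no <- no + length(unique(at$resno))
    parts[[length(parts) + 1L]] <- list(atoms = at, retract = w$dir)
  }

  ## relax the scaffold: retract movable parts until no inter-part
  ## contact is closer than the clearance (fixed-vs-fixed contacts are
  ## the configuration's own business, e.g. an occluded gatekeeper gap)
  coords_of <- function(p) as.matrix(p$atoms[, c("x", "y", "z")])
  for (round in 1:60) {
    moved <- FALSE
    for (i in seq_along(parts)) for (j in seq_along(parts)) {
      if (i >= j) next
      d <- min_dist(coords_of(parts[[i]]), coords_of(parts[[j]]))
      if (d >= 2.8) next
      k <- if (!is.null(parts[[j]]$retract)) j
           else if (!is.null(parts[[i]]$retract)) i else next
      shift <- parts[[k]]$retract * (2.8 - d + 0.05)
      parts[[k]]$atoms[, c("x", "y", "z")] <-
        sweep(coords_of(parts[[k]]), 2, shift, `+`)
      ## never retract into the anchored-peptide path
      parts[[k]]$atoms <- retract_clear(parts[[k]]$atoms,
                                        parts[[k]]$retract, path, 3.0)
      moved <- TRUE
    }
    if (!moved) break
  }

  resnos <- vapply(parts, function(p) p$atoms$resno[1], 1L)
  atoms <- do.call(rbind, lapply(parts[order(resnos)], `[[`, "atoms"))
  s <- new_structure(sprintf("toy-%s", config$favored_p2_class), "A", atoms)

  truth <- structure(list(
    surface_class = {
      th <- cycloscan_thresholds()
      charge <- sum(formal_charge(AA3_FROM_1[rim]))
      if (config$gap_width < th$occlusion_gap) "occluded"
      else if (charge <= th$acidic_charge) "acidic" else "mixed-neutral"
    },
    favored_p2_class = config$favored_p2_class,
    gap_width = config$gap_width,
    net_charge = sum(formal_charge(AA3_FROM_1[rim]))),
    class = "GroundTruth")
  list(structure = s, truth = truth)
}

#' Active-site map of a synthetic receptor
#'
#' The toy receptor carries PPIA-style residue numbers at the 16 reference
#' positions, so its map is a direct identity lookup.
#'
#' @param s a toy receptor `Structure`.
#' @return an `ActiveSiteMap`.
#' @export
toy_active_site_map <- function(s) {
  res <- structure_residues(s)
  pos <- PPIA_REFERENCE_POSITIONS
  out <- data.frame(ref_pos = pos, ref_resname = NA_character_,
                    target_resname = NA_character_,
                    target_resno = NA_integer_, mapped = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(pos)) {
    i <- which(res$resno == pos[k])
    if (length(i)) {
      out$ref_resname[k] <- out$target_resname[k] <- res$resname[i]
      out$target_resno[k] <- res$resno[i]
      out$mapped[k] <- TRUE
    }
  }
  class(out) <- c("ActiveSiteMap", "data.frame")
  out
}

#' Toy receptor plus a bound Gly-Pro template ligand
#'
#' The dipeptide is posed over the S1' site with the glycine nitrogen
#' facing the S2 groove, standing in for a crystallographic bound-peptide
#' template in [place_peptide()].
#'
#' @param config a [scenario_config()].
#' @return list with `template` (a [template_complex()]), `receptor`,
#'   `map` and `truth`.
#' @export
make_template_complex <- function(config = scenario_config()) {
  toy <- make_toy_receptor(config)
  lig <- toy_ligand()
  map <- toy_active_site_map(toy$structure)
  list(template = template_complex(toy$structure, lig, map),
       receptor = toy$structure, map = map, truth = toy$truth)
}

#' Rigid or noisy perturbation of a structure
#'
#' `"rigid"` applies a random proper rotation and translation (superposing
#' back must give RMSD 0); `"noise"` adds i.i.d. Gaussian displacement of
#' standard deviation `sigma` per coordinate.
#'
#' @param s a `Structure`.
#' @param mode `"rigid"` or `"noise"`.
#' @param sigma noise standard deviation (Angstrom per coordinate).
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return the perturbed `Structure`.
#' @export
perturb_structure <- function(s, mode = c("rigid", "noise"), sigma = 0.5,
                              seed = 1L) {
  mode <- match.arg(mode)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  xyz <- structure_coords(s)
  if (mode == "rigid") {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_d <- qr(M)
    R <- qr.Q(qr_d)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tr <- stats::runif(3, -10, 10)
    xyz <- sweep(xyz %*% t(R), 2, tr, `+`)
  } else {
    if (sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = sigma),
                          ncol = 3)
  }
  s$atoms[, c("x", "y", "z")] <- xyz
  s
}

#' Synthetic reference domain (PPIA stand-in)
#'
#' A 165-residue single chain with the PPIA active-surface identities at
#' the 16 reference positions and a pseudo-random (seeded) sequence
#' elsewhere, built as an idealised helical rod.  It is a *synthetic*
#' stand-in for testing alignment, mapping and loop logic without any
#' deposited structure; it is not the PPIA fold.
#'
#' @param seed sequence seed.
#' @param n chain length.
#' @return a `Structure` with residues numbered 1..n.
#' @export
make_reference_domain <- function(seed = 42L, n = 165L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  letters20 <- unname(AA1)
  seq1 <- sample(letters20, n, replace = TRUE)
  fixed <- c(`55` = "R", `60` = "F", `61` = "M", `63` = "Q", `73` = "T",
             `81` = "E", `82` = "K", `101` = "A", `103` = "A",
             `107` = "T", `110` = "S", `111` = "Q", `113` = "F",
             `121` = "W", `122` = "L", `126` = "H")
  for (p in names(fixed)) {
    ip <- as.integer(p)
    if (ip <= n) seq1[ip] <- fixed[[p]]
  }
  seq1[seq1 == "P"] <- "A"   # keep the rod free of backbone kinks
  build_chain(seq1, phi = -57, psi = -47, id = "synthetic-ppia-standin")
}
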