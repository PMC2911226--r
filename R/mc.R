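## Metropolis sampling of pose space and the family-wide peptide screen.
## The C++ kernel does the hot loop; this file assembles its inputs
## (annotations, exclusions, flexible torsion sets) and interprets its
## output as ScreenRecords.

#' Monte-Carlo sampling parameters
#'
#' @param iterations number of Metropolis moves (paper-scale default
#'   200,000; tests and examples use far fewer).
#' @param temperature sampling temperature in Kelvin (constant schedule);
#'   with `anneal_factor < 1` the run is split into `anneal_stages`
#'   geometric-annealing stages.
#' @param weights named non-negative move weights for the three move
#'   classes: peptide `sidechain`, peptide `backbone`, receptor
#'   `gatekeeper` sidechains.  Must not all be zero.
#' @param max_step maximum torsion perturbation per move, degrees.
#' @param seed integer seed for the kernel's own PRNG (independent of R's).
#' @param trace_interval record best-so-far energy every this many moves.
#' @param anneal_factor,anneal_stages optional geometric annealing.
#' @param extra_flexible extra receptor residue numbers whose sidechains
#'   are sampled (e.g. the PPIL2 Arg377 case).
#' @return an `MCParams` list.
#' @export
mc_params <- function(iterations = 200000L, temperature = 300,
                      weights = c(sidechain = 1, backbone = 1,
                                  gatekeeper = 1),
                      max_step = 30, seed = 1L, trace_interval = 1000L,
                      anneal_factor = 1, anneal_stages = 1L,
                      extra_flexible = integer()) {
  if (iterations < 0) stop("iterations must be >= 0")
  w <- weights[c("sidechain", "backbone", "gatekeeper")]
  if (anyNA(w)) stop("weights must name sidechain, backbone, gatekeeper")
  if (any(w < 0) || sum(w) == 0)
    stop("move weights must be non-negative and not all zero")
  structure(list(iterations = as.integer(iterations),
                 temperature = temperature, weights = w,
                 max_step = max_step, seed = as.integer(seed),
                 trace_interval = as.integer(trace_interval),
                 anneal_factor = anneal_factor,
                 anneal_stages = as.integer(anneal_stages),
                 extra_flexible = extra_flexible),
            class = "MCParams")
}

#' Screening schedule
#'
#' The Monte-Carlo schedule used for peptide screens: geometric annealing
#' from a hot start (clash resolution for bulky P2/P3 built in the
#' extended start conformation) down to effectively zero temperature,
#' with wide torsion steps.  See the vignette for why a constant-300 K
#' schedule is insufficient here.
#'
#' @param iterations total Metropolis moves (paper-scale default 200,000).
#' @param seed master seed.
#' @param ... further arguments to [mc_params()].
#' @return an `MCParams`.
#' @export
screen_params <- function(iterations = 200000L, seed = 1L, ...) {
  mc_params(iterations = iterations, seed = seed, temperature = 10000,
            anneal_factor = 0.2, anneal_stages = 6L, max_step = 60, ...)
}

KB_KCAL <- 0.0019872041

## chi torsions of one receptor residue, as kernel input (0-based indices).
receptor_residue_torsions <- function(receptor, resno, adj, weight) {
  a <- receptor$atoms
  rn <- a$resname[a$resno == resno][1]
  quads <- chi_quadruples(rn)
  out <- list()
  for (k in seq_along(quads)) {
    idx <- vapply(quads[[k]], function(an) {
      i <- which(a$resno == resno & a$atomname == an)
      if (!length(i)) NA_integer_ else i[1]
    }, 1L)
    if (anyNA(idx)) next
    moving <- torsion_moving_set(adj, idx[2], idx[3], d_side = idx[4])
    if (!length(moving)) next
    chi0 <- dihedral_angle(as.numeric(a[idx[1], c("x", "y", "z")]),
                           as.numeric(a[idx[2], c("x", "y", "z")]),
                           as.numeric(a[idx[3], c("x", "y", "z")]),
                           as.numeric(a[idx[4], c("x", "y", "z")]))
    out[[length(out) + 1L]] <- list(
      which = 1L, ai = idx[2] - 1L, aj = idx[3] - 1L,
      moving = as.integer(moving - 1L), chi0 = chi0, weight = weight,
      name = sprintf("chi%d_res%d", k, resno))
  }
  out
}

## bonded exclusions (depth 3) restricted to pairs touching `atoms_of`.
exclusions_touching <- function(adj, atoms_of, depth = 3L) {
  out <- list()
  for (i in atoms_of) {
    dist <- rep(Inf, length(adj)); dist[i] <- 0
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (dist[v] >= depth) next
      for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    nb <- setdiff(which(is.finite(dist) & dist <= depth), i)
    if (length(nb)) out[[length(out) + 1L]] <- cbind(i, nb)
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

#' Metropolis sampling of one peptide pose
#'
#' Samples the flexible torsions (peptide P2/P3 plus the receptor's
#' gatekeeper sidechains at PPIA-equivalent positions 73, 82 and 103, plus
#' any `extra_flexible` residues) with Metropolis acceptance on the total
#' energy (binding model + tether).  Returns the minimum-total-energy pose
#' seen; the reported `E_bind` excludes the tether term.  Fully
#' reproducible from the seed.
#'
#' @param pose a [place_peptide()] pose.
#' @param receptor receptor `Structure` (defaults to `pose$receptor`).
#' @param map the receptor's `ActiveSiteMap`.
#' @param model an [energy_model()].
#' @param params an [mc_params()].
#' @return list with `record` (a `ScreenRecord`: peptide, E_bind, d_S2,
#'   n_hb, accepted_moves, clash, status, best pose structures) and
#'   `trace` (data.frame of iteration vs best-so-far total energy).
#' @export
mc_sample <- function(pose, receptor = pose$receptor, map,
                      model = energy_model(), params = mc_params()) {
  stopifnot(inherits(pose, "PeptidePose"), inherits(params, "MCParams"))
  ann_p <- annotate_atoms(pose$structure$atoms)
  ann_r <- annotate_atoms(receptor$atoms)
  pep_xyz <- structure_coords(pose$structure)
  rec_xyz <- structure_coords(receptor)
  bonds_p <- structure_bonds(pose$structure)
  excl_p <- bonded_exclusions(bonds_p, nrow(pep_xyz))

  ## flexible receptor residues: the three gatekeepers + extras
  flex_resnos <- integer()
  for (nm in names(GATEKEEPER_POSITIONS)) {
    row <- map_lookup(map, GATEKEEPER_POSITIONS[[nm]], required = FALSE)
    if (!is.null(row)) flex_resnos <- c(flex_resnos, row$target_resno)
  }
  flex_resnos <- unique(c(flex_resnos, params$extra_flexible))

  bonds_r <- structure_bonds(receptor)
  adj_r <- bond_adjacency(bonds_r, nrow(rec_xyz))
  rec_tors <- list()
  for (rn in flex_resnos)
    rec_tors <- c(rec_tors,
                  receptor_residue_torsions(receptor, rn, adj_r,
                                            params$weights[["gatekeeper"]]))
  flex_atoms <- sort(unique(unlist(lapply(rec_tors, function(t)
    t$moving + 1L))))
  excl_r <- if (length(flex_atoms))
    exclusions_touching(adj_r, flex_atoms) else matrix(integer(0), ncol = 2)

  pep_tors <- lapply(pose$torsions, function(t) {
    list(which = 0L, ai = t$ai - 1L, aj = t$aj - 1L,
         moving = as.integer(t$moving - 1L), chi0 = t$chi0,
         weight = params$weights[[t$class]], name = t$name)
  })
  torsions <- c(pep_tors, rec_tors)

  ## annealing schedule: constant by default
  stages <- max(1L, params$anneal_stages)
  kT0 <- KB_KCAL * params$temperature
  per_stage <- if (stages == 1L) params$iterations
               else as.integer(ceiling(params$iterations / stages))
  res <- NULL
  trace <- NULL
  chi_start <- vapply(torsions, `[[`, 0, "chi0")
  done <- 0L
  recrec_ref <- NA_real_
  for (s in seq_len(stages)) {
    it <- min(per_stage, params$iterations - done)
    if (s == 1L) it <- if (stages == 1L) params$iterations else it
    kT <- kT0 * params$anneal_factor^(s - 1)
    tor_in <- torsions
    for (k in seq_along(tor_in)) tor_in[[k]]$chi_start <- chi_start[k]
    par <- c(model[c("cutoff", "coulomb_k", "dielectric_factor", "hb_r0",
                     "hb_eps", "hb_rmin", "hb_rmax", "hb_angle_min",
                     "k_tor", "k_tether", "clash_dist", "clash_energy")],
             list(kT = kT, max_step = params$max_step, iterations = it,
                  trace_interval = params$trace_interval,
                  recrec_ref = recrec_ref,
                  seed = (params$seed + (s - 1) * 1234567891) %% 2^31))
    stage_res <- .mc_kernel(pep_xyz, ann_p, excl_p - 1L,
                            rec_xyz, ann_r,
                            as.integer(flex_atoms - 1L), excl_r - 1L,
                            tor_in, as.integer(pose$anchor_idx - 1L),
                            pose$anchor_reference, par)
    recrec_ref <- stage_res$recrec0
    tr <- stage_res$trace
    tr[, 1] <- tr[, 1] + done
    trace <- rbind(trace, tr)
    done <- done + it
    ## continue next stage from the best pose found so far
    pep_xyz <- stage_res$pep_xyz
    rec_xyz <- stage_res$rec_xyz
    chi_start <- stage_res$chis
    if (is.null(res) || stage_res$E_total <= res$E_total) res <- stage_res
    if (done >= params$iterations) break
  }

  best_pose <- pose
  best_pose$structure$atoms[, c("x", "y", "z")] <- res$pep_xyz
  best_rec <- receptor
  best_rec$atoms[, c("x", "y", "z")] <- res$rec_xyz
  best_pose$receptor <- best_rec

  d <- s2_distance(best_pose, best_rec, map)
  record <- structure(list(
    peptide = pose$peptide,
    E_bind = res$E_bind,
    d_S2 = as.numeric(d),
    n_hb = as.integer(res$n_hb),
    accepted_moves = as.integer(res$accepted),
    uphill_accepted = as.integer(res$uphill_accepted),
    clash = isTRUE(res$clash),
    separated = isTRUE(res$separated),
    status = "ok",
    pose = best_pose), class = "ScreenRecord")
  ## a single-stage trace is the kernel's raw best-so-far sequence; for
  ## stitched annealing stages the boundary energies are exact recomputes
  ## of incrementally tracked values, and cummin reconciles the
  ## (sub-1e-6) rounding so the result is best-so-far by construction
  best_seq <- if (stages == 1L) trace[, 2] else cummin(trace[, 2])
  trace_df <- data.frame(iteration = trace[, 1], best_energy = best_seq)
  list(record = record, trace = trace_df)
}

## Polynomial string hash modulo 2^31 - 1: deterministic per-peptide seeds
## (kept in double arithmetic; R integers are 32-bit).
peptide_seed <- function(master_seed, sequence) {
  h <- 17
  for (ch in utf8ToInt(paste0(master_seed, ":", sequence)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Run the tetrapeptide specificity screen
#'
#' Places and samples every peptide of the library against the receptor.
#' Per-peptide seeds are derived deterministically from the master seed
#' and the peptide sequence, so the 400 runs are independent and
#' individually reproducible.  Peptides that fail placement are recorded
#' with status `"failed"` and the screen continues.
#'
#' @param receptor receptor `Structure`.
#' @param map its `ActiveSiteMap`.
#' @param library list of [peptide()]s (see [generate_library()]).
#' @param template a [template_complex()].
#' @param model an [energy_model()].
#' @param params an [mc_params()]; `params$seed` is the master seed.
#' @param out optional TSV path; partial results are flushed there as the
#'   screen progresses.
#' @param store_poses keep each best pose in the result (memory-heavy).
#' @param progress print one line per peptide.
#' @return data.frame of class `ScreenResults` with columns `peptide`,
#'   `p3`, `p2`, `E_bind`, `d_S2`, `n_hb`, `accepted_moves`, `status`;
#'   when `store_poses` is TRUE, attribute `"records"` holds the
#'   ScreenRecords.
#' @export
run_screen <- function(receptor, map, library, template,
                       model = energy_model(), params = screen_params(),
                       out = NULL, store_poses = FALSE, progress = FALSE) {
  if (!length(library)) stop("empty peptide library")
  rows <- vector("list", length(library))
  records <- if (store_poses) vector("list", length(library)) else NULL
  for (i in seq_along(library)) {
    pep <- library[[i]]
    row <- data.frame(peptide = pep$sequence, p3 = pep$p3, p2 = pep$p2,
                      E_bind = NA_real_, d_S2 = NA_real_,
                      n_hb = NA_integer_, accepted_moves = NA_integer_,
                      status = "failed", stringsAsFactors = FALSE)
    res <- tryCatch({
      pose <- suppressWarnings(place_peptide(pep, receptor, template, map))
      pp <- params
      pp$seed <- peptide_seed(params$seed, pep$sequence)
      mc_sample(pose, pose$receptor, map, model, pp)
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      rec <- res$record
      row$E_bind <- rec$E_bind
      row$d_S2 <- rec$d_S2
      row$n_hb <- rec$n_hb
      row$accepted_moves <- rec$accepted_moves
      row$status <- "ok"
      if (store_poses) records[[i]] <- rec
    } else {
      row$status <- paste0("failed: ", conditionMessage(res))
    }
    rows[[i]] <- row
    if (progress)
      message(sprintf("[%d/%d] %s  E=%.2f d=%.2f", i, length(library),
                      row$peptide, row$E_bind, row$d_S2))
    if (!is.null(out) && (i %% 25L == 0L || i == length(library)))
      utils::write.table(do.call(rbind, rows[seq_len(i)]), out,
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res_df <- do.call(rbind, rows)
  class(res_df) <- c("ScreenResults", "data.frame")
  if (store_poses) attr(res_df, "records") <- records
  res_df
}
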