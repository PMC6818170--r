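## Running the lattice SSA and summarizing trajectories / ensembles.

#' Simulate a lattice world
#'
#' Exact continuous-time jump-process sampling (direct method) of diffusion
#' hops, first-order reactions and separation-dependent pairwise reactions.
#'
#' @param world A [build_world()] result.
#' @param t_end Simulation horizon, s.
#' @param sample_times Times at which species counts are recorded (sorted,
#'   within `[0, t_end]`).
#' @param stop_on_first_pair Stop at the first pairwise reaction event and
#'   record its time (used for reaction-time sampling in the two-particle
#'   comparisons).
#' @param avg_start Start of the time-averaging window: time-weighted mean
#'   species counts are accumulated over `[avg_start, t_end]` and over its
#'   two halves (used by steady-state detection).  Default `t_end` (no
#'   averaging).
#' @param track_molecule Optional 1-based molecule index whose unwrapped
#'   voxel displacement is recorded at `sample_times` (for mean-squared
#'   displacement checks).
#' @param max_events Event-count guard; the run stops with a flag if
#'   exceeded.
#' @param seed Optional integer seed (`set.seed` before running).  Leave
#'   NULL to continue the current RNG stream.
#' @return Object of class `trajectory_summary`: sampled `counts` (species x
#'   times), `t_final`, `status` ("done", "stopped_on_pair", "stalled",
#'   "event_cap"), `stop_time`, time-averaged counts `avg` / `avg_first_half`
#'   / `avg_second_half`, event counts, final state and, when requested, the
#'   tracked displacement in `track` (voxel units).
#' @export
#' @examples
#' dom <- lattice_domain(2, 300, 32)
#' net <- reaction_network(list(species_def("A", 0.01, 1e-4)))
#' w <- build_world(dom, net, seed = 1)
#' simulate_world(w, t_end = 0.1, sample_times = c(0.05, 0.1))
simulate_world <- function(world, t_end, sample_times = numeric(0),
                           stop_on_first_pair = FALSE,
                           avg_start = t_end, track_molecule = NULL,
                           max_events = 1e12, seed = NULL) {
  stopifnot(inherits(world, "lattice_world"))
  if (!is.null(seed)) set.seed(seed)
  dom <- world$domain
  net <- world$network
  nm <- net$species_names
  sp_idx <- function(s) match(s, nm) - 1L
  hop <- vapply(net$species, function(s) s$diffusivity_nm2 / dom$spacing^2,
                numeric(1))
  uni_r <- vapply(net$unimolecular, function(u) sp_idx(u$reactant), integer(1))
  uni_p <- vapply(net$unimolecular, function(u) sp_idx(u$product), integer(1))
  uni_rate <- vapply(net$unimolecular, `[[`, numeric(1), "rate")
  prules <- lapply(net$pairwise, function(p) {
    list(sp_a = sp_idx(p$reactant_a), sp_b = sp_idx(p$reactant_b),
         prod_a = sp_idx(p$product_of_a), prod_b = sp_idx(p$product_of_b),
         table = make_pair_table(p, dom))
  })
  if (length(sample_times) && is.unsorted(sample_times))
    stop("sample_times must be sorted")
  res <- crdme_run(dom$dimension, dom$voxels_per_axis,
                   dom$boundary == "periodic",
                   as.integer(world$species - 1L), world$pos,
                   hop,
                   as.integer(uni_r), as.integer(uni_p), as.numeric(uni_rate),
                   prules,
                   t_end, as.numeric(sample_times),
                   stop_on_first_pair,
                   avg_start,
                   if (is.null(track_molecule)) -1L
                   else as.integer(track_molecule - 1L),
                   max_events)
  counts <- res$counts
  rownames(counts) <- nm
  win <- t_end - res$avg_start
  if (!is.finite(win) || win < 0) win <- 0
  avg_norm <- function(a, w) if (w > 0) a / w else rep(NA_real_, length(a))
  avg <- stats::setNames(avg_norm(res$acc_full, win), nm)
  avg1 <- stats::setNames(avg_norm(res$acc_h1, win / 2), nm)
  avg2 <- stats::setNames(avg_norm(res$acc_h2, win / 2), nm)
  structure(list(
    times = sample_times, counts = counts,
    t_final = res$t_final,
    status = c("done", "stopped_on_pair", "stalled", "event_cap")[res$status + 1L],
    stop_time = res$stop_time,
    avg = avg, avg_first_half = avg1, avg_second_half = avg2,
    hop_events = res$hop_events,
    uni_events = stats::setNames(res$uni_events,
                                 vapply(net$unimolecular, function(u)
                                   paste0(u$reactant, "->", u$product), character(1))),
    pair_events = stats::setNames(res$pair_events,
                                  vapply(net$pairwise, function(p)
                                    paste0(p$reactant_a, "+", p$reactant_b), character(1))),
    events = res$events,
    final_species = res$final_species + 1L,
    final_pos = res$final_pos,
    track = if (is.null(track_molecule)) NULL else res$track,
    world = world
  ), class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("Trajectory: t = %.4g s, %.3g events (%.3g hops), status %s\n",
              x$t_final, x$events, x$hop_events, x$status))
  if (length(x$pair_events))
    cat("  pairwise events:",
        paste(sprintf("%s: %g", names(x$pair_events), x$pair_events),
              collapse = ", "), "\n")
  invisible(x)
}

#' Run an ensemble of independent trajectories
#'
#' Trajectory `k` is seeded deterministically with `base_seed + k - 1`
#' (`set.seed`, then world construction, optional state initialization and
#' simulation all consume that one stream), so ensembles are reproducible
#' bit-for-bit and two ensembles sharing `base_seed` are pairwise coupled by
#' common random numbers.
#'
#' @param domain,network Passed to [build_world()].
#' @param t_end,sample_times,avg_start,stop_on_first_pair,max_events Passed
#'   to [simulate_world()].
#' @param n_trajectories Number of independent trajectories.
#' @param base_seed Integer base seed.
#' @param counts Optional named count overrides for [build_world()].
#' @param init Optional `function(world)` applied after world construction
#'   (e.g. warm-starting modification states); it may use the trajectory's
#'   RNG stream.
#' @return Object of class `ensemble_summary`: per-trajectory time-averaged
#'   counts (`avg`, matrices n_trajectories x species, with halves), stop
#'   times, mean sampled counts with standard errors, and event totals.
#' @export
run_ensemble <- function(domain, network, t_end, n_trajectories, base_seed,
                         sample_times = numeric(0), avg_start = t_end,
                         stop_on_first_pair = FALSE, counts = NULL,
                         init = NULL, max_events = 1e12) {
  stopifnot(n_trajectories >= 1)
  nm <- network$species_names
  S <- length(nm)
  nT <- length(sample_times)
  avg <- avg1 <- avg2 <- matrix(NA_real_, n_trajectories, S,
                                dimnames = list(NULL, nm))
  stop_times <- rep(NA_real_, n_trajectories)
  statuses <- character(n_trajectories)
  csum <- matrix(0, S, nT); csum2 <- matrix(0, S, nT)
  events <- 0
  for (k in seq_len(n_trajectories)) {
    set.seed(base_seed + k - 1L)
    ## count-rounding warnings are identical across trajectories: keep the
    ## first, muffle the repeats
    w <- withCallingHandlers(
      build_world(domain, network, counts = counts),
      reachsim_count_rounding = function(wc) {
        if (k > 1) invokeRestart("muffleWarning")
      })
    if (!is.null(init)) w <- init(w)
    tr <- simulate_world(w, t_end, sample_times = sample_times,
                         stop_on_first_pair = stop_on_first_pair,
                         avg_start = avg_start, max_events = max_events)
    avg[k, ] <- tr$avg; avg1[k, ] <- tr$avg_first_half
    avg2[k, ] <- tr$avg_second_half
    stop_times[k] <- tr$stop_time
    statuses[k] <- tr$status
    if (nT) { csum <- csum + tr$counts; csum2 <- csum2 + tr$counts^2 }
    events <- events + tr$events
  }
  mean_counts <- if (nT) csum / n_trajectories else NULL
  se_counts <- if (nT && n_trajectories > 1) {
    sqrt(pmax(csum2 / n_trajectories - mean_counts^2, 0) / (n_trajectories - 1))
  } else NULL
  if (nT) rownames(mean_counts) <- nm
  structure(list(
    n_trajectories = n_trajectories, base_seed = base_seed,
    species = nm, sample_times = sample_times,
    avg = avg, avg_first_half = avg1, avg_second_half = avg2,
    stop_times = stop_times, statuses = statuses,
    mean_counts = mean_counts, se_counts = se_counts,
    events = events
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble: %d trajectories (base seed %d), %.3g events total\n",
              x$n_trajectories, x$base_seed, x$events))
  if (all(!is.na(x$stop_times))) {
    cat(sprintf("  stop times: mean %.4g s, SE %.3g s\n",
                mean(x$stop_times), stats::sd(x$stop_times) / sqrt(length(x$stop_times))))
  } else if (any(!is.na(x$avg))) {
    m <- colMeans(x$avg)
    cat("  window-averaged counts:",
        paste(sprintf("%s=%.3g", names(m), m), collapse = ", "), "\n")
  }
  invisible(x)
}
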