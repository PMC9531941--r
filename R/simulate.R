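# Synthetic multi-region datasets with planted, optionally nested state
# boundaries. Regions carry piecewise-constant multi-voxel patterns; regions
# in the same network share a tunable fraction of their boundaries, and
# event boundaries are a subset of the slowest network's boundaries.

#' Simulation configuration
#'
#' @param n_timepoints number of TRs (default 193, a typical short movie
#'   scan).
#' @param tr repetition time in seconds (default 2.47).
#' @param n_voxels_per_region voxels per simulated region (default 40,
#'   a mid-sized searchlight).
#' @param n_regions number of regions (default 4).
#' @param n_networks number of networks regions are assigned to
#'   round-robin (default 2).
#' @param states_per_region inclusive range (length-2) of the number of
#'   states per region (default `c(10, 20)`).
#' @param nestedness probability in `[0, 1]` that a slower region's
#'   boundary is copied from the fastest region of its network (default
#'   0.5, a partially nested hierarchy).
#' @param noise_sd SD of the additive Gaussian noise relative to the unit
#'   SD of the state patterns (default 1).
#' @param ar_coef optional AR(1) coefficient of the noise (default 0 =
#'   white).
#' @param n_subjects number of subjects (default 20).
#' @param hrf_convolve convolve the noiseless pattern course with the
#'   canonical HRF before adding noise (default FALSE).
#' @param event_fraction fraction of the slowest region's boundaries that
#'   become event boundaries (default 0.5).
#' @param min_state_len minimum state length in TRs (default 2; length-1
#'   states leave within-state correlations undefined in the t-distance).
#' @param seed integer seed making the whole dataset reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 193, tr = 2.47, n_voxels_per_region = 40,
                       n_regions = 4, n_networks = 2,
                       states_per_region = c(10, 20), nestedness = 0.5,
                       noise_sd = 1, ar_coef = 0, n_subjects = 20,
                       hrf_convolve = FALSE, event_fraction = 0.5,
                       min_state_len = 2, seed = 1) {
  cfg <- list(n_timepoints = as.integer(n_timepoints), tr = tr,
              n_voxels_per_region = as.integer(n_voxels_per_region),
              n_regions = as.integer(n_regions), n_networks = as.integer(n_networks),
              states_per_region = as.integer(rep_len(states_per_region, 2L)),
              nestedness = nestedness, noise_sd = noise_sd, ar_coef = ar_coef,
              n_subjects = as.integer(n_subjects), hrf_convolve = isTRUE(hrf_convolve),
              event_fraction = event_fraction, min_state_len = as.integer(min_state_len),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_timepoints < 4L) stop("need at least 4 timepoints")
    if (n_voxels_per_region < 2L) stop("need at least 2 voxels per region")
    if (states_per_region[1L] < 2L) stop("states_per_region must be at least 2")
    if (states_per_region[2L] < states_per_region[1L]) stop("invalid states_per_region range")
    if (states_per_region[2L] > n_timepoints / 2)
      stop("infeasible configuration: states_per_region exceeds n_timepoints / 2")
    if (nestedness < 0 || nestedness > 1) stop("nestedness must be in [0, 1]")
    if (noise_sd < 0) stop("noise_sd must be nonnegative")
    if (n_regions < 1L || n_networks < 1L || n_subjects < 1L) stop("counts must be positive")
    if (event_fraction <= 0 || event_fraction > 1) stop("event_fraction must be in (0, 1]")
  })
  invisible(cfg)
}

# Draw `k` boundary locations in [min_len + 1, n - min_len + 1] keeping all
# states at least `min_len` TRs long, given already-fixed locations.
draw_boundaries <- function(k, n, existing = integer(), min_len = 2L, max_tries = 50L) {
  lo <- min_len + 1L; hi <- n - min_len + 1L
  for (try in seq_len(max_tries)) {
    chosen <- sort(existing)
    ok <- TRUE
    for (i in seq_len(k)) {
      allowed <- setdiff(lo:hi, unlist(lapply(chosen, function(b) (b - min_len + 1L):(b + min_len - 1L))))
      if (!length(allowed)) { ok <- FALSE; break }
      chosen <- sort(c(chosen, allowed[sample.int(length(allowed), 1L)]))
    }
    if (ok) return(setdiff(chosen, existing))
  }
  stop("infeasible configuration: could not place boundaries with the requested spacing")
}

#' Generate planted ground-truth boundaries
#'
#' Regions are assigned to networks round-robin and each draws its number
#' of states from `states_per_region`. Within a network the region with the
#' most states (the fastest) draws its boundaries first; each boundary of a
#' slower region is copied from that reference set with probability
#' `nestedness` and drawn fresh otherwise. Event boundaries are a random
#' `event_fraction` subset of the boundaries of the slowest region of the
#' slowest network, so every event boundary coincides with a region
#' boundary.
#'
#' @param cfg a [sim_config()].
#' @return Object of class `ground_truth` with fields `n_timepoints`, `tr`,
#'   `regions` (list of sorted boundary TR indices), `network_assignment`,
#'   `event_boundaries`, and per-region pattern seeds.
#' @export
generate_ground_truth <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_timepoints
    pattern_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_regions)
    k_per_region <- resample(seq(cfg$states_per_region[1L], cfg$states_per_region[2L]),
                             cfg$n_regions, replace = TRUE)
    network <- rep_len(seq_len(cfg$n_networks), cfg$n_regions)
    regions <- vector("list", cfg$n_regions)
    ref_set <- vector("list", cfg$n_networks)   # fastest region's boundaries per network
    for (net in seq_len(cfg$n_networks)) {
      members <- which(network == net)
      members <- members[order(-k_per_region[members])]   # fastest first
      for (m in seq_along(members)) {
        r <- members[m]
        nb <- k_per_region[r] - 1L
        if (m == 1L) {
          regions[[r]] <- sort(draw_boundaries(nb, n, min_len = cfg$min_state_len))
          ref_set[[net]] <- regions[[r]]
        } else {
          n_nested <- stats::rbinom(1L, nb, cfg$nestedness)
          n_nested <- min(n_nested, length(ref_set[[net]]))
          nested <- if (n_nested > 0L)
            sort(resample(ref_set[[net]], n_nested)) else integer()
          fresh <- if (nb - n_nested > 0L)
            draw_boundaries(nb - n_nested, n, existing = nested,
                            min_len = cfg$min_state_len) else integer()
          regions[[r]] <- sort(c(nested, fresh))
        }
      }
    }
    mean_k_net <- vapply(seq_len(cfg$n_networks),
                         function(net) mean(k_per_region[network == net]), numeric(1))
    slow_net <- which.min(mean_k_net)
    slow_members <- which(network == slow_net)
    slow_region <- slow_members[which.min(k_per_region[slow_members])]
    src <- regions[[slow_region]]
    n_ev <- max(1L, ceiling(cfg$event_fraction * length(src)))
    events <- sort(resample(src, n_ev))
    names(regions) <- paste0("region", seq_len(cfg$n_regions))
    structure(list(n_timepoints = n, tr = cfg$tr, regions = regions,
                   k_per_region = k_per_region, network_assignment = network,
                   event_boundaries = events, pattern_seeds = pattern_seeds,
                   slowest_region = slow_region),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> n = %d TRs, %d region(s) in %d network(s), %d event boundaries\n",
              x$n_timepoints, length(x$regions), max(x$network_assignment),
              length(x$event_boundaries)))
  invisible(x)
}

#' Binary boundary series of a planted region
#'
#' @param gt a [generate_ground_truth()] result.
#' @param region_id region index.
#' @return A binary [boundary_series()].
#' @export
gt_boundary_series <- function(gt, region_id) {
  if (region_id < 1L || region_id > length(gt$regions)) stop("unknown region_id")
  v <- numeric(gt$n_timepoints)
  v[gt$regions[[region_id]]] <- 1
  boundary_series(v, names(gt$regions)[region_id])
}

#' Simulate one subject's data for one region
#'
#' Each state gets one mean pattern with iid standard-normal voxel values
#' (shared across subjects via the ground truth's per-region pattern seed),
#' held constant across the state's timepoints. Optionally the noiseless
#' pattern course is convolved with the canonical HRF; Gaussian noise with
#' SD `noise_sd` (optionally AR(1)) is then added per timepoint and voxel.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param region_id region index.
#' @param cfg the [sim_config()] used for `gt`.
#' @param subject_seed integer seed for this subject's noise.
#' @return A [bold_matrix()] of `n_timepoints` x `n_voxels_per_region`.
#' @export
generate_subject_data <- function(gt, region_id, cfg, subject_seed) {
  if (region_id < 1L || region_id > length(gt$regions)) stop("unknown region_id")
  n <- gt$n_timepoints; v <- cfg$n_voxels_per_region
  seg <- segmentation(n, gt$regions[[region_id]])
  lab <- state_labels(seg)
  pats <- with_seed(gt$pattern_seeds[region_id],
                    matrix(stats::rnorm(seg$k * v), seg$k, v))
  signal <- pats[lab, , drop = FALSE]
  if (cfg$hrf_convolve)
    signal <- convolve_hrf(bold_matrix(signal, gt$tr), canonical_hrf(gt$tr))$values
  noise <- with_seed(subject_seed, {
    if (cfg$ar_coef > 0) {
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar_coef^2)
      apply(matrix(stats::rnorm(n * v, sd = innov_sd), n, v), 2L,
            function(w) as.numeric(stats::filter(w, cfg$ar_coef, method = "recursive")))
    } else matrix(stats::rnorm(n * v, sd = cfg$noise_sd), n, v)
  })
  bold_matrix(signal + noise, gt$tr)
}

#' Generate a full multi-region, multi-subject dataset
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory; when given, per-subject 4-D NIfTI volumes
#'   (regions tiled along the second axis), a 3-D region label NIfTI, an
#'   events TSV (`onset_s`, `salience`) and the ground truth as JSON are
#'   written there.
#' @return List with `ground_truth`, `data` (list: region, then subject, of
#'   [bold_matrix()]), `events` (data frame `onset_s`, `salience`),
#'   `subject_seeds`, and `paths` when files were written.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  gt <- generate_ground_truth(cfg)
  aux <- with_seed(cfg$seed + 1L, list(
    subject_seeds = sample.int(.Machine$integer.max - 1L, cfg$n_subjects),
    salience = sample(5:16, length(gt$event_boundaries), replace = TRUE)))
  data <- lapply(seq_len(cfg$n_regions), function(r)
    lapply(aux$subject_seeds, function(s) generate_subject_data(gt, r, cfg, s)))
  names(data) <- names(gt$regions)
  # mid-TR onsets round-trip exactly through floor(onset / tr) + 1
  events <- data.frame(onset_s = (gt$event_boundaries - 0.5) * gt$tr,
                       salience = aux$salience)
  out <- list(ground_truth = gt, data = data, events = events,
              subject_seeds = aux$subject_seeds)
  if (!is.null(dir)) out$paths <- write_dataset(out, cfg, dir)
  out
}

#' Mean pairwise relative overlap between planted regions
#'
#' Convenience summary used to check that boundary sharing between regions
#' grows with the nestedness parameter.
#'
#' @param gt a [generate_ground_truth()] result.
#' @return Mean of the off-diagonal pairwise relative overlaps.
#' @export
gt_mean_pairwise_or <- function(gt) {
  series <- lapply(seq_along(gt$regions), function(r) gt_boundary_series(gt, r))
  m <- pairwise_overlap_matrix(series)
  mean(m[lower.tri(m)], na.rm = TRUE)
}
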