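test_that("ground truth generation honours nesting, events, and determinism", {
  cfg <- sim_config(n_timepoints = 100, n_regions = 2, n_networks = 1,
                    states_per_region = c(8, 8), nestedness = 1, seed = 5)
  gt <- generate_ground_truth(cfg)
  # full nesting + equal state counts forces identical boundary sets
  expect_identical(gt$regions[[1]], gt$regions[[2]])
  # determinism
  expect_identical(generate_ground_truth(cfg), gt)
  # invariants: boundaries sorted, within [2, n], min state length respected
  for (b in gt$regions) {
    expect_true(all(diff(b) >= cfg$min_state_len))
    expect_true(all(b >= 2 & b <= 100))
  }
  # events are a subset of a region's boundaries
  expect_true(all(gt$event_boundaries %in% gt$regions[[gt$slowest_region]]))

  expect_error(sim_config(n_timepoints = 20, states_per_region = c(11, 12)),
               "infeasible")
})

test_that("independent regions share about the chance number of boundaries", {
  # closed-form expectation under independence: (1/n) * sum(E) * sum(S)
  n <- 100; k <- 8
  shared <- vapply(1:500, function(s) {
    gt <- generate_ground_truth(sim_config(n_timepoints = n, n_regions = 2,
                                           n_networks = 1,
                                           states_per_region = c(k, k),
                                           nestedness = 0, seed = s))
    length(intersect(gt$regions[[1]], gt$regions[[2]]))
  }, numeric(1))
  expected <- (k - 1)^2 / n
  # spacing constraints shrink the effective position pool a little, so
  # allow a generous band around the unconstrained expectation
  expect_lt(abs(mean(shared) - expected), 0.35 * expected)
})

test_that("subject data are piecewise-constant patterns plus subject noise", {
  cfg <- sim_config(n_timepoints = 60, n_voxels_per_region = 40, n_regions = 2,
                    n_networks = 2, states_per_region = c(4, 6), noise_sd = 0,
                    n_subjects = 2, seed = 9)
  gt <- generate_ground_truth(cfg)
  x <- generate_subject_data(gt, 1, cfg, subject_seed = 77)
  lab <- state_labels(segmentation(60, gt$regions[[1]]))
  # exactly piecewise-constant across the planted boundaries
  for (s in unique(lab)) {
    rows <- x$values[lab == s, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(col) diff(range(col)))), 0)
  }
  # GSBS recovers every planted boundary exactly on noiseless data
  fit <- gsbs(x, k_max = 15)
  expect_equal(fit$segmentation$boundaries, gt$regions[[1]])
  expect_equal(fit$optimum_k, length(gt$regions[[1]]) + 1L)

  # two subjects differ only in the noise component: the signal part is a
  # function of the ground truth alone
  expect_identical(generate_subject_data(gt, 1, cfg, subject_seed = 1)$values,
                   generate_subject_data(gt, 1, cfg, subject_seed = 2)$values)
  cfg2 <- sim_config(n_timepoints = 60, n_voxels_per_region = 40, n_regions = 2,
                     n_networks = 2, states_per_region = c(4, 6), noise_sd = 1,
                     n_subjects = 2, seed = 9)
  a <- generate_subject_data(gt, 1, cfg2, subject_seed = 1)
  b <- generate_subject_data(gt, 1, cfg2, subject_seed = 2)
  expect_false(isTRUE(all.equal(a$values, b$values)))
  noise_a <- a$values - x$values   # x is the noiseless realization
  noise_b <- b$values - x$values
  expect_equal(sd(noise_a), 1, tolerance = 0.1)
  expect_lt(abs(cor(as.vector(noise_a), as.vector(noise_b))), 0.1)

  expect_error(generate_subject_data(gt, 99, cfg, 1), "unknown region_id")
})

test_that("HRF convolution blurs the pattern course before noise", {
  cfg <- sim_config(n_timepoints = 60, n_voxels_per_region = 8, n_regions = 1,
                    n_networks = 1, states_per_region = c(4, 4), noise_sd = 0,
                    hrf_convolve = TRUE, seed = 12)
  gt <- generate_ground_truth(cfg)
  x <- generate_subject_data(gt, 1, cfg, 5)
  cfg0 <- sim_config(n_timepoints = 60, n_voxels_per_region = 8, n_regions = 1,
                     n_networks = 1, states_per_region = c(4, 4), noise_sd = 0,
                     hrf_convolve = FALSE, seed = 12)
  x0 <- generate_subject_data(gt, 1, cfg0, 5)
  expect_equal(x$values, convolve_hrf(x0, canonical_hrf(cfg$tr))$values,
               tolerance = 1e-10)
})

test_that("datasets assemble regions, subjects and events coherently", {
  cfg <- sim_config(n_timepoints = 80, n_voxels_per_region = 6, n_regions = 4,
                    n_networks = 2, states_per_region = c(5, 8), noise_sd = 0.5,
                    n_subjects = 3, seed = 31)
  ds <- generate_dataset(cfg)
  expect_length(ds$data, 4)
  expect_length(ds$data[[1]], 3)
  expect_equal(sort(unique(ds$ground_truth$network_assignment)), 1:2)
  # events TSV round-trips through events_to_series onto the planted TRs
  e <- events_to_series(ds$events$onset_s, ds$events$salience,
                        tr = cfg$tr, n = cfg$n_timepoints)
  expect_equal(which(e$values > 0), ds$ground_truth$event_boundaries)
  # determinism of the whole dataset
  ds2 <- generate_dataset(cfg)
  expect_equal(ds$data[[2]][[3]]$values, ds2$data[[2]][[3]]$values)
})

test_that("group averaging reduces noise variance by the group size", {
  cfg <- sim_config(n_timepoints = 60, n_voxels_per_region = 10, n_regions = 1,
                    n_networks = 1, states_per_region = c(4, 4), noise_sd = 2,
                    n_subjects = 20, seed = 44)
  gt <- generate_ground_truth(cfg)
  lab <- state_labels(segmentation(60, gt$regions[[1]]))
  noise_var <- function(x) {
    sm <- rowsum(x$values, lab) / as.vector(table(lab))
    # residual variance about per-state means, correcting for the mean fit
    resid <- x$values - sm[lab, ]
    sum(resid^2) / (length(resid) - 10 * length(unique(lab)))
  }
  set.seed(1)
  reps <- 100
  ratio <- vapply(seq_len(reps), function(i) {
    xs <- lapply(1:20, function(s) generate_subject_data(gt, 1, cfg, i * 100 + s))
    noise_var(group_average(xs)) / mean(vapply(xs, noise_var, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1 / 20), 0.05 / 20)
})

test_that("boundary sharing increases monotonically with nestedness", {
  or_at <- function(nest) {
    mean(vapply(1:20, function(s) {
      gt <- generate_ground_truth(sim_config(n_timepoints = 150, n_regions = 4,
                                             n_networks = 1,
                                             states_per_region = c(10, 14),
                                             nestedness = nest, seed = 500 + s))
      gt_mean_pairwise_or(gt)
    }, numeric(1)))
  }
  ors <- c(or_at(0), or_at(0.5), or_at(1))
  expect_true(all(diff(ors) > 0))
  expect_lt(abs(ors[1]), 0.15)
  expect_gt(ors[3], 0.5)
})
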