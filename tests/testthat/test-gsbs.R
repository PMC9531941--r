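test_that("state means and fit score match direct arithmetic", {
  set.seed(10)
  X <- matrix(rnorm(18), 6, 3)
  seg <- segmentation(6, c(3, 5))
  m <- state_means(X, seg)
  expect_equal(m[1, ], colMeans(X[1:2, ]))
  expect_equal(m[2, ], colMeans(X[3:4, ]))
  expect_equal(m[3, ], colMeans(X[5:6, ]))
  expect_equal(state_means(X, segmentation(6))[1, ], colMeans(X))

  # noiseless piecewise-constant data: perfect fit at the true boundaries
  Xc <- piecewise_data(30, 8, c(11, 23))
  expect_equal(fit_score(Xc, segmentation(30, c(11, 23))), 1)
  expect_lt(fit_score(Xc, segmentation(30, c(12, 23))), 1)
  expect_equal(unname(state_means(Xc, segmentation(30, c(11, 23)))),
               unname(Xc[c(1, 11, 23), ]))

  # scale invariance, and equality with the looped oracle
  set.seed(11)
  Xr <- matrix(rnorm(25 * 6), 25, 6)
  for (b in list(c(7), c(4, 13, 20), c(2, 10, 16, 24))) {
    s <- segmentation(25, b)
    expect_equal(fit_score(Xr, s), oracle_fit_score(Xr, b), tolerance = 1e-12)
    expect_equal(fit_score(3.7 * Xr, s), fit_score(Xr, s), tolerance = 1e-12)
  }
})

test_that("fast candidate-search machinery equals the naive fit definition", {
  set.seed(12)
  X <- matrix(rnorm(40 * 7), 40, 7)
  pre <- neurostates:::gsbs_precompute(X)
  for (b in list(integer(), c(5L), c(3L, 18L, 30L), sort(sample(2:40, 8)))) {
    expect_equal(neurostates:::fit_from_bounds(pre, as.integer(b)),
                 oracle_fit_score(X, b), tolerance = 1e-8)
  }
})

test_that("t-distance equals the brute-force oracle and is voxel-order invariant", {
  set.seed(13)
  X <- matrix(rnorm(10 * 4), 10, 4)
  for (b in list(c(4), c(3, 7), c(2, 5, 8))) {
    seg <- segmentation(10, b)
    expect_equal(t_distance(X, seg), oracle_t_distance(X, b), tolerance = 1e-10)
    perm <- sample(ncol(X))
    expect_equal(t_distance(X[, perm], seg), t_distance(X, seg), tolerance = 1e-12)
  }
  # orthogonal two-pattern data: the correct k = 2 split beats every k = 3 one
  pats <- rbind(c(1, -1, 1, -1, 1, -1), c(1, 1, -1, -1, 1, 1))
  X2 <- pats[rep(1:2, each = 6), ] + 0.01 * matrix(rnorm(72), 12, 6)
  t2 <- t_distance(X2, segmentation(12, 7))
  t3 <- c()
  for (b1 in 2:11) for (b2 in (b1 + 1):12) {
    if (b2 > 12) next
    t3 <- c(t3, t_distance(X2, segmentation(12, c(b1, b2))))
  }
  expect_true(all(t2 > t3[!is.na(t3)]))
  # insufficient pairs propagate as NA, not zero
  expect_true(is.na(t_distance(matrix(rnorm(16), 4, 4), segmentation(4, c(2, 3, 4)))))
})

test_that("boundary strengths are 1 - r of flanking state means", {
  X <- rbind(matrix(1:6, 2, 3, byrow = TRUE),
             matrix(c(2, 4, 6), 2, 3, byrow = TRUE),
             matrix(c(6, 4, 2), 2, 3, byrow = TRUE))
  seg <- segmentation(6, c(3, 5))
  st <- boundary_strengths(X, seg)
  expect_equal(st[1], 0)            # identical up to scale: r = 1
  expect_equal(st[2], 2)            # exactly opposite pattern: r = -1
  set.seed(14)
  Xr <- piecewise_data(18, 5, c(7, 13))
  m <- state_means(Xr, segmentation(18, c(7, 13)))
  expect_equal(boundary_strengths(Xr, segmentation(18, c(7, 13))),
               c(1 - cor(m[1, ], m[2, ]), 1 - cor(m[2, ], m[3, ])))
  expect_error(boundary_strengths(Xr, segmentation(18)), "no boundaries")
})

test_that("noiseless data is recovered exactly, with the planted k", {
  # small case: 3 states, 10 voxels
  X3 <- piecewise_data(30, 10, c(11, 21), seed = 40)
  fit3 <- gsbs(X3, k_max = 10, tr = 1)
  expect_equal(fit3$optimum_k, 3L)
  expect_equal(fit3$segmentation$boundaries, c(11L, 21L))

  # richer case: 6 states, realistic searchlight-sized voxel count
  for (seed in 1:3) {
    set.seed(100 + seed)
    bounds <- sort(sample(seq(3, 58, by = 4), 5)) + seed
    X <- piecewise_data(60, 40, bounds, seed = seed)
    fit <- gsbs(X, k_max = 15, tr = 1)
    expect_equal(fit$optimum_k, length(bounds) + 1)
    expect_equal(fit$segmentation$boundaries, as.integer(bounds))
    expect_equal(fit_score(X, fit$segmentation), 1, tolerance = 1e-10)
  }
})

test_that("search output nests across iterations and fit is monotone on noiseless data", {
  X <- piecewise_data(48, 8, c(9, 17, 30, 41), seed = 7)
  res <- place_boundaries(X, k_max = 12, tr = 1)
  segs <- res$segmentations
  for (i in seq_len(length(segs) - 1)) {
    prev <- segs[[i]]$boundaries
    nxt <- segs[[i + 1]]$boundaries
    # every earlier boundary persists, possibly shifted by 1 by fine-tuning
    expect_true(all(vapply(prev, function(b) any(abs(nxt - b) <= 1), logical(1))))
  }
  expect_true(all(diff(res$fits) > -1e-10))
})

test_that("reduced mode reproduces the classic single-boundary greedy search", {
  set.seed(15)
  X <- piecewise_data(24, 6, c(8, 15, 20), noise_sd = 0.4, seed = 21)
  res <- place_boundaries(X, k_max = 5, finetune = FALSE, pair_search = FALSE, tr = 1)
  ref <- oracle_greedy_single(X, 5)
  expect_equal(res$segmentations[[length(res$segmentations)]]$boundaries,
               as.integer(ref))
})

test_that("select_k maximizes t-distance with ties toward smaller k", {
  expect_equal(select_k(tdistance_curve(4, 2.2)), 4L)
  expect_equal(select_k(tdistance_curve(c(2, 3, 4), c(1, 5, 4))), 3L)
  expect_equal(select_k(tdistance_curve(c(2, 3, 4), c(1, 5, 5))), 3L)
  expect_equal(select_k(tdistance_curve(c(1, 2, 3), c(NA, 1, 2))), 3L)
  expect_error(select_k(tdistance_curve(c(1, 2), c(NA, NA))), "undefined")
})

test_that("voxel permutation changes no output of the full search", {
  set.seed(16)
  X <- piecewise_data(40, 9, c(10, 22, 31), noise_sd = 0.3, seed = 9)
  fit1 <- gsbs(X, k_max = 10, tr = 1)
  fit2 <- gsbs(X[, sample(9)], k_max = 10, tr = 1)
  expect_equal(fit1$segmentation$boundaries, fit2$segmentation$boundaries)
  expect_equal(fit1$curve$tdist, fit2$curve$tdist, tolerance = 1e-9)
})

test_that("state duration summaries follow the quantile convention", {
  seg <- segmentation(10, c(3, 6))         # lengths 2, 3, 5
  out <- state_duration_summary(seg, 2.47)
  expect_equal(out$median_duration_s, 3 * 2.47)
  eq <- segmentation(9, c(4, 7))           # lengths 3, 3, 3
  expect_equal(state_duration_summary(eq, 1)$iqr_over_median, 0)
  seg2 <- segmentation(16, c(3, 5, 9))     # lengths 2, 2, 4, 8
  out2 <- state_duration_summary(seg2, 1)
  expect_equal(out2$median_duration_s, 3)
  # independent percentile computation (linear interpolation)
  q <- unname(quantile(c(2, 2, 4, 8), c(0.25, 0.75)))
  expect_equal(out2$iqr_over_median, (q[2] - q[1]) / 3)
})
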