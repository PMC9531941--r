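test_that("event onsets map to the TR containing them", {
  s <- events_to_series(10, 16, tr = 2.47, n = 20)
  expect_equal(which(s$values > 0), floor(10 / 2.47) + 1)   # TR 5
  expect_equal(sum(events_to_series(c(5, 9), c(4, 3), tr = 2.47, n = 20)$values), 0)
  two <- events_to_series(c(10.0, 11.5), c(8, 9), tr = 2.47, n = 20)
  expect_equal(sum(two$values), 1)                          # same TR collapses
  expect_error(events_to_series(60, 10, tr = 2.47, n = 20), "outside")
})

test_that("expected overlap follows the independence formula", {
  a <- boundary_series(c(0, 1, 0, 1, 0, 0))
  b <- boundary_series(c(0, 1, 1, 0, 0, 1))
  expect_equal(expected_overlap(a, b), 2 * 3 / 6)
  expect_equal(expected_overlap(a, boundary_series(numeric(6))), 0)
  aw <- boundary_series(3 * a$values)
  expect_equal(expected_overlap(aw, b), 3 * expected_overlap(a, b))
  expect_error(expected_overlap(a, boundary_series(c(0, 1))), "lengths differ")
})

test_that("absolute overlap is 1 at perfect alignment and 0 at chance", {
  e <- boundary_series(c(0, 1, 0, 1))
  expect_equal(absolute_overlap(e, boundary_series(c(0, 1, 0, 1)))$absolute, 1)
  r <- absolute_overlap(e, boundary_series(c(0, 1, 1, 0)))
  expect_equal(r$raw, 1); expect_equal(r$expected, 1); expect_equal(r$absolute, 0)
  # hand evaluation of the printed formula
  e6 <- boundary_series(c(0, 1, 0, 0, 0, 0))
  s6 <- boundary_series(c(0, 1, 0, 1, 0, 1))
  expect_equal(absolute_overlap(e6, s6)$absolute, (1 - 0.5) / (3 - 0.5))
  expect_warning(absolute_overlap(e6, boundary_series(numeric(6))), "undefined")
})

test_that("relative overlap is symmetric and 1 when the smaller set is covered", {
  a <- boundary_series(c(0, 1, 0, 0, 0, 0))
  b <- boundary_series(c(0, 1, 0, 1, 0, 1))
  expect_equal(relative_overlap(a, b)$relative, 1)
  set.seed(20)
  for (i in 1:200) {
    x <- random_binary_series(25, sample(2:8, 1))
    y <- random_binary_series(25, sample(2:8, 1))
    or_xy <- suppressWarnings(relative_overlap(x, y)$relative)
    expect_identical(or_xy, suppressWarnings(relative_overlap(y, x)$relative))
    if (!is.na(or_xy)) {
      expect_lte(or_xy, 1 + 1e-12)
      O <- sum(x$values * y$values)
      if (or_xy == 1) expect_equal(O, min(sum(x$values), sum(y$values)))
    }
  }
})

test_that("overlap statistics are null-calibrated for independent series", {
  set.seed(21)
  n <- 40; draws <- 10000
  oa <- or_ <- numeric(draws)
  for (i in seq_len(draws)) {
    e <- random_binary_series(n, 6)
    s <- random_binary_series(n, 10)
    oa[i] <- absolute_overlap(e, s)$absolute
    or_[i] <- relative_overlap(e, s)$relative
  }
  expect_lt(abs(mean(oa)), 0.01)
  expect_lt(abs(mean(or_)), 0.01)
})

test_that("strength weighting preserves the overlap identities", {
  s <- boundary_series(c(0, 1, 0, 1, 0, 1, 0, 0))
  e <- boundary_series(c(0, 1, 0, 0, 0, 1, 0, 0))
  expect_equal(weight_by_strength(s, c(1, 1, 1))$values, s$values)
  # uniform weights leave OA unchanged (scale cancels in the formula)
  oa_bin <- absolute_overlap(e, s)$absolute
  oa_unif <- absolute_overlap(e, weight_by_strength(s, c(0.37, 0.37, 0.37)))$absolute
  expect_equal(oa_unif, oa_bin, tolerance = 1e-12)
  # concentrating strength on event-coinciding marks raises OA
  oa_conc <- absolute_overlap(e, weight_by_strength(s, c(1.5, 0.1, 1.5)))$absolute
  expect_gt(oa_conc, oa_bin)
  expect_error(weight_by_strength(s, c(1, 2)), "one strength per boundary")
})

test_that("co-occurrence weighting uses the scope proportion", {
  s1 <- boundary_series(c(0, 1, 0, 1, 0))
  s2 <- boundary_series(c(0, 1, 0, 0, 0))
  s3 <- boundary_series(c(0, 1, 0, 1, 0))
  all_s <- list(s1, s2, s3)
  w_self <- weight_by_cooccurrence(s1, all_s, scope = 1)
  expect_equal(w_self$values[c(2, 4)], c(1, 1))
  w_all <- weight_by_cooccurrence(s1, all_s, scope = 1:3)
  expect_equal(w_all$values[c(2, 4)], c(1, 2 / 3))
  expect_error(weight_by_cooccurrence(s1, all_s, scope = integer()), "empty scope")
  # three-searchlight toy OA against hand evaluation
  e <- boundary_series(c(0, 1, 0, 0, 0))
  v <- w_all$values               # (0, 1, 0, 2/3, 0)
  O <- sum(e$values * v); OE <- sum(e$values) * sum(v) / 5
  expect_equal(absolute_overlap(e, w_all)$absolute, (O - OE) / (sum(v) - OE))
})

test_that("shared/unique decomposition conserves both inputs", {
  si <- boundary_series(c(0, 1, 1, 0))
  sj <- boundary_series(c(0, 1, 0, 1))
  d <- shared_unique_decomposition(si, sj)
  expect_equal(d$shared$values, c(0, 1, 0, 0))
  expect_equal(d$unique_i$values, c(0, 0, 1, 0))
  expect_equal(d$unique_j$values, c(0, 0, 0, 1))
  set.seed(22)
  for (i in 1:1000) {
    x <- random_binary_series(30, sample(2:10, 1))
    y <- random_binary_series(30, sample(2:10, 1))
    d <- shared_unique_decomposition(x, y)
    expect_identical(d$shared$values + d$unique_i$values, x$values)
    expect_identical(d$shared$values + d$unique_j$values, y$values)
  }
  expect_error(shared_unique_decomposition(boundary_series(c(0, 0.5, 0, 0)), sj),
               "binary")
})

test_that("shared-vs-unique statistic rewards event-aligned shared boundaries", {
  # shared marks on events, unique marks off events
  e  <- boundary_series(c(0, 1, 0, 1, 0, 0, 0, 0, 0, 0))
  si <- boundary_series(c(0, 1, 0, 1, 0, 1, 0, 0, 1, 0))
  sj <- boundary_series(c(0, 1, 0, 1, 0, 0, 1, 0, 0, 1))
  stat <- shared_vs_unique_statistic(e, si, sj)
  d <- shared_unique_decomposition(si, sj)
  oa_u <- max(absolute_overlap(e, d$unique_i)$absolute,
              absolute_overlap(e, d$unique_j)$absolute)
  expect_equal(stat, 1 - oa_u)
  expect_gt(stat, 0)
  expect_equal(shared_vs_unique_statistic(e, sj, si), stat)   # symmetric
  # empty decomposed series propagates as NA
  expect_true(is.na(shared_vs_unique_statistic(e, si, si)))
})

test_that("pairwise overlap matrices are symmetric and self-consistent", {
  set.seed(23)
  series <- lapply(1:5, function(i) random_binary_series(30, 6))
  m <- pairwise_overlap_matrix(series)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 5))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(m[i, j],
                 suppressWarnings(relative_overlap(series[[i]], series[[j]])$relative))
  ident <- pairwise_overlap_matrix(lapply(1:3, function(i) series[[1]]))
  expect_true(all(ident == 1))
})

test_that("matrix similarity correlates lower triangles", {
  set.seed(24)
  m1 <- matrix(rnorm(16), 4); m1 <- (m1 + t(m1)) / 2
  expect_equal(matrix_similarity(m1, m1), 1)
  expect_equal(matrix_similarity(m1, -m1), -1)
  m2 <- matrix(rnorm(16), 4); m2 <- (m2 + t(m2)) / 2
  expect_equal(matrix_similarity(m1, m2),
               cor(m1[lower.tri(m1)], m2[lower.tri(m2)]))
  expect_error(matrix_similarity(m1, matrix(0, 3, 3)), "shape")
})
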