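# Independent oracles used across the suite. Everything here is written
# from first principles (loops, textbook formulas, enumeration) and stays
# independent of the package's computational paths.

# mean over timepoints of cor(timepoint pattern, its state's mean pattern),
# by direct looping
oracle_fit_score <- function(X, bounds) {
  n <- nrow(X)
  lab <- findInterval(seq_len(n), c(1, bounds))
  total <- 0
  for (t in seq_len(n)) {
    idx <- which(lab == lab[t])
    m <- colMeans(X[idx, , drop = FALSE])
    r <- suppressWarnings(cor(X[t, ], m))
    if (is.na(r)) r <- 0
    total <- total + r
  }
  total / n
}

# full correlation matrix, explicit pair collection, textbook pooled t
oracle_t_distance <- function(X, bounds) {
  n <- nrow(X)
  lab <- findInterval(seq_len(n), c(1, bounds))
  CC <- suppressWarnings(cor(t(X)))
  CC[is.na(CC)] <- 0
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (lab[j] == lab[i]) within <- c(within, CC[i, j])
    if (lab[j] == lab[i] + 1) between <- c(between, CC[i, j])
  }
  nw <- length(within); nb <- length(between)
  if (nw < 2 || nb < 2) return(NA_real_)
  sp2 <- ((nw - 1) * var(within) + (nb - 1) * var(between)) / (nw + nb - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(within) - mean(between)) / sqrt(sp2 * (1 / nw + 1 / nb))
}

# classic greedy search: one boundary per iteration, no fine-tuning,
# candidate chosen by the naive fit score (smallest location on ties)
oracle_greedy_single <- function(X, k_max) {
  n <- nrow(X)
  bounds <- integer()
  while (length(bounds) + 1 < k_max) {
    cands <- setdiff(2:n, bounds)
    fits <- vapply(cands, function(p) oracle_fit_score(X, sort(c(bounds, p))), numeric(1))
    bounds <- sort(c(bounds, cands[which.max(fits)]))
  }
  bounds
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  p <- 2 * min(mean(Wnull <= W), mean(Wnull >= W))
  min(1, p)
}

# textbook AMI: explicit contingency table, explicit hypergeometric EMI sum
oracle_ami <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  N <- matrix(0, length(ua), length(ub))
  for (t in seq_len(n))
    N[match(a[t], ua), match(b[t], ub)] <- N[match(a[t], ua), match(b[t], ub)] + 1
  ai <- rowSums(N); bj <- colSums(N)
  MI <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub)) if (N[i, j] > 0)
    MI <- MI + (N[i, j] / n) * log(N[i, j] * n / (ai[i] * bj[j]))
  H <- function(cnt) -sum((cnt / n) * log(cnt / n))
  EMI <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub)) {
    A <- ai[i]; B <- bj[j]
    for (nij in max(1, A + B - n):min(A, B)) {
      if (nij < max(1, A + B - n)) next
      p <- exp(lfactorial(A) + lfactorial(B) + lfactorial(n - A) + lfactorial(n - B) -
               lfactorial(n) - lfactorial(nij) - lfactorial(A - nij) -
               lfactorial(B - nij) - lfactorial(n - A - B + nij))
      EMI <- EMI + p * (nij / n) * log(nij * n / (A * B))
    }
  }
  den <- max(H(ai), H(bj)) - EMI
  if (abs(den) < 1e-12)
    return(if (identical(outer(a, a, `==`), outer(b, b, `==`))) 1 else 0)
  (MI - EMI) / den
}

# random binary boundary series with a fixed number of marks (never at t=1)
random_binary_series <- function(n, n_marks) {
  v <- numeric(n)
  v[sample(2:n, n_marks)] <- 1
  boundary_series(v)
}

# piecewise-constant multi-voxel data with given boundaries
piecewise_data <- function(n, v, bounds, noise_sd = 0, seed = 1) {
  set.seed(seed)
  k <- length(bounds) + 1
  lab <- findInterval(seq_len(n), c(1, bounds))
  pats <- matrix(rnorm(k * v), k, v)
  pats[lab, , drop = FALSE] + matrix(rnorm(n * v, sd = noise_sd), n, v)
}
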