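# Group-level inference: balanced random subject splits, exact Wilcoxon
# signed-rank tests of per-group statistics against zero, BH-FDR, and a
# sign-consistency guard against effects whose pooled and group-average
# signs disagree.

#' Split subjects into balanced random groups
#'
#' @param n_subjects total number of subjects.
#' @param n_groups number of independent groups; sizes differ by at most 1.
#' @param seed integer seed.
#' @return Object of class `group_design` with `assignments` (group id per
#'   subject), `n_groups`, `seed`.
#' @export
split_groups <- function(n_subjects, n_groups, seed = 1) {
  if (n_groups < 1) stop("n_groups must be at least 1")
  if (n_subjects < n_groups) stop("need at least one subject per group")
  assignments <- integer(n_subjects)
  with_seed(seed, {
    assignments[sample.int(n_subjects)] <- rep_len(seq_len(n_groups), n_subjects)
  })
  structure(list(assignments = assignments, n_groups = as.integer(n_groups),
                 seed = as.integer(seed)), class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("<group_design> %d subjects in %d group(s), sizes %s\n",
              length(x$assignments), x$n_groups,
              paste(as.vector(table(x$assignments)), collapse = "/")))
  invisible(x)
}

# cache of exact signed-rank null distributions, keyed by the doubled
# (integer) midrank multiset
.wsr_cache <- new.env(parent = emptyenv())

# exact null of the doubled positive-rank sum 2*W+ by convolution over
# sign assignments; returns probability vector over 0..sum(2r)
wsr_exact_null <- function(r2) {
  key <- paste(sort(r2), collapse = ",")
  hit <- .wsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(r2)
  p <- numeric(total + 1L); p[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), p[seq_len(total + 1L - r)])
    p <- (p + shifted) / 2
  }
  .wsr_cache[[key]] <- p
  p
}

#' Wilcoxon signed-rank test against zero
#'
#' Two-sided test that the values are symmetrically distributed around a
#' nonzero median. Zeros are dropped, ties get midranks, and the null
#' distribution of the positive-rank sum is computed exactly (by
#' convolution over sign assignments, honouring midranks) for up to 25
#' nonzero values; beyond that a normal approximation with continuity and
#' tie correction is used. At least `min_n` nonzero, non-missing values are
#' required, otherwise NA is returned with a message.
#'
#' @param values numeric vector of per-group statistics.
#' @param min_n minimum usable values (default 5).
#' @param exact_max largest n for the exact null (default 25).
#' @return Two-sided p-value (or NA).
#' @export
wilcoxon_signed_rank <- function(values, min_n = 5, exact_max = 25) {
  x <- values[!is.na(values)]
  x <- x[x != 0]
  n <- length(x)
  if (n < min_n) {
    message(sprintf("wilcoxon_signed_rank: only %d usable value(s), need %d; returning NA", n, min_n))
    return(NA_real_)
  }
  r <- rank(abs(x))
  W2 <- sum(2 * r[x > 0])        # doubled statistic keeps midranks integer
  if (n <= exact_max) {
    null <- wsr_exact_null(as.integer(round(2 * r)))
    idx <- seq_along(null) - 1L
    p_lo <- sum(null[idx <= W2])
    p_hi <- sum(null[idx >= W2])
    min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- sum(r) / 2
    sg <- sqrt(sum(r^2)) / 2
    z <- (W2 / 2 - mu - sign(W2 / 2 - mu) * 0.5) / sg
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control at level `q`; missing p-values are excluded from the
#' correction and flagged NA.
#'
#' @param pvals vector of p-values in `[0, 1]`, NA allowed.
#' @param q target false discovery rate (default 0.05).
#' @return List with `significant` (logical, NA where p was NA) and
#'   `critical_p` (the largest p-value that passes; 0 when none do).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  sig <- rep(NA, length(pvals))
  if (any(ok)) {
    adj <- stats::p.adjust(pvals[ok], method = "BH")
    sig[ok] <- adj <= q
  }
  crit <- if (any(ok) && any(sig[ok])) max(pvals[ok][sig[ok]]) else 0
  list(significant = sig, critical_p = crit)
}

#' Sign-consistency guard
#'
#' An effect is only trusted when the sign of the pooled (all-subjects)
#' estimate matches the sign of the mean effect across the independent
#' groups; FDR significance should be vetoed otherwise.
#'
#' @param pooled_effect effect estimated from the pooled analysis.
#' @param group_effects per-group effects (NA dropped).
#' @return TRUE when the signs match; FALSE otherwise (including a zero
#'   group mean, with a message).
#' @export
sign_consistency <- function(pooled_effect, group_effects) {
  if (is.na(pooled_effect)) stop("pooled effect must be defined")
  m <- mean(group_effects, na.rm = TRUE)
  if (is.nan(m) || m == 0) {
    message("sign_consistency: zero/undefined group mean; flagged inconsistent")
    return(FALSE)
  }
  sign(pooled_effect) == sign(m)
}

#' Group-level test of a searchlight statistic
#'
#' Convenience wrapper for the full inference recipe: per searchlight, a
#' Wilcoxon signed-rank test of the per-group values against zero, BH-FDR
#' across searchlights, and the sign-consistency veto against the pooled
#' effects.
#'
#' @param group_values searchlights x groups matrix of the statistic.
#' @param pooled_effects pooled (all-subject) effect per searchlight; when
#'   NULL the per-searchlight group mean is used and the veto never fires.
#' @param q FDR level (default 0.05).
#' @return Data frame with columns `p`, `significant`, `sign_consistent`,
#'   plus attribute `critical_p`.
#' @export
group_test <- function(group_values, pooled_effects = NULL, q = 0.05) {
  group_values <- as.matrix(group_values)
  p <- apply(group_values, 1L, wilcoxon_signed_rank)
  fdr <- fdr_bh(p, q)
  gm <- rowMeans(group_values, na.rm = TRUE)
  pooled <- pooled_effects %||% gm
  cons <- vapply(seq_len(nrow(group_values)), function(i) {
    if (is.na(pooled[i])) return(FALSE)
    isTRUE(sign_consistency(pooled[i], group_values[i, ]))
  }, logical(1))
  out <- data.frame(p = p,
                    significant = ifelse(is.na(fdr$significant), NA,
                                         fdr$significant & cons),
                    sign_consistent = cons)
  attr(out, "critical_p") <- fdr$critical_p
  out
}
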