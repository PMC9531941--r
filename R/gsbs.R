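# Greedy state boundary search (GSBS).
#
# The search places boundaries so that each timepoint's multi-voxel pattern
# correlates maximally with the mean pattern of its state. Candidate
# placements are scored with an O(1)-per-segment identity: with Z the
# row-standardized data (each timepoint z-scored across voxels) and P the
# column-wise running sum of the raw data, the correlation between timepoint
# t and the mean pattern m of segment [a, b] is
#   corr(x_t, m) = (z_t . m) / ((v - 1) sd(m)),
# and both z_t . m and sd(m) reduce to differences of precomputed
# cross-product cumulative sums. Candidate searches over all split points
# therefore cost O(1) per candidate after an O(n^2 v) setup.

gsbs_precompute <- function(X) {
  n <- nrow(X); v <- ncol(X)
  rm_ <- rowMeans(X)
  rsd <- sqrt(rowSums((X - rm_)^2) / (v - 1))
  zero_tp <- rsd < 1e-12
  if (any(zero_tp))
    warning(sprintf("%d zero-variance timepoint(s): correlations involving them treated as 0", sum(zero_tp)))
  Z <- (X - rm_) / ifelse(zero_tp, 1, rsd)
  Z[zero_tp, ] <- 0
  Pfull <- rbind(0, apply(X, 2L, cumsum))          # (n+1) x v ; row a = P_{a-1}
  C <- Z %*% t(Pfull)                              # n x (n+1)
  Rfull <- rbind(0, apply(C, 2L, cumsum))          # (n+1) x (n+1)
  G <- tcrossprod(Pfull)                           # (n+1) x (n+1)
  S1 <- c(0, cumsum(rowSums(X)))

  CC <- suppressWarnings(stats::cor(t(X)))
  if (anyNA(CC)) CC[is.na(CC)] <- 0
  ut <- upper.tri(CC)
  utRow <- row(CC)[ut]; utCol <- col(CC)[ut]; utVals <- CC[ut]

  list(n = n, v = v, Rfull = Rfull, G = G, S1 = S1,
       utRow = utRow, utCol = utCol, utVals = utVals)
}

# Sum over t in [a, b] of corr(x_t, mean pattern of [a, b]); vectorized
# over parallel segment vectors a, b.
seg_contrib <- function(pre, a, b) {
  L <- b - a + 1
  v <- pre$v
  i_b <- b + 1L
  sumdot <- (pre$Rfull[cbind(i_b, i_b)] - pre$Rfull[cbind(a, i_b)]) -
            (pre$Rfull[cbind(i_b, a)]  - pre$Rfull[cbind(a, a)])
  sumX <- pre$S1[i_b] - pre$S1[a]
  ssqP <- pre$G[cbind(i_b, i_b)] - 2 * pre$G[cbind(i_b, a)] + pre$G[cbind(a, a)]
  varm <- (ssqP / L^2 - v * (sumX / (L * v))^2) / (v - 1)
  sdm <- sqrt(pmax(varm, 0))
  ifelse(sdm < 1e-10, 0, sumdot / (L * sdm * (v - 1)))
}

fit_from_bounds <- function(pre, bnds) {
  a <- c(1L, bnds); b <- c(bnds - 1L, pre$n)
  sum(seg_contrib(pre, a, b)) / pre$n
}

# Pooled-variance two-sample t contrasting within-state timepoint
# correlations against consecutive-state ones; NA when either sample has
# fewer than 2 pairs.
tdist_from_labels <- function(pre, labels) {
  dd <- labels[pre$utCol] - labels[pre$utRow]
  w <- pre$utVals[dd == 0L]
  btw <- pre$utVals[dd == 1L]
  nw <- length(w); nb <- length(btw)
  if (nw < 2L || nb < 2L) return(NA_real_)
  sp2 <- ((nw - 1) * stats::var(w) + (nb - 1) * stats::var(btw)) / (nw + nb - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(w) - mean(btw)) / sqrt(sp2 * (1 / nw + 1 / nb))
}

labels_from_bounds <- function(n, bnds) {
  if (!length(bnds)) return(rep.int(1L, n))
  findInterval(seq_len(n), c(1L, bnds))
}

#' Mean multi-voxel activity pattern per state
#'
#' @param x a [bold_matrix()] (or matrix).
#' @param seg a [segmentation()] over the same timepoints.
#' @return A k x voxels matrix; row j is the mean pattern of state j.
#' @export
state_means <- function(x, seg) {
  X <- if (inherits(x, "bold_matrix")) x$values else as.matrix(x)
  if (nrow(X) != seg$n_timepoints) stop("segmentation does not match the data length")
  lab <- state_labels(seg)
  rowsum(X, lab) / as.vector(table(lab))
}

#' Fit of a segmentation to the data
#'
#' The mean, over timepoints, of the Pearson correlation (across voxels)
#' between each timepoint's activity pattern and the mean pattern of the
#' state it belongs to. Correlations involving a zero-variance pattern are
#' counted as 0.
#'
#' @inheritParams state_means
#' @return A single number; 1 for noiseless piecewise-constant data split at
#'   the true boundaries.
#' @export
fit_score <- function(x, seg) {
  X <- if (inherits(x, "bold_matrix")) x$values else as.matrix(x)
  if (nrow(X) != seg$n_timepoints) stop("segmentation does not match the data length")
  m <- state_means(x, seg)
  lab <- state_labels(seg)
  r <- vapply(seq_len(nrow(X)), function(t) {
    a <- X[t, ]; b <- m[lab[t], ]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
    stats::cor(a, b)
  }, numeric(1))
  mean(r)
}

#' t-distance of a segmentation
#'
#' Pooled-variance two-sample t-statistic contrasting the Pearson
#' correlations (across voxels) of timepoint pairs that fall within one
#' state against pairs falling in consecutive states. Large positive values
#' indicate states that are internally coherent and mutually distinct; the
#' maximum over k selects the number of states.
#'
#' @inheritParams state_means
#' @return A single number, or NA when fewer than two pairs exist in either
#'   set.
#' @export
t_distance <- function(x, seg) {
  X <- if (inherits(x, "bold_matrix")) x$values else as.matrix(x)
  if (nrow(X) != seg$n_timepoints) stop("segmentation does not match the data length")
  CC <- suppressWarnings(stats::cor(t(X)))
  if (anyNA(CC)) {
    warning("zero-variance timepoint(s): correlations treated as 0")
    CC[is.na(CC)] <- 0
  }
  ut <- upper.tri(CC)
  pre <- list(utRow = row(CC)[ut], utCol = col(CC)[ut], utVals = CC[ut])
  tdist_from_labels(pre, state_labels(seg))
}

#' Strength of each state boundary
#'
#' One minus the Pearson correlation between the mean activity patterns of
#' the states immediately before and after each boundary; ranges over
#' `[0, 2]`.
#'
#' @inheritParams state_means
#' @return Numeric vector, one value per boundary.
#' @export
boundary_strengths <- function(x, seg) {
  if (seg$k < 2L) stop("segmentation has no boundaries")
  m <- state_means(x, seg)
  vapply(seq_len(seg$k - 1L), function(j) {
    a <- m[j, ]; b <- m[j + 1L, ]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
      warning("zero-variance state mean: correlation treated as 0")
      return(1)
    }
    1 - stats::cor(a, b)
  }, numeric(1))
}

strengths_internal <- function(X, bnds) {
  n <- nrow(X)
  lab <- labels_from_bounds(n, bnds)
  m <- rowsum(X, lab) / as.vector(table(lab))
  k <- length(bnds) + 1L
  out <- numeric(k - 1L)
  for (j in seq_len(k - 1L)) {
    a <- m[j, ]; b <- m[j + 1L, ]
    out[j] <- if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) 1 else 1 - stats::cor(a, b)
  }
  out
}

# One fine-tuning sweep: boundaries visited from weakest to strongest
# (ties: earlier position first), each shifted by 1 TR when that improves
# the fit; earlier shift preferred on equal improvement.
finetune_sweep <- function(pre, X, bnds) {
  if (!length(bnds)) return(bnds)
  st <- strengths_internal(X, bnds)
  ord <- order(st, bnds)
  n <- pre$n
  for (idx in ord) {
    b <- bnds[idx]
    prevstart <- if (idx > 1L) bnds[idx - 1L] else 1L
    nextend <- if (idx < length(bnds)) bnds[idx + 1L] - 1L else n
    base <- sum(seg_contrib(pre, c(prevstart, b), c(b - 1L, nextend)))
    best_delta <- 0; best_b <- b
    for (nb in c(b - 1L, b + 1L)) {
      if (nb <= prevstart || nb > nextend || nb < 2L) next
      delta <- sum(seg_contrib(pre, c(prevstart, nb), c(nb - 1L, nextend))) - base
      if (delta > best_delta + 1e-12) { best_delta <- delta; best_b <- nb }
    }
    bnds[idx] <- best_b
  }
  bnds
}

# Best single-boundary addition by fit; returns NULL when no legal split.
best_single <- function(pre, bnds, basefit) {
  n <- pre$n
  a_st <- c(1L, bnds); b_st <- c(bnds - 1L, n)
  keep <- (b_st - a_st) >= 1L           # state length >= 2
  if (!any(keep)) return(NULL)
  a_st <- a_st[keep]; b_st <- b_st[keep]
  L <- b_st - a_st + 1L
  avec <- rep.int(a_st, L - 1L)
  bvec <- rep.int(b_st, L - 1L)
  pvec <- unlist(lapply(seq_along(a_st), function(i) (a_st[i] + 1L):b_st[i]))
  newfit <- basefit + (seg_contrib(pre, avec, pvec - 1L) +
                       seg_contrib(pre, pvec, bvec) -
                       seg_contrib(pre, avec, bvec)) / n
  i <- which.max(newfit)
  list(p = pvec[i], fit = newfit[i])
}

# Best two-boundary addition (both interior to one existing state) by fit.
best_pair <- function(pre, bnds, basefit) {
  n <- pre$n
  a_st <- c(1L, bnds); b_st <- c(bnds - 1L, n)
  keep <- (b_st - a_st) >= 2L           # state length >= 3
  if (!any(keep)) return(NULL)
  a_st <- a_st[keep]; b_st <- b_st[keep]
  pp <- qq <- aa <- bb <- vector("list", length(a_st))
  for (i in seq_along(a_st)) {
    s <- (a_st[i] + 1L):b_st[i]
    cmb <- utils::combn(s, 2L)
    pp[[i]] <- cmb[1L, ]; qq[[i]] <- cmb[2L, ]
    aa[[i]] <- rep.int(a_st[i], ncol(cmb)); bb[[i]] <- rep.int(b_st[i], ncol(cmb))
  }
  pvec <- unlist(pp); qvec <- unlist(qq)
  avec <- unlist(aa); bvec <- unlist(bb)
  newfit <- basefit + (seg_contrib(pre, avec, pvec - 1L) +
                       seg_contrib(pre, pvec, qvec - 1L) +
                       seg_contrib(pre, qvec, bvec) -
                       seg_contrib(pre, avec, bvec)) / n
  i <- which.max(newfit)
  list(p = pvec[i], q = qvec[i], fit = newfit[i])
}

#' Greedy state boundary search
#'
#' Iteratively adds state boundaries to a multi-voxel time series. Each
#' iteration finds (a) the single boundary and (b) the pair of boundaries
#' interior to one existing state that maximize the fit ([fit_score()]),
#' adopts whichever candidate segmentation has the higher [t_distance()]
#' (the single one on ties or when pairs are unavailable), and then, if
#' `finetune`, sweeps all boundaries once from weakest to strongest, moving
#' each by 1 TR when that improves the fit. The search stops when the number
#' of states would exceed `k_max` or no legal placement remains.
#'
#' @param x a [bold_matrix()] (or bare matrix plus `tr`).
#' @param k_max maximum number of states (default 100).
#' @param finetune run the per-iteration fine-tuning sweep (default TRUE).
#' @param pair_search allow two boundaries per iteration (default TRUE);
#'   with `pair_search = FALSE` and `finetune = FALSE` the search reduces to
#'   the classic one-boundary-per-iteration greedy search.
#' @param tr TR in seconds, when `x` is a bare matrix.
#' @return A list of class `gsbs_states` with `segmentations` (one
#'   [segmentation()] per achieved k, fine-tuned), `curve` (a
#'   [tdistance_curve()]; k may skip values where a pair was placed), and
#'   `fits` (fit score per achieved k).
#' @seealso [gsbs()] for the high-level interface that also selects k.
#' @export
place_boundaries <- function(x, k_max = 100, finetune = TRUE, pair_search = TRUE,
                             tr = NULL) {
  x <- as_bold(x, tr %||% 1)
  X <- x$values
  if (k_max < 2) stop("k_max must be at least 2")
  pre <- gsbs_precompute(X)
  n <- pre$n
  bnds <- integer()
  ks <- 1L
  ts <- tdist_from_labels(pre, labels_from_bounds(n, bnds))
  fits <- fit_from_bounds(pre, bnds)
  segs <- list(segmentation(n, bnds))

  repeat {
    k_now <- length(bnds) + 1L
    if (k_now >= k_max) break
    basefit <- fit_from_bounds(pre, bnds)
    single <- best_single(pre, bnds, basefit)
    if (is.null(single)) {
      if (k_now == 1L) stop("degenerate input: no legal boundary placement")
      break
    }
    cand1 <- sort(c(bnds, single$p))
    t1 <- tdist_from_labels(pre, labels_from_bounds(n, cand1))
    use_pair <- FALSE
    if (pair_search && k_now + 2L <= k_max) {
      pair <- best_pair(pre, bnds, basefit)
      if (!is.null(pair)) {
        cand2 <- sort(c(bnds, pair$p, pair$q))
        t2 <- tdist_from_labels(pre, labels_from_bounds(n, cand2))
        if (!is.na(t2) && (is.na(t1) || t2 > t1)) use_pair <- TRUE
      }
    }
    bnds <- if (use_pair) cand2 else cand1
    if (finetune) bnds <- finetune_sweep(pre, X, bnds)
    k_now <- length(bnds) + 1L
    ks <- c(ks, k_now)
    ts <- c(ts, tdist_from_labels(pre, labels_from_bounds(n, bnds)))
    fits <- c(fits, fit_from_bounds(pre, bnds))
    segs <- c(segs, list(segmentation(n, bnds)))
  }
  names(segs) <- as.character(ks)
  structure(list(segmentations = segs, curve = tdistance_curve(ks, ts),
                 fits = fits), class = "gsbs_states")
}

#' Select the optimal number of states
#'
#' The k attaining the maximum t-distance; ties are broken toward the
#' smaller k. Undefined (NA) values are ignored.
#'
#' @param curve a [tdistance_curve()].
#' @return The selected k (integer).
#' @export
select_k <- function(curve) {
  ok <- is.finite(curve$tdist)
  if (!any(ok)) stop("t-distance is undefined at every evaluated k")
  kk <- curve$evaluated_k[ok]; tt <- curve$tdist[ok]
  kk[order(-tt, kk)][1L]
}

#' Segment a multi-voxel time series into neural states
#'
#' High-level interface: runs [place_boundaries()], selects the optimal
#' number of states with [select_k()], and attaches boundary strengths.
#'
#' @inheritParams place_boundaries
#' @return A list of class `gsbs_fit` with `segmentation` (at the optimal
#'   k, including `strengths`), `optimum_k`, `curve`, `all_segmentations`,
#'   `fits`, and `tr`.
#' @examples
#' set.seed(1)
#' pats <- matrix(rnorm(3 * 12), 3)            # 3 states x 12 voxels
#' x <- pats[rep(1:3, each = 10), ] + 0.2 * rnorm(30 * 12)
#' fit <- gsbs(x, k_max = 10, tr = 2.47)
#' fit$optimum_k
#' fit$segmentation$boundaries
#' @export
gsbs <- function(x, k_max = 100, finetune = TRUE, pair_search = TRUE, tr = NULL) {
  x <- as_bold(x, tr %||% 1)
  res <- place_boundaries(x, k_max = k_max, finetune = finetune,
                          pair_search = pair_search)
  k <- select_k(res$curve)
  seg <- res$segmentations[[as.character(k)]]
  seg$strengths <- if (seg$k >= 2L) boundary_strengths(x, seg) else numeric()
  structure(list(segmentation = seg, optimum_k = k, curve = res$curve,
                 all_segmentations = res$segmentations, fits = res$fits,
                 tr = x$tr), class = "gsbs_fit")
}

#' @export
print.gsbs_fit <- function(x, ...) {
  cat(sprintf("<gsbs_fit> optimum k = %d (%d boundaries), n = %d timepoints, TR = %g s\n",
              x$optimum_k, x$optimum_k - 1L, x$segmentation$n_timepoints, x$tr))
  invisible(x)
}

#' Median state duration and its relative spread
#'
#' Per-state duration is the state length in TRs times the TR. The spread
#' statistic is the interquartile range divided by the median, a
#' nonparametric analogue of the coefficient of variation. Quartiles use
#' linear interpolation between order statistics.
#'
#' @param seg a [segmentation()].
#' @param tr TR in seconds.
#' @return List with `median_duration_s` and `iqr_over_median`.
#' @export
state_duration_summary <- function(seg, tr) {
  lens <- diff(c(1L, seg$boundaries, seg$n_timepoints + 1L))
  dur <- lens * tr
  med <- stats::median(dur)
  iqr <- stats::IQR(dur, type = 7)
  list(median_duration_s = med, iqr_over_median = iqr / med)
}
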