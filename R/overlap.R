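# Boundary-overlap algebra. All overlap statistics compare two length-n
# boundary time series pointwise; scaling against the chance-expected
# overlap makes them 0 at independence.

series_values <- function(s) {
  if (inherits(s, "boundary_series")) s$values
  else if (is.numeric(s)) boundary_series(s)$values
  else stop("expected a boundary_series")
}

check_same_n <- function(a, b) {
  if (length(a) != length(b)) stop("boundary series lengths differ")
}

#' Build a binary event-boundary series from annotated onsets
#'
#' Event onsets are retained when at least `min_salience` observers marked
#' them, mapped to the TR containing the onset (`floor(onset / tr) + 1`,
#' 1-based), and multiple onsets inside one TR collapse to a single mark.
#'
#' @param onsets_s event onsets in seconds, within `[0, n * tr)`.
#' @param salience number of observers marking each onset.
#' @param tr TR in seconds.
#' @param n number of timepoints of the target series.
#' @param min_salience minimum observer count to keep an onset (default 5).
#' @return A binary [boundary_series()].
#' @export
events_to_series <- function(onsets_s, salience, tr, n, min_salience = 5) {
  if (length(onsets_s) != length(salience)) stop("one salience per onset required")
  if (any(onsets_s < 0 | onsets_s >= n * tr)) stop("onset outside the scan")
  keep <- salience >= min_salience
  v <- numeric(n)
  if (any(keep)) {
    idx <- floor(onsets_s[keep] / tr) + 1
    v[unique(idx)] <- 1
  }
  if (v[1L] != 0) {
    warning("an event onset fell in the first TR; dropped (timepoint 1 is never a transition)")
    v[1L] <- 0
  }
  boundary_series(v, "events")
}

#' Chance-expected overlap between two boundary series
#'
#' Under independence of the two series the expected pointwise overlap is
#' `sum(a) * sum(b) / n`; valid for binary and weighted series.
#'
#' @param a,b [boundary_series()] of equal length.
#' @return A single number.
#' @export
expected_overlap <- function(a, b) {
  va <- series_values(a); vb <- series_values(b)
  check_same_n(va, vb)
  sum(va) * sum(vb) / length(va)
}

#' Absolute boundary overlap
#'
#' Raw overlap `O = sum(e * s)` rescaled so that 0 means chance-level
#' overlap and 1 means every state boundary (weighted by its value)
#' coincides with an event boundary: `OA = (O - OE) / (sum(s) - OE)`.
#' The second argument carries the state boundaries being assessed; it may
#' be weighted (by strength or co-occurrence), the reference series `e`
#' stays binary.
#'
#' @param e reference (event) [boundary_series()], binary.
#' @param s state [boundary_series()], binary or weighted.
#' @return An [overlap_result()]; `absolute` is NA (with a warning) when
#'   `sum(s)` is 0 or equals the expected overlap.
#' @export
absolute_overlap <- function(e, s) {
  ve <- series_values(e); vs <- series_values(s)
  check_same_n(ve, vs)
  O <- sum(ve * vs)
  OE <- sum(ve) * sum(vs) / length(ve)
  den <- sum(vs) - OE
  OA <- if (sum(vs) == 0 || abs(den) < 1e-12) {
    warning("absolute overlap undefined (empty series or degenerate denominator)")
    NA_real_
  } else (O - OE) / den
  overlap_result(raw = O, expected = OE, absolute = OA)
}

#' Relative boundary overlap
#'
#' Overlap rescaled by the maximum achievable given both boundary counts:
#' `OR = (O - OE) / (min(sum(a), sum(b)) - OE)`, so regions with more or
#' fewer boundaries than the reference are not penalized. Symmetric in its
#' arguments for binary series.
#'
#' @param a,b [boundary_series()] of equal length.
#' @return An [overlap_result()]; `relative` is NA (with a warning) when
#'   undefined.
#' @export
relative_overlap <- function(a, b) {
  va <- series_values(a); vb <- series_values(b)
  check_same_n(va, vb)
  O <- sum(va * vb)
  OE <- sum(va) * sum(vb) / length(va)
  den <- min(sum(va), sum(vb)) - OE
  OR <- if (min(sum(va), sum(vb)) == 0 || abs(den) < 1e-12) {
    warning("relative overlap undefined (empty series or degenerate denominator)")
    NA_real_
  } else (O - OE) / den
  overlap_result(raw = O, expected = OE, relative = OR)
}

#' Replace binary boundary marks with boundary strengths
#'
#' @param s binary [boundary_series()].
#' @param strengths one value per mark, in temporal order (e.g. from
#'   [boundary_strengths()]).
#' @return A weighted [boundary_series()].
#' @export
weight_by_strength <- function(s, strengths) {
  vs <- series_values(s)
  if (!all(vs %in% c(0, 1))) stop("series must be binary")
  marks <- which(vs > 0)
  if (length(marks) != length(strengths)) stop("one strength per boundary mark required")
  vs[marks] <- strengths
  boundary_series(vs, if (inherits(s, "boundary_series")) s$label else "")
}

#' Replace boundary marks with their co-occurrence proportion
#'
#' Each mark of `s` is replaced by the proportion of series in `scope`
#' (indices into `all_series`, e.g. the searchlights of one network or the
#' whole brain) that also mark that timepoint.
#'
#' @param s binary [boundary_series()].
#' @param all_series list of binary [boundary_series()] of the same length.
#' @param scope integer indices into `all_series`; must be nonempty.
#' @return A weighted [boundary_series()].
#' @export
weight_by_cooccurrence <- function(s, all_series, scope) {
  if (!length(scope)) stop("empty scope")
  vs <- series_values(s)
  if (!all(vs %in% c(0, 1))) stop("series must be binary")
  mat <- vapply(all_series[scope], series_values, numeric(length(vs)))
  if (!all(mat %in% c(0, 1))) stop("all series in scope must be binary")
  prop <- rowMeans(mat)
  marks <- which(vs > 0)
  vs[marks] <- prop[marks]
  boundary_series(vs, if (inherits(s, "boundary_series")) s$label else "")
}

#' Decompose two boundary series into shared and unique parts
#'
#' For binary series `si`, `sj`: shared marks are the pointwise product, and
#' the unique parts are what remains of each series; shared + unique
#' reconstructs each input exactly.
#'
#' @param si,sj binary [boundary_series()] of equal length.
#' @return List with binary series `shared`, `unique_i`, `unique_j`.
#' @export
shared_unique_decomposition <- function(si, sj) {
  vi <- series_values(si); vj <- series_values(sj)
  check_same_n(vi, vj)
  if (!all(vi %in% c(0, 1)) || !all(vj %in% c(0, 1))) stop("series must be binary")
  sh <- vi * vj
  list(shared = boundary_series(sh, "shared"),
       unique_i = boundary_series(vi - sh, "unique_i"),
       unique_j = boundary_series(vj - sh, "unique_j"))
}

#' Shared-versus-unique boundary overlap statistic
#'
#' Tests whether boundaries shared by two searchlights align with event
#' boundaries better than boundaries unique to either, using the larger of
#' the two unique-overlap values as the baseline:
#' `OA(e, shared) - max(OA(e, unique_i), OA(e, unique_j))`.
#'
#' @param e binary event [boundary_series()].
#' @param si,sj binary state [boundary_series()].
#' @return A single number, NA when any of the three component overlaps is
#'   undefined (e.g. an empty decomposed series).
#' @export
shared_vs_unique_statistic <- function(e, si, sj) {
  d <- shared_unique_decomposition(si, sj)
  oa <- suppressWarnings(c(absolute_overlap(e, d$shared)$absolute,
                           absolute_overlap(e, d$unique_i)$absolute,
                           absolute_overlap(e, d$unique_j)$absolute))
  if (anyNA(oa)) return(NA_real_)
  oa[1L] - max(oa[2L], oa[3L])
}

#' Pairwise relative-overlap matrix of boundary series
#'
#' @param series list of at least two binary [boundary_series()] of equal
#'   length.
#' @return Symmetric matrix of pairwise relative overlaps; diagonal 1 by
#'   convention; undefined entries are NA.
#' @export
pairwise_overlap_matrix <- function(series) {
  m <- length(series)
  if (m < 2L) stop("need at least two series")
  out <- matrix(NA_real_, m, m)
  diag(out) <- 1
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    or_ij <- suppressWarnings(relative_overlap(series[[i]], series[[j]])$relative)
    out[i, j] <- out[j, i] <- or_ij
  }
  labs <- vapply(series, function(s) if (inherits(s, "boundary_series")) s$label else "", "")
  if (any(nzchar(labs))) dimnames(out) <- list(labs, labs)
  out
}

#' Similarity of two symmetric matrices
#'
#' Pearson correlation of the lower-triangle entries (diagonal excluded),
#' dropping pairs where either entry is missing.
#'
#' @param m1,m2 symmetric matrices of equal shape.
#' @return A single correlation.
#' @export
matrix_similarity <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2))) stop("matrices must share the same shape")
  lt <- lower.tri(m1)
  a <- m1[lt]; b <- m2[lt]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("fewer than 3 valid entry pairs")
  stats::cor(a[ok], b[ok])
}
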