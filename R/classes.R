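#' Multi-voxel BOLD time-series matrix
#'
#' The unit the state-segmentation machinery operates on: a timepoints x
#' voxels matrix of BOLD amplitudes sampled every `tr` seconds. Rows are
#' timepoints (TRs), columns are voxels.
#'
#' @param values numeric matrix, timepoints x voxels; no missing values,
#'   at least 4 timepoints and 2 voxels.
#' @param tr repetition time in seconds (sampling interval).
#' @return An object of class `bold_matrix` with elements `values` and `tr`.
#' @export
bold_matrix <- function(values, tr) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (anyNA(values)) stop("values must not contain missing values")
  if (nrow(values) < 4L) stop("need at least 4 timepoints")
  if (ncol(values) < 2L) stop("need at least 2 voxels")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be a positive scalar")
  structure(list(values = values, tr = tr), class = "bold_matrix")
}

#' @export
print.bold_matrix <- function(x, ...) {
  cat(sprintf("<bold_matrix> %d timepoints x %d voxels, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' @export
dim.bold_matrix <- function(x) dim(x$values)

as_bold <- function(x, tr = NULL) {
  if (inherits(x, "bold_matrix")) return(x)
  if (is.null(tr)) stop("tr required when passing a bare matrix")
  bold_matrix(x, tr)
}

#' State segmentation of a time series
#'
#' A boundary at timepoint t (1-based) means t starts a new state; timepoint
#' 1 is never a boundary, so a segmentation with `b` boundaries has
#' `k = b + 1` states.
#'
#' @param n_timepoints number of timepoints the segmentation refers to.
#' @param boundaries strictly increasing integer TR indices in
#'   `[2, n_timepoints]`; may be empty (single state).
#' @param strengths optional per-boundary strengths (see
#'   [boundary_strengths()]).
#' @return Object of class `segmentation` with fields `n_timepoints`,
#'   `boundaries`, `k`, `strengths`.
#' @export
segmentation <- function(n_timepoints, boundaries = integer(), strengths = NULL) {
  n_timepoints <- as.integer(n_timepoints)
  boundaries <- as.integer(boundaries)
  if (length(boundaries)) {
    if (any(boundaries < 2L | boundaries > n_timepoints))
      stop("boundaries must lie in [2, n_timepoints]")
    if (any(diff(boundaries) <= 0L)) stop("boundaries must be strictly increasing")
  }
  if (!is.null(strengths) && length(strengths) != length(boundaries))
    stop("one strength per boundary required")
  structure(list(n_timepoints = n_timepoints, boundaries = boundaries,
                 k = length(boundaries) + 1L, strengths = strengths),
            class = "segmentation")
}

#' State membership of each timepoint
#'
#' @param seg a [segmentation()].
#' @return Integer vector of length `n_timepoints`, nondecreasing, onto
#'   `1..k`.
#' @export
state_labels <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  lab <- integer(seg$n_timepoints)
  lab[] <- 1L
  if (length(seg$boundaries))
    lab <- findInterval(seq_len(seg$n_timepoints), c(1L, seg$boundaries))
  lab
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> n = %d, k = %d states, boundaries: %s\n",
              x$n_timepoints, x$k,
              if (length(x$boundaries)) paste(x$boundaries, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Boundary time series
#'
#' A length-n series that is 0 at timepoints with no transition and positive
#' (1, or a weight) where a new state or event starts. The first timepoint
#' starts the first state and is by convention never a transition.
#'
#' @param values numeric vector, entries >= 0, first entry 0.
#' @param label optional text label.
#' @return Object of class `boundary_series`.
#' @export
boundary_series <- function(values, label = "") {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0)) stop("values must be nonnegative and non-missing")
  if (length(values) < 1L) stop("empty series")
  if (values[1L] != 0) stop("first timepoint cannot be a transition")
  structure(list(values = values, n = length(values), label = label),
            class = "boundary_series")
}

is_binary_series <- function(s) all(s$values %in% c(0, 1))

#' @export
print.boundary_series <- function(x, ...) {
  cat(sprintf("<boundary_series>%s n = %d, %d transition(s)%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$n, sum(x$values > 0),
              if (is_binary_series(x)) " (binary)" else " (weighted)"))
  invisible(x)
}

# Convert a segmentation to its binary boundary series.
#' Binary boundary series of a segmentation
#' @param seg a [segmentation()].
#' @param label optional label.
#' @return A binary [boundary_series()].
#' @export
as_boundary_series <- function(seg, label = "") {
  v <- numeric(seg$n_timepoints)
  v[seg$boundaries] <- 1
  boundary_series(v, label)
}

#' t-distance curve over candidate state counts
#'
#' @param evaluated_k integer vector of state counts that were evaluated.
#' @param tdist matching t-distance values (NA where undefined).
#' @return Object of class `tdistance_curve` with `optimum_k` set per
#'   [select_k()].
#' @export
tdistance_curve <- function(evaluated_k, tdist) {
  evaluated_k <- as.integer(evaluated_k)
  if (length(evaluated_k) != length(tdist)) stop("k and tdist lengths differ")
  obj <- structure(list(evaluated_k = evaluated_k, tdist = as.numeric(tdist),
                        optimum_k = NA_integer_), class = "tdistance_curve")
  if (any(is.finite(obj$tdist))) obj$optimum_k <- select_k(obj)
  obj
}

#' @export
print.tdistance_curve <- function(x, ...) {
  cat(sprintf("<tdistance_curve> k in [%d, %d], optimum k = %s\n",
              min(x$evaluated_k), max(x$evaluated_k),
              ifelse(is.na(x$optimum_k), "undefined", x$optimum_k)))
  invisible(x)
}

#' Overlap statistics between two boundary series
#'
#' Container for the raw overlap O, the chance-expected overlap OE, and the
#' rescaled absolute (OA) and relative (OR) overlap.
#'
#' @param raw raw overlap O.
#' @param expected expected overlap OE under independence.
#' @param absolute absolute overlap OA (NA when not computed/undefined).
#' @param relative relative overlap OR (NA when not computed/undefined).
#' @return Object of class `overlap_result`.
#' @export
overlap_result <- function(raw, expected, absolute = NA_real_, relative = NA_real_) {
  structure(list(raw = raw, expected = expected,
                 absolute = absolute, relative = relative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap> O = %.4g, OE = %.4g, OA = %.4g, OR = %.4g\n",
              x$raw, x$expected, x$absolute, x$relative))
  invisible(x)
}
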