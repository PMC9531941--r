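#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking about 5 s after the
#' stimulus minus a later, smaller gamma density modelling the undershoot
#' (peak delay 6 s, undershoot delay 16 s, dispersions 1 s, undershoot ratio
#' 1/6), sampled on the TR grid and normalized to unit peak.
#'
#' @param tr sampling interval in seconds.
#' @param duration kernel length in seconds (default 32).
#' @return Object of class `hrf_kernel` with fields `samples`, `tr`,
#'   `duration`.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be a positive scalar")
  if (tr >= duration) stop("tr must be smaller than the kernel duration")
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h <- h / max(h)
  structure(list(samples = h, tr = tr, duration = duration), class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %d samples, TR = %g s, peak at %g s\n",
              length(x$samples), x$tr, (which.max(x$samples) - 1) * x$tr))
  invisible(x)
}

# Direct-form II transposed IIR filter with explicit initial state.
iir_filter <- function(b, a, x, zi) {
  nf <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    xt <- x[t]
    yt <- b[1L] * xt + z[1L]
    if (nf > 2L) for (j in 1:(nf - 2L)) z[j] <- b[j + 1L] * xt + z[j + 1L] - a[j + 1L] * yt
    z[nf - 1L] <- b[nf] * xt - a[nf] * yt
    y[t] <- yt
  }
  y
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions, so step/DC inputs produce no edge
# transient (the scipy/MATLAB filtfilt algorithm).
filtfilt_zero_phase <- function(b, a, x) {
  nf <- max(length(b), length(a))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  npad <- 3L * nf
  if (length(x) <= npad)
    stop(sprintf("series too short to filter (need more than %d samples)", npad))
  A <- diag(nf - 1L) - cbind(-a[2:nf], rbind(diag(nf - 2L), 0))
  zi <- solve(A, b[2:nf] - b[1L] * a[2:nf])
  pre <- 2 * x[1L] - x[(npad + 1L):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - npad)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe, zi * xe[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + length(x))]
}

#' High-pass filter voxel time courses
#'
#' Removes slow drift below `cutoff_hz` from every voxel time course with a
#' 5th-order zero-phase (forward-backward) Butterworth filter, so boundary
#' timing is not shifted by filter delay. Edge transients are suppressed by
#' odd-reflection padding with steady-state initial conditions; a constant
#' series filters to (numerically) zero.
#'
#' @param x a [bold_matrix()].
#' @param cutoff_hz high-pass cutoff frequency in Hz (default 0.008).
#' @return Filtered [bold_matrix()] of the same shape; per-voxel means are
#'   approximately zero.
#' @export
highpass <- function(x, cutoff_hz = 0.008) {
  x <- as_bold(x)
  nyq <- 1 / (2 * x$tr)
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  if (cutoff_hz >= nyq) stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff_hz, nyq))
  bf <- signal::butter(5, W = cutoff_hz / nyq, type = "high")
  out <- apply(x$values, 2L, function(v) filtfilt_zero_phase(bf$b, bf$a, v))
  bold_matrix(out, x$tr)
}

# Shared FFT geometry: next power of two >= 2n suppresses circular
# wrap-around at the series ends.
fft_len <- function(n) 2L^ceiling(log2(2L * n))

#' Convolve voxel time courses with an HRF kernel
#'
#' Causal convolution of every voxel time course with the kernel, trimmed to
#' the input length. Used by the simulator and by round-trip checks of
#' [wiener_deconvolve()].
#'
#' @param x a [bold_matrix()] (or bare matrix with `tr`).
#' @param hrf an [canonical_hrf()] kernel sampled at the same TR.
#' @param tr TR, only needed when `x` is a bare matrix.
#' @return Convolved [bold_matrix()] of the same shape.
#' @export
convolve_hrf <- function(x, hrf, tr = NULL) {
  x <- as_bold(x, tr)
  if (abs(hrf$tr - x$tr) > 1e-9) stop("HRF must be sampled at the TR of the data")
  n <- nrow(x$values)
  nfft <- fft_len(n + length(hrf$samples))
  H <- stats::fft(c(hrf$samples, numeric(nfft - length(hrf$samples))))
  Y <- stats::mvfft(rbind(x$values, matrix(0, nfft - n, ncol(x$values))))
  out <- Re(stats::mvfft(Y * H, inverse = TRUE)) / nfft
  bold_matrix(out[seq_len(n), , drop = FALSE], x$tr)
}

#' Wiener deconvolution of BOLD time courses
#'
#' Removes the haemodynamic blur by applying the non-iterative Wiener
#' inverse per voxel in the frequency domain:
#' \eqn{\hat X = \bar H Y / (|H|^2 + \lambda)}, where H is the transfer
#' function of the HRF and \eqn{\lambda} a noise regularizer. Before the
#' inverse, each time course is extended by holding its final sample for
#' one kernel length (the observed series truncates the convolution tail;
#' the hold is the continuation an activity pattern persisting past the end
#' of the scan would produce) and then zero-padded to the next power of two
#' at least twice the extended length, suppressing circular wrap-around;
#' the output is trimmed back to the input length.
#'
#' @param x a [bold_matrix()].
#' @param hrf an [canonical_hrf()] kernel at the same TR.
#' @param noise_reg nonnegative regularizer \eqn{\lambda}; default
#'   `0.1 * mean(|H|^2)`.
#' @return Deconvolved [bold_matrix()] of the same shape.
#' @export
wiener_deconvolve <- function(x, hrf, noise_reg = NULL) {
  x <- as_bold(x)
  if (abs(hrf$tr - x$tr) > 1e-9) stop("HRF must be sampled at the TR of the data")
  if (all(hrf$samples == 0)) stop("all-zero HRF kernel")
  n <- nrow(x$values)
  nh <- length(hrf$samples)
  vals <- rbind(x$values, x$values[rep.int(n, nh), , drop = FALSE])  # hold-last extension
  nfft <- fft_len(n + 2L * nh)
  H <- stats::fft(c(hrf$samples, numeric(nfft - nh)))
  H2 <- Mod(H)^2
  if (is.null(noise_reg)) noise_reg <- 0.1 * mean(H2)
  if (noise_reg < 0) stop("noise_reg must be nonnegative")
  if (noise_reg == 0 && any(H2 == 0)) stop("singular transfer function at noise_reg = 0")
  Y <- stats::mvfft(rbind(vals, matrix(0, nfft - nrow(vals), ncol(vals))))
  Xhat <- Conj(H) * Y / (H2 + noise_reg)
  out <- Re(stats::mvfft(Xhat, inverse = TRUE)) / nfft
  bold_matrix(out[seq_len(n), , drop = FALSE], x$tr)
}

#' Element-wise group average of BOLD matrices
#'
#' Averaging across a group of subjects suppresses subject-specific noise;
#' state boundaries are detected on the averaged time courses.
#'
#' @param xs list of [bold_matrix()] objects with identical shape and TR.
#' @return The element-wise mean as a [bold_matrix()].
#' @export
group_average <- function(xs) {
  if (!length(xs)) stop("empty input list")
  xs <- lapply(xs, as_bold)
  d <- dim(xs[[1L]]$values); tr <- xs[[1L]]$tr
  for (x in xs) {
    if (!identical(dim(x$values), d)) stop("all matrices must share the same shape")
    if (abs(x$tr - tr) > 1e-9) stop("all matrices must share the same TR")
  }
  bold_matrix(Reduce(`+`, lapply(xs, `[[`, "values")) / length(xs), tr)
}
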