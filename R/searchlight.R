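# Spherical searchlights over a 3-D mask. Coordinates are 1-based voxel
# indices in image axis order throughout the R interface.

#' Integer voxel offsets of a sphere
#'
#' All integer offsets `(dx, dy, dz)` with squared Euclidean norm at most
#' `radius^2`, center included. A radius of 3 yields 123 offsets — the size
#' of a full searchlight sphere.
#'
#' @param radius sphere radius in voxels (default 3).
#' @return Integer matrix with one offset per row and columns dx, dy, dz.
#' @export
sphere_offsets <- function(radius = 3) {
  if (radius < 1) stop("radius must be at least 1")
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- NULL
  g
}

#' Build spherical searchlights over a mask
#'
#' Searchlight centers sit on a lattice with the given step size, anchored
#' at the minimum corner of the mask's bounding box and restricted to
#' in-mask voxels. Members are the in-mask voxels within `radius` of the
#' center; searchlights with fewer than `min_voxels` members are dropped.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param step lattice step size in voxels (default 2).
#' @param radius sphere radius in voxels (default 3).
#' @param min_voxels minimum member count to keep a searchlight (default
#'   16, i.e. more than 15 voxels).
#' @return List of searchlights, each a list with `center` (length-3
#'   integer) and `members` (m x 3 integer matrix); the mask dimensions are
#'   attached as attribute `mask_dim`.
#' @export
build_searchlights <- function(mask, step = 2, radius = 3, min_voxels = 16) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2L, min)
  centers <- as.matrix(expand.grid(seq(lo[1L], d[1L], by = step),
                                   seq(lo[2L], d[2L], by = step),
                                   seq(lo[3L], d[3L], by = step)))
  in_mask <- mask[centers]
  centers <- centers[in_mask, , drop = FALSE]
  off <- sphere_offsets(radius)
  out <- list()
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    mem <- sweep(off, 2L, ctr, `+`)
    ok <- mem[, 1L] >= 1L & mem[, 1L] <= d[1L] &
          mem[, 2L] >= 1L & mem[, 2L] <= d[2L] &
          mem[, 3L] >= 1L & mem[, 3L] <= d[3L]
    mem <- mem[ok, , drop = FALSE]
    mem <- mem[mask[mem], , drop = FALSE]
    if (nrow(mem) >= min_voxels)
      out[[length(out) + 1L]] <- list(center = as.integer(ctr), members = mem)
  }
  attr(out, "mask_dim") <- d
  out
}

# timepoints x members matrix for one searchlight from a 4-D array.
extract_searchlight_matrix <- function(data4d, sl) {
  d <- dim(data4d)
  nt <- d[4L]
  nvox3 <- prod(d[1:3])
  lin <- sl$members[, 1L] + d[1L] * (sl$members[, 2L] - 1L) +
    d[1L] * d[2L] * (sl$members[, 3L] - 1L)
  flat <- matrix(data4d, nvox3, nt)
  t(flat[lin, , drop = FALSE])
}

#' Run GSBS in every searchlight
#'
#' @param data4d 4-D numeric array (x, y, z, time), e.g. from
#'   [RNifti::readNifti()].
#' @param searchlights output of [build_searchlights()].
#' @param k_max maximum number of states per searchlight (default 100).
#' @param tr TR in seconds.
#' @return List, one element per searchlight: `series` (binary
#'   [boundary_series()] at the optimal k), `segmentation`, `curve`, and
#'   `error` (NULL, or the error message when that searchlight failed —
#'   failures do not stop the run).
#' @export
segment_searchlights <- function(data4d, searchlights, k_max = 100, tr = 1) {
  if (length(dim(data4d)) != 4L) stop("data must be a 4-D array")
  lapply(seq_along(searchlights), function(i) {
    tryCatch({
      X <- extract_searchlight_matrix(data4d, searchlights[[i]])
      fit <- gsbs(bold_matrix(X, tr), k_max = k_max)
      list(series = as_boundary_series(fit$segmentation, label = paste0("sl", i)),
           segmentation = fit$segmentation, curve = fit$curve, error = NULL)
    }, error = function(e)
      list(series = NULL, segmentation = NULL, curve = NULL,
           error = conditionMessage(e)))
  })
}

#' Keep searchlights with reproducible boundaries across two groups
#'
#' Screens searchlights by the relative overlap of their boundary series
#' obtained from two independent subject groups; searchlights with
#' undefined overlap (or a failed segmentation in either group) are
#' excluded.
#'
#' @param results_a,results_b outputs of [segment_searchlights()] for the
#'   same searchlight list on two independent groups.
#' @param threshold minimum between-group relative overlap (default 0:
#'   exclude only undefined).
#' @return Integer indices of retained searchlights.
#' @export
reliability_filter <- function(results_a, results_b, threshold = 0) {
  if (length(results_a) != length(results_b)) stop("searchlight lists differ")
  n_undef <- 0L
  keep <- logical(length(results_a))
  for (i in seq_along(results_a)) {
    sa <- results_a[[i]]$series; sb <- results_b[[i]]$series
    if (is.null(sa) || is.null(sb)) { n_undef <- n_undef + 1L; next }
    or_ab <- suppressWarnings(relative_overlap(sa, sb)$relative)
    if (is.na(or_ab)) { n_undef <- n_undef + 1L; next }
    keep[i] <- or_ab >= threshold
  }
  if (n_undef > 0L)
    message(sprintf("reliability_filter: %d searchlight(s) excluded with undefined overlap", n_undef))
  which(keep)
}

#' Project searchlight scalars back to voxels
#'
#' Each voxel receives the mean of the values of the searchlights covering
#' it (searchlights with missing values excluded). Voxels where fewer than
#' `min_coverage` of the covering searchlights have a defined value are set
#' to missing, as are voxels covered by no searchlight.
#'
#' @param values numeric vector, one (possibly NA) value per searchlight.
#' @param searchlights output of [build_searchlights()].
#' @param mask the 3-D mask the searchlights were built on.
#' @param min_coverage minimum defined/total coverage ratio (default 0.5).
#' @return List with `grid` (3-D array, NA where missing) and `mask`.
#' @export
project_to_voxels <- function(values, searchlights, mask, min_coverage = 0.5) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(values) != length(searchlights)) stop("one value per searchlight required")
  d <- dim(mask)
  sums <- array(0, d); n_def <- array(0L, d); n_cov <- array(0L, d)
  for (i in seq_along(searchlights)) {
    mem <- searchlights[[i]]$members
    n_cov[mem] <- n_cov[mem] + 1L
    if (is.finite(values[i])) {
      sums[mem] <- sums[mem] + values[i]
      n_def[mem] <- n_def[mem] + 1L
    }
  }
  grid <- array(NA_real_, d)
  ok <- n_cov > 0L & (n_def / pmax(n_cov, 1L)) >= min_coverage & n_def > 0L
  grid[ok] <- sums[ok] / n_def[ok]
  grid[!mask] <- NA_real_
  list(grid = grid, mask = mask)
}
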