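# Plain-text and NIfTI round-tripping. Tables are TSV; images are NIfTI-1
# via RNifti; voxel indices are reported 1-based in image axis order.

#' Write / read a boundary series as TSV
#'
#' Two columns: `timepoint` (1-based TR index) and `value`.
#'
#' @param s a [boundary_series()].
#' @param path file path.
#' @return `write_boundary_series_tsv` returns `path` invisibly;
#'   `read_boundary_series_tsv` returns a [boundary_series()].
#' @export
write_boundary_series_tsv <- function(s, path) {
  v <- series_values(s)
  utils::write.table(data.frame(timepoint = seq_along(v), value = v),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boundary_series_tsv
#' @export
read_boundary_series_tsv <- function(path) {
  d <- utils::read.delim(path)
  boundary_series(d$value[order(d$timepoint)],
                  label = sub("\\.tsv$", "", basename(path)))
}

#' Write / read a labelled numeric matrix as TSV
#'
#' @param m numeric matrix (e.g. a pairwise overlap or consensus matrix).
#' @param path file path.
#' @return The path (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  d <- as.data.frame(m)
  names(d) <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  utils::write.table(cbind(id = rownames(m) %||% paste0("c", seq_len(nrow(m))), d),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}

#' Write a segmentation's boundary table as TSV
#'
#' Columns: `boundary` (TR index) and `strength`.
#'
#' @param seg a [segmentation()] (strengths optional).
#' @param path file path.
#' @export
write_segmentation_tsv <- function(seg, path) {
  utils::write.table(data.frame(boundary = seg$boundaries,
                                strength = seg$strengths %||% rep(NA_real_, length(seg$boundaries))),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a t-distance curve as TSV
#'
#' Columns: `k` and `tdist`.
#'
#' @param curve a [tdistance_curve()].
#' @param path file path.
#' @export
write_tdistance_tsv <- function(curve, path) {
  utils::write.table(data.frame(k = curve$evaluated_k, tdist = curve$tdist),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an event annotation table as TSV
#'
#' Columns: `onset_s` (seconds) and `salience` (observer count).
#'
#' @param events data frame with `onset_s` and `salience`.
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events[, c("onset_s", "salience")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) utils::read.delim(path)

# 4-D array -> NIfTI file with TR in the 4th pixdim
write_nifti_4d <- function(arr, path, tr = 1) {
  im <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(im)
  pd[length(pd)] <- tr
  RNifti::pixdim(im) <- pd
  RNifti::writeNifti(im, path)
  invisible(path)
}

# Write a simulated dataset to disk: per-subject 4-D volumes with regions
# tiled along the y axis, a 3-D region label map, events TSV, ground-truth
# JSON and the config YAML.
write_dataset <- function(ds, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- ds$ground_truth
  v <- cfg$n_voxels_per_region; R <- cfg$n_regions; n <- gt$n_timepoints
  paths <- list()
  for (s in seq_len(cfg$n_subjects)) {
    arr <- array(0, c(v, R, 1L, n))
    for (r in seq_len(R)) arr[, r, 1L, ] <- t(ds$data[[r]][[s]]$values)
    paths$subjects[s] <- write_nifti_4d(arr, file.path(dir, sprintf("subject%03d.nii.gz", s)), gt$tr)
  }
  region_map <- array(rep(seq_len(R), each = v), c(v, R, 1L))
  paths$region_map <- write_nifti_4d(region_map, file.path(dir, "region_labels.nii.gz"))
  paths$events <- write_events_tsv(ds$events, file.path(dir, "events.tsv"))
  gt_json <- list(n_timepoints = gt$n_timepoints, tr = gt$tr,
                  regions = gt$regions, k_per_region = gt$k_per_region,
                  network_assignment = gt$network_assignment,
                  event_boundaries = gt$event_boundaries,
                  slowest_region = gt$slowest_region)
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt_json, paths$ground_truth, auto_unbox = TRUE, digits = NA)
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), paths$config)
  paths
}
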