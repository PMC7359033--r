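# Plain-text and NIfTI I/O for the pipeline's objects. All tables are TSV.

#' Read and write network timeseries as TSV
#'
#' The on-disk format is a TSV with a `time_s` column, optional identifier
#' columns, and one column per network.
#'
#' @param ts Network timeseries tibble.
#' @param path File path.
#' @export
write_network_tsv <- function(ts, path) {
  readr::write_tsv(ts, path)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read and write step distance vectors as TSV
#'
#' Columns `t_s`, `step`, and `ci_low`/`ci_high` when present.
#'
#' @param sdv Step distance tibble.
#' @param path File path.
#' @export
write_step_tsv <- function(sdv, path) {
  readr::write_tsv(sdv, path)
  invisible(path)
}

#' @rdname write_step_tsv
#' @export
read_step_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read and write detected timepoints as TSV
#'
#' Columns `onset_s`, `kind`, and `prominence` or `width`.
#'
#' @param tp Timepoint tibble.
#' @param path File path.
#' @export
write_timepoints_tsv <- function(tp, path) {
  readr::write_tsv(tp, path)
  invisible(path)
}

#' @rdname write_timepoints_tsv
#' @export
read_timepoints_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read boundary annotations (onset_s, label) as a feature tibble
#'
#' @param path TSV with columns `onset_s` and optionally `label`.
#' @param duration_s Run duration in seconds.
#' @param name Feature name for the resulting boundary vector.
#' @export
read_boundary_tsv <- function(path, duration_s, name = "events") {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  boundary_vector(x$onset_s, duration_s, name = name)
}

#' Read a continuous feature (time_s, value) as a feature tibble
#'
#' @param path TSV with columns `time_s` and `value`.
#' @param name Feature name.
#' @export
read_feature_tsv <- function(path, name) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    feature = name, kind = "continuous",
    time_s = x$time_s, value = x$value, usable = TRUE
  )
}

#' Read a 4-D NIfTI volume series as an array
#'
#' @param path NIfTI-1 file.
#' @return Plain numeric array (x, y, z, t) with attribute
#'   `"voxel_size_mm"`.
#' @export
read_volume_series <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(out))))]
  out
}

#' Write a volume (3-D array) as NIfTI-1
#'
#' @param v 3-D array.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @export
write_volume <- function(v, path, voxel_size_mm = c(1.6, 1.6, 1.6)) {
  img <- RNifti::asNifti(unclass(v))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
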