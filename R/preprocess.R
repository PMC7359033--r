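# Ingestion of volume or matrix inputs into smoothed network-activation
# timeseries: dual regression against known spatial maps, and temporal
# smoothing with a centered moving average.

#' Build a network timeseries tibble from a matrix
#'
#' The package represents network-activation timeseries as plain tibbles: one
#' row per timepoint, a `time_s` column, optional `participant_id` / `run_id` /
#' `run_type` identifiers, and one numeric column per network. All pipeline
#' functions accept these tibbles and chain with the pipe.
#'
#' @param values T x K numeric matrix of network activations.
#' @param tr_s Sampling interval in seconds (default 1, the TR of the data
#'   this method was designed for).
#' @param participant_id,run_id,run_type Optional identifiers; `run_type`
#'   is one of "movie", "rest", "synthetic".
#' @return A tibble with `time_s` and one column per network.
#' @export
network_timeseries <- function(values, tr_s = 1, participant_id = NULL,
                               run_id = NULL, run_type = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("need at least 2 timepoints and 2 networks", call. = FALSE)
  }
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  check_scalar_number(tr_s, "tr_s", positive = TRUE)
  k <- ncol(values)
  nm <- colnames(values) %||% sprintf("net_%02d", seq_len(k))
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  names(out) <- nm
  out <- dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(nrow(values)) - 1) * tr_s), out
  )
  if (!is.null(run_type)) {
    run_type <- match.arg(run_type, c("movie", "rest", "synthetic"))
    out <- dplyr::bind_cols(tibble::tibble(run_type = run_type), out)
  }
  if (!is.null(run_id)) out <- dplyr::bind_cols(tibble::tibble(run_id = run_id), out)
  if (!is.null(participant_id)) {
    out <- dplyr::bind_cols(tibble::tibble(participant_id = participant_id), out)
  }
  out
}

#' Dual regression: project volumes onto known spatial network maps
#'
#' Per-timepoint least squares of the voxel vector on K spatial map columns,
#' turning a 4-D functional series (here, a T x V matrix of masked voxels)
#' into one activation timeseries per network. Map columns and each volume
#' are demeaned before regression, matching the stage-1 behavior of the
#' standard dual-regression procedure.
#'
#' @param volumes T x V matrix, one row per functional volume.
#' @param maps V x K matrix of spatial network maps (full column rank).
#' @param demean Demean map columns and each volume before regression
#'   (default TRUE).
#' @param variance_normalize Scale each output timeseries to unit variance
#'   (off by default; the equivalent option in common pipelines is optional
#'   and its use is dataset-specific).
#' @param tr_s Sampling interval of the output timeseries.
#' @return A network timeseries tibble with T rows and K network columns.
#' @export
dual_regression <- function(volumes, maps, demean = TRUE,
                            variance_normalize = FALSE, tr_s = 1) {
  volumes <- as.matrix(volumes)
  maps <- as.matrix(maps)
  if (ncol(volumes) != nrow(maps)) {
    stop("`volumes` and `maps` disagree on the number of voxels", call. = FALSE)
  }
  k <- ncol(maps)
  if (nrow(maps) <= k) stop("need more voxels than maps", call. = FALSE)
  if (demean) {
    maps <- sweep(maps, 2, colMeans(maps))
    volumes <- volumes - rowMeans(volumes)
  }
  qr_m <- qr(maps)
  if (qr_m$rank < k) {
    stop("spatial maps are rank deficient (degenerate design)", call. = FALSE)
  }
  coefs <- t(qr.coef(qr_m, t(volumes))) # T x K
  if (variance_normalize) {
    s <- apply(coefs, 2, stats::sd)
    s[s == 0] <- 1
    coefs <- sweep(coefs, 2, s, "/")
  }
  colnames(coefs) <- colnames(maps) %||% sprintf("net_%02d", seq_len(k))
  network_timeseries(coefs, tr_s = tr_s)
}

# Centered moving average with shrinking (truncated) windows at the edges,
# so output length equals input length.
moving_average <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Temporally smooth network timeseries with a moving average
#'
#' Each network column is replaced by its centered moving average over a
#' window of `span_s` seconds (rounded to the nearest odd number of samples).
#' Edges use shrinking windows, so the output has the same length as the
#' input. The default 5-s span is close to the time-to-peak of the
#' hemodynamic response.
#'
#' @param ts A network timeseries tibble (single run or cohort; cohorts are
#'   smoothed run by run).
#' @param span_s Smoothing span in seconds (default 5). A span equal to the
#'   sampling interval leaves the data unchanged.
#' @return The smoothed timeseries, same shape as the input.
#' @export
smooth_networks <- function(ts, span_s = 5) {
  check_scalar_number(span_s, "span_s", positive = TRUE)
  pieces <- split_runs(ts)
  out <- purrr::map(pieces, function(p) {
    run <- p$data
    tr <- infer_tr(run$time_s)
    if (span_s < tr) stop("`span_s` must be at least the sampling interval", call. = FALSE)
    w <- round(span_s / tr)
    if (w %% 2 == 0) w <- w + 1L # keep the window centered
    if (w > nrow(run)) stop("smoothing span exceeds run length", call. = FALSE)
    nets <- network_cols(run)
    run[nets] <- purrr::map(run[nets], moving_average, w = w)
    p$result <- run
    p$keys <- p$keys[, setdiff(names(p$keys), names(run)), drop = FALSE]
    p
  })
  bind_runs(out)
}
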