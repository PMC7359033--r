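# Transition and meta-stable timepoint detection on mean step distance
# vectors: peak finding with prominence and width criteria, threshold
# calibration, and transition rates.

# Local maxima of a vector; a plateau counts once, at its leftmost sample.
# Endpoints are never peaks.
local_maxima <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Prominence of each peak: height above the higher of the two bounding
# saddles, where each saddle is the minimum between the peak and the nearest
# higher sample (or the signal edge) on that side.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  t(vapply(peaks, function(p) {
    h <- x[p]
    i <- p - 1L
    lmin <- h
    lbase <- p
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) {
        lmin <- x[i]
        lbase <- i
      }
      i <- i - 1L
    }
    i <- p + 1L
    rmin <- h
    rbase <- p
    while (i <= n && x[i] <= h) {
      if (x[i] < rmin) {
        rmin <- x[i]
        rbase <- i
      }
      i <- i + 1L
    }
    c(prominence = h - max(lmin, rmin), left_base = lbase, right_base = rbase)
  }, numeric(3)))
}

# Width of each peak at a reference height `rel_height` of the way down its
# prominence, with linear interpolation at the crossings (samples).
peak_widths <- function(x, peaks, prominences, left_bases, right_bases,
                        rel_height = 0.5) {
  vapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    href <- x[p] - rel_height * prominences[k]
    i <- p
    while (i > left_bases[k] && x[i - 1L] > href) i <- i - 1L
    left_ip <- if (i > left_bases[k] && x[i - 1L] < href) {
      (i - 1L) + (href - x[i - 1L]) / (x[i] - x[i - 1L])
    } else {
      if (i > left_bases[k]) i - 1L else as.numeric(left_bases[k])
    }
    i <- p
    while (i < right_bases[k] && x[i + 1L] > href) i <- i + 1L
    right_ip <- if (i < right_bases[k] && x[i + 1L] < href) {
      (i + 1L) - (href - x[i + 1L]) / (x[i] - x[i + 1L])
    } else {
      if (i < right_bases[k]) i + 1L else as.numeric(right_bases[k])
    }
    right_ip - left_ip
  }, numeric(1))
}

sdv_vector <- function(sdv) {
  if (is.data.frame(sdv)) {
    list(step = sdv$step, t_s = sdv$t_s)
  } else {
    list(step = as.numeric(sdv), t_s = seq_along(sdv))
  }
}

#' Detect transition timepoints in a mean step distance vector
#'
#' Transitions are local maxima of the mean step distance vector whose peak
#' prominence is at least `mpp`. Prominence (the height of a peak above the
#' higher of its two bounding saddles) is used instead of a plain height
#' threshold so that the neighborhood of each peak is taken into account.
#'
#' @param sdv Step distance tibble from [ensemble_step_distance()] (columns
#'   `t_s`, `step`; cohorts are processed per run), or a bare numeric vector.
#' @param mpp Minimum peak prominence (default 0.06, the calibrated value at
#'   which roughly 80% of all step distance values fall below the 5th
#'   percentile transition-associated value; see [calibrate_mpp()]).
#' @return Tibble of detected timepoints: identifier columns (if present),
#'   `onset_s`, `kind = "transition"` and `prominence`. May be empty.
#' @export
find_transitions <- function(sdv, mpp = 0.06) {
  check_scalar_number(mpp, "mpp")
  detect_peaks_tbl(sdv, function(v) {
    x <- v$step
    pk <- local_maxima(x)
    if (length(pk) == 0) {
      return(tibble::tibble(
        onset_s = numeric(0), kind = character(0), prominence = numeric(0)
      ))
    }
    pr <- peak_prominences(x, pk)
    keep <- pr[, "prominence"] >= mpp
    tibble::tibble(
      onset_s = v$t_s[pk[keep]],
      kind = "transition",
      prominence = unname(pr[keep, "prominence"])
    )
  })
}

#' Detect meta-stable timepoints in a mean step distance vector
#'
#' The step distance vector is inverted and peaks of the inverted signal
#' (troughs of the original) are kept when their width at half prominence is
#' at least `min_width_samples`, so that only persistently meta-stable
#' periods qualify. No prominence threshold is applied.
#'
#' @inheritParams find_transitions
#' @param min_width_samples Minimum trough width in samples (default 10;
#'   samples equal seconds at the 1-s sampling interval the method targets).
#' @return Tibble with `onset_s` (the trough sample), `kind = "metastable"`
#'   and `width` (samples).
#' @export
find_metastable <- function(sdv, min_width_samples = 10) {
  check_scalar_number(min_width_samples, "min_width_samples", positive = TRUE)
  detect_peaks_tbl(sdv, function(v) {
    x <- -v$step
    pk <- local_maxima(x)
    if (length(pk) == 0) {
      return(tibble::tibble(
        onset_s = numeric(0), kind = character(0), width = numeric(0)
      ))
    }
    pr <- peak_prominences(x, pk)
    w <- peak_widths(x, pk, pr[, "prominence"], pr[, "left_base"], pr[, "right_base"])
    keep <- w >= min_width_samples
    tibble::tibble(
      onset_s = v$t_s[pk[keep]],
      kind = "metastable",
      width = unname(w[keep])
    )
  })
}

detect_peaks_tbl <- function(sdv, fn) {
  if (!is.data.frame(sdv)) {
    return(fn(sdv_vector(sdv)))
  }
  pieces <- split_runs(sdv)
  out <- purrr::map(pieces, function(p) {
    p$result <- fn(sdv_vector(p$data))
    p
  })
  bind_runs(out)
}

#' Detect both transition and meta-stable timepoints
#'
#' Convenience wrapper returning the union of [find_transitions()] and
#' [find_metastable()] results in one tibble.
#'
#' @inheritParams find_transitions
#' @inheritParams find_metastable
#' @export
detect_timepoints <- function(sdv, mpp = 0.06, min_width_samples = 10) {
  tr <- find_transitions(sdv, mpp = mpp)
  ms <- find_metastable(sdv, min_width_samples = min_width_samples)
  dplyr::bind_rows(tr, ms)
}

#' Calibrate the minimum peak prominence threshold
#'
#' For each candidate threshold, transitions are detected across all supplied
#' step distance vectors, the 5th percentile of step distance values at
#' transition timepoints is computed, and the fraction of all step distance
#' values below that percentile recorded. The returned grid value is the one
#' whose fraction is closest to `target_fraction` (0.80 reproduces the
#' published calibration that selected 0.06).
#'
#' @param sdvs A cohort step distance tibble, or a list of step distance
#'   tibbles/vectors.
#' @param target_fraction Target fraction of all values below the 5th
#'   percentile transition-associated value (default 0.80).
#' @param grid Strictly increasing candidate thresholds.
#' @return The selected grid value, with the achieved fractions attached as
#'   attribute `"fractions"`. Warns if the target is outside the achievable
#'   range (the boundary grid value is returned).
#' @export
calibrate_mpp <- function(sdvs, target_fraction = 0.80,
                          grid = seq(0.01, 0.11, by = 0.01)) {
  if (is.null(grid) || length(grid) == 0 || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  if (is.data.frame(sdvs)) {
    sdvs <- purrr::map(split_runs(sdvs), "data")
  }
  if (length(sdvs) == 0) stop("need at least one step distance vector", call. = FALSE)
  all_steps <- unlist(purrr::map(sdvs, function(s) sdv_vector(s)$step))
  frac <- vapply(grid, function(mpp) {
    at_tr <- unlist(purrr::map(sdvs, function(s) {
      tp <- find_transitions(s, mpp = mpp)
      v <- sdv_vector(s)
      v$step[match(tp$onset_s, v$t_s)]
    }))
    if (length(at_tr) == 0) {
      return(NA_real_)
    }
    q5 <- stats::quantile(at_tr, 0.05, names = FALSE)
    mean(all_steps < q5)
  }, numeric(1))
  if (all(is.na(frac))) {
    stop("no transitions detected at any grid value", call. = FALSE)
  }
  best <- which.min(abs(frac - target_fraction))
  rng <- range(frac, na.rm = TRUE)
  if ((target_fraction < rng[1] || target_fraction > rng[2]) &&
    best %in% c(1L, length(grid))) {
    warning("target fraction outside achievable range; returning boundary grid value")
  }
  structure(grid[best], fractions = stats::setNames(frac, grid))
}

#' Transition rate in transitions per minute
#'
#' @param tp Timepoint tibble from [find_transitions()] (rows with other
#'   `kind` values are ignored), or a bare count.
#' @param duration_min Run duration in minutes.
#' @return Transitions per minute.
#' @export
transition_rate <- function(tp, duration_min) {
  check_scalar_number(duration_min, "duration_min", positive = TRUE)
  n <- if (is.data.frame(tp)) {
    if ("kind" %in% names(tp)) sum(tp$kind == "transition") else nrow(tp)
  } else {
    as.numeric(tp)
  }
  n / duration_min
}

#' Per-run transition rates for a cohort
#'
#' @param tp Cohort timepoint tibble with `participant_id` (and optionally
#'   `run_id`) columns.
#' @param duration_min Run duration in minutes (shared across runs).
#' @param keys Optional tibble of participant/run keys to report; runs with
#'   no detected transitions then appear with rate 0 instead of being
#'   dropped.
#' @return Tibble of keys plus `n_transitions` and `rate_per_min`.
#' @export
transition_rates <- function(tp, duration_min, keys = NULL) {
  check_scalar_number(duration_min, "duration_min", positive = TRUE)
  kc <- intersect(c("participant_id", "run_id"), names(tp))
  if (length(kc) == 0) stop("`tp` has no participant/run columns", call. = FALSE)
  if ("kind" %in% names(tp)) tp <- dplyr::filter(tp, .data$kind == "transition")
  counts <- dplyr::summarise(
    dplyr::group_by(tp, dplyr::across(dplyr::all_of(kc))),
    n_transitions = dplyr::n(), .groups = "drop"
  )
  if (!is.null(keys)) {
    counts <- dplyr::left_join(keys, counts, by = kc)
    counts$n_transitions[is.na(counts$n_transitions)] <- 0L
  }
  dplyr::mutate(counts, rate_per_min = .data$n_transitions / duration_min)
}
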