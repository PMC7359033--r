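# Movie and motion feature timeseries: construction, the censoring cascade
# that disentangles nested feature levels, hemodynamic-lag sampling at
# detected onsets, and the eta-squared alignment statistic.
#
# A feature timeseries is a tibble with columns `feature` (name), `kind`
# ("boundary" or "continuous"), `time_s` (integer 1-s bins starting at 0),
# `value`, and `usable` (censoring mask, TRUE = usable). Several features
# stack into one long tibble.

#' Binarized boundary feature from onset times
#'
#' Onsets are allocated to the nearest 1-s time bin; coincident onsets
#' collapse to a single 1.
#'
#' @param onsets_s Onset times in seconds, each within `[0, duration_s]`.
#' @param duration_s Run duration in seconds (number of 1-s bins).
#' @param name Feature name (default "events").
#' @return A feature tibble with 0/1 `value`.
#' @export
boundary_vector <- function(onsets_s, duration_s, name = "events") {
  duration_s <- as.integer(duration_s)
  if (any(onsets_s < 0 | onsets_s > duration_s)) {
    stop("onsets must lie within [0, duration_s]", call. = FALSE)
  }
  v <- numeric(duration_s)
  if (length(onsets_s) > 0) {
    bins <- pmin(round(onsets_s), duration_s - 1L) + 1L
    v[unique(bins)] <- 1
  }
  tibble::tibble(
    feature = name, kind = "boundary",
    time_s = seq_len(duration_s) - 1L, value = v, usable = TRUE
  )
}

#' Continuous change-magnitude feature from a multi-channel timeseries
#'
#' `"sum_derivative"` sums across channels and takes the first difference
#' (the construction used for the semantic and motion-energy label sets);
#' `"abs_derivative"` takes the absolute first difference of a single
#' channel (the construction used for auditory amplitude). The output keeps
#' the input length, with a leading 0.
#'
#' @param feature_matrix T x C numeric matrix (C = 1 for `abs_derivative`).
#' @param mode `"sum_derivative"` or `"abs_derivative"`.
#' @param name Feature name.
#' @return A continuous feature tibble.
#' @export
change_magnitude <- function(feature_matrix, mode = c("sum_derivative", "abs_derivative"),
                             name = "semantic_change") {
  mode <- match.arg(mode)
  m <- as.matrix(feature_matrix)
  if (nrow(m) < 2) stop("need at least 2 timepoints", call. = FALSE)
  v <- switch(mode,
    sum_derivative = c(0, diff(rowSums(m))),
    abs_derivative = c(0, abs(diff(m[, 1])))
  )
  tibble::tibble(
    feature = name, kind = "continuous",
    time_s = seq_len(nrow(m)) - 1L, value = v, usable = TRUE
  )
}

#' Censoring cascade across nested feature levels
#'
#' Higher-level boundaries censor all lower-level features in a centered
#' `window_s`-second window (3 s = the boundary bin and one bin on each
#' side): event boundaries censor everything else, sub-event boundaries
#' censor everything except events, and cuts censor everything except events
#' and sub-events. Features not named in the hierarchy (the continuous and
#' motion features) sit below every level. Independently, the first
#' `clip_censor_s` seconds of each clip are censored in every feature, in
#' both the censored and uncensored variants, to remove clip-onset
#' artifacts.
#'
#' @param features Long feature tibble (several features stacked).
#' @param hierarchy Boundary feature names, highest level first. Default
#'   `c("events", "sub_events", "cuts")`.
#' @param window_s Censoring window in seconds, centered on each boundary
#'   (odd; default 3).
#' @param clip_starts_s Clip start times in seconds (default none).
#' @param clip_censor_s Seconds censored at the start of each clip
#'   (default 6).
#' @return A list with elements `censored` (cascade + clip censoring applied
#'   to the `usable` column) and `uncensored` (clip censoring only).
#' @export
censor_cascade <- function(features, hierarchy = c("events", "sub_events", "cuts"),
                           window_s = 3, clip_starts_s = numeric(),
                           clip_censor_s = 6) {
  stopifnot(is.data.frame(features))
  present <- unique(features$feature)
  missing_h <- setdiff(hierarchy, present)
  if (length(missing_h) > 0) {
    stop(
      sprintf("hierarchy feature(s) not found: %s", paste(missing_h, collapse = ", ")),
      call. = FALSE
    )
  }
  bkinds <- unique(features$kind[features$feature %in% hierarchy])
  if (!all(bkinds == "boundary")) {
    stop("hierarchy features must all be boundary features", call. = FALSE)
  }
  if (window_s %% 2 != 1) stop("`window_s` must be odd", call. = FALSE)
  half <- (window_s - 1) / 2

  tmax <- max(features$time_s)
  clip_bins <- unlist(purrr::map(clip_starts_s, function(s) {
    seq(floor(s), min(floor(s) + clip_censor_s - 1, tmax))
  }))
  level <- match(features$feature, hierarchy) # NA = below every level

  mask_clip <- features$time_s %in% clip_bins
  uncensored <- dplyr::mutate(features, usable = .data$usable & !mask_clip)

  censored <- uncensored
  for (li in seq_along(hierarchy)) {
    b <- dplyr::filter(features, .data$feature == hierarchy[li], .data$value == 1)
    if (nrow(b) == 0) next
    win <- unique(unlist(purrr::map(b$time_s, function(t) (t - half):(t + half))))
    below <- is.na(level) | level > li
    censored$usable <- censored$usable &
      !(below & censored$time_s %in% win)
  }
  list(censored = censored, uncensored = uncensored)
}

# Mean usable feature value in the HRF-lag window preceding one onset set.
# Bins t - lag_window_s[2] .. t - lag_window_s[1] (inclusive integer bins).
# Onsets whose window extends beyond the run, or contains no usable bin, are
# skipped; the rule is applied uniformly to censored and uncensored data.
sample_window_means <- function(f, onsets_s, lag_window_s) {
  vapply(onsets_s, function(t) {
    bins <- (floor(t) - lag_window_s[2]):(floor(t) - lag_window_s[1])
    if (any(bins < min(f$time_s)) || any(bins > max(f$time_s))) {
      return(NA_real_)
    }
    i <- match(bins, f$time_s)
    i <- i[!is.na(i)]
    i <- i[f$usable[i]]
    if (length(i) == 0) NA_real_ else mean(f$value[i])
  }, numeric(1))
}

#' Average feature value in an HRF-lagged window before onsets
#'
#' For each onset, the feature is averaged over the usable 1-s bins in a
#' window `lag_window_s` seconds earlier (default 3-6 s, working backwards
#' along the canonical hemodynamic response), and the mean over surviving
#' onsets returned. Onsets are skipped when their window extends beyond the
#' run or contains no usable (uncensored) bins - the same rule for censored
#' and uncensored data; if every onset is skipped the result is `NA` with a
#' warning.
#'
#' @param f A single feature's tibble (with `usable` mask applied as
#'   desired, e.g. one element of [censor_cascade()] output filtered to one
#'   feature).
#' @param onsets_s Onset times in seconds (nonempty), e.g. the `onset_s`
#'   column of [find_transitions()] output.
#' @param lag_window_s Two numbers, earliest and latest lag in seconds
#'   (default `c(3, 6)`).
#' @return Grand mean feature value across surviving onsets.
#' @export
sample_at_onsets <- function(f, onsets_s, lag_window_s = c(3, 6)) {
  if (length(onsets_s) == 0) stop("`onsets_s` must be nonempty", call. = FALSE)
  stopifnot(length(lag_window_s) == 2, lag_window_s[1] <= lag_window_s[2])
  per <- sample_window_means(f, onsets_s, lag_window_s)
  if (all(is.na(per))) {
    warning("all onsets skipped (no usable bins in any lag window)")
    return(NA_real_)
  }
  mean(per, na.rm = TRUE)
}

#' Feature alignment to transitions vs meta-stability (eta-squared)
#'
#' For each feature and participant, the mean feature value in the
#' HRF-lagged window before transition onsets and before meta-stable onsets
#' is computed per run and averaged across runs, giving one
#' transition-minus-meta-stable difference per participant. A paired t test
#' across participants yields `t` and `df = n - 1`, converted to the
#' proportion of feature variance explained, `eta_sq = t^2 / (t^2 + df)`.
#' A percentile bootstrap of the mean difference gives a CI whose bounds are
#' divided by the plug-in standard error of the differences and converted to
#' eta-squared the same way.
#'
#' @param features Long feature tibble (e.g. the `censored` element of
#'   [censor_cascade()]); if it has a `run_id` column features are matched to
#'   onsets by run.
#' @param onsets Cohort timepoint tibble containing both kinds, i.e.
#'   [detect_timepoints()] output with `participant_id` (and optionally
#'   `run_id`) columns.
#' @param n_boot,seed,probs Bootstrap settings as in [bootstrap_mean()].
#' @param lag_window_s HRF lag window, see [sample_at_onsets()].
#' @return A tibble with one row per feature: participant means, `t`, `df`,
#'   `eta_sq`, CI bounds, `direction` (+1 = aligned to transitions, -1 = to
#'   meta-stability) and a `flagged` column for degenerate (zero-variance)
#'   cases.
#' @export
feature_alignment <- function(features, onsets, n_boot = 1000, seed = 1L,
                              lag_window_s = c(3, 6), probs = c(0.025, 0.975)) {
  stopifnot(is.data.frame(features), is.data.frame(onsets))
  if (!"participant_id" %in% names(onsets)) {
    stop("`onsets` must have a participant_id column", call. = FALSE)
  }
  by_run <- "run_id" %in% names(features) && "run_id" %in% names(onsets)
  feat_names <- unique(features$feature)
  seed <- check_seed(seed)

  purrr::map_dfr(seq_along(feat_names), function(fi) {
    fname <- feat_names[fi]
    f_all <- dplyr::filter(features, .data$feature == fname)
    per_ppt <- onsets |>
      dplyr::group_by(dplyr::across(dplyr::all_of(intersect(
        c("participant_id", "run_id"), names(onsets)
      )))) |>
      dplyr::group_map(function(g, key) {
        f <- if (by_run) dplyr::filter(f_all, .data$run_id == key$run_id) else f_all
        tr <- g$onset_s[g$kind == "transition"]
        ms <- g$onset_s[g$kind == "metastable"]
        if (length(tr) == 0 || length(ms) == 0 || nrow(f) == 0) {
          return(NULL)
        }
        mt <- suppressWarnings(sample_at_onsets(f, tr, lag_window_s))
        mm <- suppressWarnings(sample_at_onsets(f, ms, lag_window_s))
        tibble::tibble(
          participant_id = key$participant_id,
          m_transition = mt, m_metastable = mm
        )
      }) |>
      dplyr::bind_rows()
    if (nrow(per_ppt) == 0) {
      return(tibble::tibble(
        feature = fname, n_participants = 0L, flagged = TRUE
      ))
    }
    by_p <- per_ppt |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(
        m_transition = mean(.data$m_transition, na.rm = TRUE),
        m_metastable = mean(.data$m_metastable, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::filter(is.finite(.data$m_transition), is.finite(.data$m_metastable))
    n <- nrow(by_p)
    if (n < 3) {
      return(tibble::tibble(
        feature = fname, n_participants = n, flagged = TRUE
      ))
    }
    d <- by_p$m_transition - by_p$m_metastable
    se <- stats::sd(d) / sqrt(n)
    df <- n - 1L
    if (!is.finite(se) || se == 0) {
      return(tibble::tibble(
        feature = fname,
        mean_transition_value = mean(by_p$m_transition),
        mean_metastable_value = mean(by_p$m_metastable),
        t = NA_real_, df = df, eta_sq = NA_real_,
        eta_sq_low = NA_real_, eta_sq_high = NA_real_,
        direction = sign(mean(d)), n_participants = n, flagged = TRUE
      ))
    }
    tstat <- mean(d) / se
    eta <- tstat^2 / (tstat^2 + df)
    b <- bootstrap_mean(d, n_boot = n_boot, seed = seed + fi, probs = probs)
    t_bounds <- b$ci / se
    eta_bounds <- sort(t_bounds^2 / (t_bounds^2 + df))
    # CI straddling zero reaches down to eta = 0
    if (prod(sign(t_bounds)) <= 0) eta_bounds[1] <- 0
    tibble::tibble(
      feature = fname,
      mean_transition_value = mean(by_p$m_transition),
      mean_metastable_value = mean(by_p$m_metastable),
      t = tstat, df = df, eta_sq = eta,
      eta_sq_low = eta_bounds[1], eta_sq_high = eta_bounds[2],
      ci_contains_zero = prod(sign(b$ci)) <= 0,
      direction = ifelse(tstat >= 0, 1, -1),
      n_participants = n, flagged = FALSE
    )
  })
}

#' Regress a feature timeseries on the network node timeseries
#'
#' Ordinary least squares of the (binned) feature on the K network columns
#' of one run; the adjusted R-squared measures how well individual network
#' activity predicts the feature. Cohorts give one value per
#' participant/run.
#'
#' @param ts Network timeseries tibble.
#' @param f A single feature's tibble (only bins present in both are used).
#' @return Tibble with identifier columns and `adj_r_squared`.
#' @export
per_network_feature_regression <- function(ts, f) {
  pieces <- split_runs(ts)
  out <- purrr::map(pieces, function(p) {
    run <- p$data
    x <- as_run_matrix(run)
    i <- match(round(run$time_s), f$time_s)
    ok <- !is.na(i)
    y <- f$value[i[ok]]
    x <- x[ok, , drop = FALSE]
    if (nrow(x) < ncol(x) + 2) {
      stop("too few timepoints for the number of networks", call. = FALSE)
    }
    if (qr(cbind(1, x))$rank < ncol(x) + 1) {
      stop("network design is rank deficient", call. = FALSE)
    }
    fit <- stats::lm(y ~ x)
    p$result <- tibble::tibble(adj_r_squared = summary(fit)$adj.r.squared)
    p
  })
  bind_runs(out)
}
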