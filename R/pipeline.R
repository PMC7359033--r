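# Pipeline orchestration: resolved configurations and parameter sweeps.

#' Resolved analysis configuration
#'
#' Collects every tunable of the pipeline with its default, so that analysis
#' outputs can embed the full configuration and seed they were produced
#' under. Serializes to JSON.
#'
#' @param seed Base seed.
#' @param n_iter Embedding repetitions per run.
#' @param n_boot Bootstrap resamples.
#' @param perplexity,max_iter t-SNE settings.
#' @param mpp Minimum peak prominence.
#' @param min_width_samples Meta-stable minimum width.
#' @param span_s Temporal smoothing span (seconds).
#' @param trim_epochs Conformity trimming.
#' @param lag_window_s HRF lag window.
#' @param censor_window_s Boundary censoring window.
#' @param clip_censor_s Clip-onset censoring.
#' @return A `metastate_config` list.
#' @export
run_config <- function(seed = 1L, n_iter = 100, n_boot = 1000, perplexity = 30,
                       max_iter = 350, mpp = 0.06, min_width_samples = 10,
                       span_s = 5, trim_epochs = 5, lag_window_s = c(3, 6),
                       censor_window_s = 3, clip_censor_s = 6) {
  structure(
    list(
      seed = check_seed(seed), n_iter = n_iter, n_boot = n_boot,
      perplexity = perplexity, max_iter = max_iter, mpp = mpp,
      min_width_samples = min_width_samples, span_s = span_s,
      trim_epochs = trim_epochs, lag_window_s = lag_window_s,
      censor_window_s = censor_window_s, clip_censor_s = clip_censor_s
    ),
    class = "metastate_config"
  )
}

#' @export
print.metastate_config <- function(x, ...) {
  cat("<metastate_config>\n")
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE), "\n")
  invisible(x)
}

#' Write / read a configuration as JSON
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Sweep a pipeline parameter and re-run detection (and alignment)
#'
#' Runs the smooth -> embed -> detect pipeline once per candidate value of
#' the minimum peak prominence (`"mpp"`) or the temporal smoothing span
#' (`"span_s"`), reporting the mean transition rate and, when planted
#' features are supplied, the eta-squared alignment per feature. For the
#' `mpp` sweep the embeddings are computed once and only detection is
#' repeated.
#'
#' @param ts Cohort network timeseries tibble (unsmoothed).
#' @param param `"mpp"` or `"span_s"`.
#' @param values Candidate values (the reference analysis used
#'   0.01..0.11 for mpp and 1, 3, 5, 7, 9 s for the span).
#' @param features Optional feature tibble for alignment (see
#'   [feature_alignment()]).
#' @param mpp,min_width_samples,span_s Fixed values of the non-swept
#'   parameters.
#' @param n_iter,n_boot,seed,perplexity,max_iter Embedding and bootstrap
#'   settings (CIs are not needed here, so `n_boot` only affects
#'   alignment).
#' @return Tidy tibble: `param`, `value`, `mean_rate_per_min`,
#'   `mean_n_transitions`, and per-feature `eta_sq` rows when features are
#'   given.
#' @export
sweep_parameter <- function(ts, param = c("mpp", "span_s"), values,
                            features = NULL, mpp = 0.06,
                            min_width_samples = 10, span_s = 5, n_iter = 20,
                            n_boot = 200, seed = 1L, perplexity = 30,
                            max_iter = 350) {
  param <- match.arg(param)
  if (length(values) == 0) stop("`values` must be nonempty", call. = FALSE)
  seed <- check_seed(seed)
  duration_min <- (max(ts$time_s) - min(ts$time_s) + infer_tr(ts$time_s)) / 60

  sdv_for_span <- function(sp) {
    ts |>
      smooth_networks(span_s = sp) |>
      ensemble_step_distance(
        n_iter = n_iter, n_boot = 0, seed = seed,
        perplexity = perplexity, max_iter = max_iter
      )
  }
  eval_one <- function(sdv, mpp_val, value) {
    tp <- detect_timepoints(sdv, mpp = mpp_val, min_width_samples = min_width_samples)
    tr <- dplyr::filter(tp, .data$kind == "transition")
    rates <- transition_rates(tr, duration_min,
      keys = dplyr::distinct(ts, .data$participant_id, .data$run_id)
    )
    base <- tibble::tibble(
      param = param, value = value,
      mean_rate_per_min = mean(rates$rate_per_min),
      mean_n_transitions = mean(rates$n_transitions)
    )
    if (!is.null(features)) {
      al <- feature_alignment(features, tp, n_boot = n_boot, seed = seed)
      base <- dplyr::bind_cols(
        base[rep(1, nrow(al)), ],
        al[, c("feature", "eta_sq", "direction")]
      )
    }
    base
  }

  if (param == "mpp") {
    sdv <- sdv_for_span(span_s)
    purrr::map_dfr(values, function(v) eval_one(sdv, v, v))
  } else {
    purrr::map_dfr(values, function(v) eval_one(sdv_for_span(v), mpp, v))
  }
}
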