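# Group-level metrics: conformity of an individual's step distance vector to
# the leave-one-out group median (run- and clip-level), ICC(2,k)
# trait-stability, and clip-wise covariate correlations.

conformity_one <- function(self, med, trim_epochs, eps) {
  n <- length(self)
  if (n != length(med)) stop("step vectors differ in length", call. = FALSE)
  idx <- (trim_epochs + 1):(n - trim_epochs)
  if (length(idx) < 3) stop("vectors too short after trimming", call. = FALSE)
  a <- log(self[idx] + eps)
  b <- log(med[idx] + eps)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance step vector after trimming", call. = FALSE)
  }
  r <- stats::cor(a, b)
  clamped <- abs(r) >= 1 - 1e-12
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  tibble::tibble(r = r, z = atanh(r), clamped = clamped)
}

# Small positive offset for the logs; near-zero step distances otherwise
# explode the log-correlation.
default_eps <- function(steps) {
  pos <- steps[steps > 0]
  if (length(pos) == 0) {
    return(1e-12)
  }
  1e-6 * stats::median(pos)
}

#' Conformity of each participant's step distance vector to the group
#'
#' For each participant and run, the elementwise median of the other
#' participants' mean step distance vectors is computed (leave-one-out), the
#' first and last `trim_epochs` epochs are discarded to avoid run onset and
#' offset effects, and the Fisher z of the Pearson correlation between the
#' logs of the two vectors is returned. Shared stimulus structure (movies)
#' yields higher conformity than idiosyncratic structure (rest).
#'
#' @param sdv Cohort step distance tibble ([ensemble_step_distance()] output
#'   with a `participant_id` column; multiple runs are handled per `run_id`).
#' @param trim_epochs Epochs dropped at each end (default 5).
#' @param eps Offset added inside the logs. Default `1e-6` times the median
#'   positive step value of the run's cohort.
#' @return Tibble with `participant_id`, `run_id` (if present), `scope`,
#'   `r`, `z` and a `clamped` flag for degenerate perfect correlations.
#' @export
conformity <- function(sdv, trim_epochs = 5, eps = NULL) {
  stopifnot(is.data.frame(sdv), "participant_id" %in% names(sdv))
  run_col <- intersect("run_id", names(sdv))
  grp <- if (length(run_col)) dplyr::group_by(sdv, .data$run_id) else dplyr::group_by(sdv)
  keys <- dplyr::group_keys(grp)
  runs <- dplyr::group_split(grp)
  purrr::map_dfr(seq_along(runs), function(ri) {
    run <- runs[[ri]]
    wide <- run |>
      dplyr::select(dplyr::all_of(c("participant_id", "t_s", "step"))) |>
      tidyr::pivot_wider(names_from = "participant_id", values_from = "step") |>
      dplyr::arrange(.data$t_s)
    m <- as.matrix(wide[, -1, drop = FALSE])
    if (ncol(m) < 3) stop("conformity needs at least 3 participants", call. = FALSE)
    e <- eps %||% default_eps(as.vector(m))
    res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
      med <- apply(m[, -j, drop = FALSE], 1, stats::median)
      out <- conformity_one(m[, j], med, trim_epochs, e)
      dplyr::bind_cols(tibble::tibble(participant_id = colnames(m)[j]), out)
    })
    res$scope <- "run"
    if (nrow(keys) > 0 && ncol(keys) > 0) {
      dplyr::bind_cols(keys[rep(ri, nrow(res)), , drop = FALSE], res)
    } else {
      res
    }
  })
}

#' Clip-level conformity
#'
#' [conformity()] restricted to each clip's timepoints: the leave-one-out
#' median, trimming and log-correlation are computed within each clip
#' separately.
#'
#' @inheritParams conformity
#' @param clips Tibble with `clip_id`, `start_s`, `end_s` (clip intervals,
#'   end exclusive).
#' @return One conformity row per participant x clip, `scope = "clip"`.
#' @export
clip_conformity <- function(sdv, clips, trim_epochs = 5, eps = NULL) {
  stopifnot(is.data.frame(clips), all(c("clip_id", "start_s", "end_s") %in% names(clips)))
  purrr::map_dfr(seq_len(nrow(clips)), function(ci) {
    cl <- clips[ci, ]
    piece <- dplyr::filter(sdv, .data$t_s >= cl$start_s, .data$t_s < cl$end_s)
    if (length(unique(piece$t_s)) < 2 * trim_epochs + 3) {
      stop(sprintf(
        "clip %s too short for trim_epochs = %d", cl$clip_id, trim_epochs
      ), call. = FALSE)
    }
    out <- conformity(piece, trim_epochs = trim_epochs, eps = eps)
    out$scope <- "clip"
    out$clip_id <- cl$clip_id
    out
  })
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' Quantifies how consistent a participant-level measure (one row per
#' participant) is across runs (columns), from the standard two-way ANOVA
#' mean squares:
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#' The F test is `MSR / MSE` with `df = (n - 1, (n - 1)(k - 1))`, and the
#' confidence interval follows the usual two-way absolute-agreement
#' construction (single-measure bounds stepped up with Spearman-Brown).
#'
#' @param m Numeric matrix, participants x runs, no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci`, `f_stat`, `df1`,
#'   `df2`, `p`, and the mean squares. Zero between-participant variance is
#'   degenerate and warns.
#' @export
icc_2k <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2 x 2 matrix", call. = FALSE)
  if (anyNA(m)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  gm <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  sse <- sum((m - outer(rowm, colm, "+") + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  if (msr <= .Machine$double.eps * abs(gm + 1)) {
    warning("zero between-participant variance; ICC is degenerate")
  }
  f_stat <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  # CI via the single-measure absolute-agreement bounds
  r1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * r1 / (n * (1 - r1))
  b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  structure(
    list(
      icc = icc, ci = c(sb(l1), sb(u1)), conf_level = conf_level,
      f_stat = f_stat, df1 = df1, df2 = df2, p = p,
      ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(2,k) = %.3f, %g%% CI [%.3f, %.3f], F(%d, %d) = %.2f, p = %.3g\n",
    x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$df1, x$df2, x$f_stat, x$p
  ))
  invisible(x)
}

#' Correlate a per-clip metric with a per-clip covariate across participants
#'
#' Each participant's metric values over clips are correlated with the
#' covariate (e.g. clip arousal ratings, or events per minute), and the
#' distribution of per-participant correlation coefficients is summarized by
#' [bootstrap_mean()].
#'
#' @param per_clip_metric Tibble with `participant_id`, `clip_id`, `value`
#'   (one metric value per participant per clip).
#' @param covariate Tibble with `clip_id`, `value`, or a vector named by
#'   clip id.
#' @param n_boot,seed,probs Bootstrap settings.
#' @return A `metastate_boot` object with the per-participant correlations
#'   attached as element `r_values`.
#' @export
clipwise_metric_correlation <- function(per_clip_metric, covariate,
                                        n_boot = 1000, seed = 1L,
                                        probs = c(0.025, 0.975)) {
  stopifnot(is.data.frame(per_clip_metric))
  if (is.data.frame(covariate)) {
    covariate <- stats::setNames(covariate$value, covariate$clip_id)
  }
  if (length(covariate) < 3) stop("need at least 3 clips", call. = FALSE)
  if (any(!is.finite(covariate))) stop("covariate must be finite", call. = FALSE)
  if (stats::sd(covariate) == 0) stop("covariate is constant", call. = FALSE)
  rs <- per_clip_metric |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      r = stats::cor(
        .data$value,
        covariate[as.character(.data$clip_id)]
      ),
      .groups = "drop"
    )
  rvec <- rs$r[is.finite(rs$r)]
  out <- bootstrap_mean(rvec, n_boot = n_boot, seed = seed, probs = probs)
  out$r_values <- stats::setNames(rs$r, rs$participant_id)
  out
}
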