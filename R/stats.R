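# Shared bootstrap machinery: means, correlations, correlation differences,
# and the bootstrap ratio (BSR) statistic used throughout the analyses.

new_boot_result <- function(estimate, boot, probs, n, n_removed = 0L,
                            one_tailed = FALSE, extra = list()) {
  # type 1 (inverse ECDF): CI endpoints are order statistics of the
  # recorded bootstrap distribution
  ci <- unname(stats::quantile(boot, probs, names = FALSE, type = 1))
  bsd <- stats::sd(boot)
  degenerate <- !is.finite(bsd) || bsd == 0
  bsr <- if (degenerate) {
    if (mean(boot) == 0) 0 else sign(mean(boot)) * Inf
  } else {
    mean(boot) / bsd
  }
  p <- if (is.infinite(bsr)) 0 else if (one_tailed) {
    stats::pnorm(-abs(bsr))
  } else {
    2 * stats::pnorm(-abs(bsr))
  }
  structure(
    c(
      list(
        estimate = estimate, ci = ci, bsr = bsr, p = p,
        n_boot = length(boot), n = n, n_removed_outliers = n_removed,
        probs = probs, one_tailed = one_tailed, degenerate = degenerate,
        boot = boot
      ),
      extra
    ),
    class = "metastate_boot"
  )
}

#' Percentile bootstrap of a mean with bootstrap ratio
#'
#' Resamples the input values with replacement `n_boot` times, records the
#' mean of each resample, and summarizes the resulting sampling distribution:
#' a percentile confidence interval, the bootstrap ratio
#' (BSR = bootstrap mean / bootstrap SE, treated as approximately standard
#' normal) and the corresponding normal-theory p value.
#'
#' @param x Numeric vector of at least 3 finite values.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; results are bit-identical for a fixed seed.
#' @param probs Percentile CI bounds. Default `c(0.025, 0.975)` (a 95% CI);
#'   use `c(0.05, 0.95)` for 5th/95th percentile bounds.
#' @param one_tailed Report a one-tailed p value (directional hypotheses).
#' @return A `metastate_boot` object; see [tidy.metastate_boot()].
#' @examples
#' b <- bootstrap_mean(rnorm(50), seed = 1)
#' tidy(b)
#' @export
bootstrap_mean <- function(x, n_boot = 1000, seed = 1L,
                           probs = c(0.025, 0.975), one_tailed = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be numeric with all values finite", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 values to bootstrap", call. = FALSE)
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  seed <- check_seed(seed)
  withr_seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot <- rowMeans(matrix(x[idx], nrow = n_boot))
  new_boot_result(mean(x), boot, probs, n, one_tailed = one_tailed)
}

withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# Robust (MAD-based) or plain-SD outlier flags about the median.
outlier_flags <- function(x, k, method) {
  ctr <- stats::median(x)
  scale <- switch(method,
    mad = stats::mad(x), # 1.4826 * median absolute deviation
    sd = stats::sd(x)
  )
  if (!is.finite(scale) || scale == 0) {
    return(rep(FALSE, length(x)))
  }
  abs(x - ctr) > k * scale
}

#' Bootstrap correlation with robust outlier removal
#'
#' Pairs whose x or y value lies more than `outlier_k` robust standard
#' deviations (1.4826 x MAD about the median; `outlier_method = "sd"` uses the
#' plain SD about the median instead) from the marginal median are removed,
#' then pairs are resampled with replacement and the Pearson correlation of
#' each resample recorded.
#'
#' @inheritParams bootstrap_mean
#' @param x,y Paired numeric vectors, length >= 5.
#' @param outlier_k Robust z-score cutoff for outlier removal (default 3).
#' @param outlier_method `"mad"` (default) or `"sd"`.
#' @return A `metastate_boot` object whose `estimate` is the Pearson r of the
#'   retained pairs.
#' @export
bootstrap_corr <- function(x, y, n_boot = 1000, seed = 1L, outlier_k = 3,
                           outlier_method = c("mad", "sd"),
                           probs = c(0.025, 0.975), one_tailed = FALSE) {
  outlier_method <- match.arg(outlier_method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 5) stop("need at least 5 pairs", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  out <- outlier_flags(x, outlier_k, outlier_method) |
    outlier_flags(y, outlier_k, outlier_method)
  n_removed <- sum(out)
  x <- x[!out]
  y <- y[!out]
  n <- length(x)
  if (n < 5) stop("fewer than 5 pairs remain after outlier removal", call. = FALSE)
  seed <- check_seed(seed)
  withr_seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(x[i], y[i]))
  }, numeric(1))
  boot[!is.finite(boot)] <- 0 # constant resample: no evidence either way
  new_boot_result(stats::cor(x, y), boot, probs, n,
    n_removed = n_removed, one_tailed = one_tailed
  )
}

#' Bootstrap difference between two independent correlations
#'
#' Resamples pairs independently within each group and summarizes the
#' distribution of `r_a - r_b`.
#'
#' @inheritParams bootstrap_corr
#' @param xa,ya Paired values for group a.
#' @param xb,yb Paired values for group b.
#' @export
bootstrap_corr_diff <- function(xa, ya, xb, yb, n_boot = 1000, seed = 1L,
                                outlier_k = 3, outlier_method = c("mad", "sd"),
                                probs = c(0.025, 0.975), one_tailed = FALSE) {
  outlier_method <- match.arg(outlier_method)
  clean <- function(x, y) {
    if (length(x) != length(y) || length(x) < 5) {
      stop("each group needs at least 5 pairs", call. = FALSE)
    }
    out <- outlier_flags(x, outlier_k, outlier_method) |
      outlier_flags(y, outlier_k, outlier_method)
    if (sum(!out) < 5) stop("fewer than 5 pairs remain after outlier removal", call. = FALSE)
    list(x = x[!out], y = y[!out], removed = sum(out))
  }
  a <- clean(xa, ya)
  b <- clean(xb, yb)
  seed <- check_seed(seed)
  withr_seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    ia <- sample.int(length(a$x), replace = TRUE)
    ib <- sample.int(length(b$x), replace = TRUE)
    ra <- suppressWarnings(stats::cor(a$x[ia], a$y[ia]))
    rb <- suppressWarnings(stats::cor(b$x[ib], b$y[ib]))
    if (!is.finite(ra)) ra <- 0
    if (!is.finite(rb)) rb <- 0
    ra - rb
  }, numeric(1))
  new_boot_result(stats::cor(a$x, a$y) - stats::cor(b$x, b$y), boot, probs,
    n = length(a$x) + length(b$x),
    n_removed = a$removed + b$removed, one_tailed = one_tailed
  )
}

#' @export
print.metastate_boot <- function(x, ...) {
  cat(sprintf(
    "<bootstrap> estimate = %.4g, %g%% CI [%.4g, %.4g], BSR = %.3g, p = %.3g\n",
    x$estimate, 100 * diff(x$probs), x$ci[1], x$ci[2], x$bsr, x$p
  ))
  if (x$n_removed_outliers > 0) {
    cat(sprintf("  (%d outlier pair(s) removed)\n", x$n_removed_outliers))
  }
  invisible(x)
}
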