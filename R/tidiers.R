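# broom-style tidiers for the package's fitted objects.

#' Tidy a bootstrap result
#'
#' @param x A `metastate_boot` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `bsr`,
#'   `p.value`.
#' @export
tidy.metastate_boot <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, ci_low = x$ci[1], ci_high = x$ci[2],
    bsr = x$bsr, p.value = x$p
  )
}

#' @rdname tidy.metastate_boot
#' @export
glance.metastate_boot <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_boot = x$n_boot,
    n_removed_outliers = x$n_removed_outliers,
    conf_low_prob = x$probs[1], conf_high_prob = x$probs[2],
    one_tailed = x$one_tailed, degenerate = x$degenerate
  )
}

#' Tidy an ICC(2,k) result
#'
#' @param x An `icc_result` object.
#' @param ... Unused.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `statistic`, `df1`,
#'   `df2`, `p.value`.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci[1], ci_high = x$ci[2],
    statistic = x$f_stat, df1 = x$df1, df2 = x$df2, p.value = x$p
  )
}

#' @rdname tidy.icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, conf_level = x$conf_level,
    msr = x$ms["msr"], msc = x$ms["msc"], mse = x$ms["mse"]
  )
}
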