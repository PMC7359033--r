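# ggplot2 displays for the pipeline's result types.

#' Plot a mean step distance vector with detected timepoints
#'
#' Line plus bootstrap CI ribbon; transition onsets are marked with upward
#' triangles, meta-stable onsets with downward triangles.
#'
#' @param sdv Single-run step distance tibble.
#' @param timepoints Optional [detect_timepoints()] tibble for the same run.
#' @return A ggplot object.
#' @export
plot_step_distance <- function(sdv, timepoints = NULL) {
  p <- ggplot2::ggplot(sdv, ggplot2::aes(x = .data$t_s, y = .data$step))
  if (all(c("ci_low", "ci_high") %in% names(sdv))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey70", alpha = 0.6
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.3)
  if (!is.null(timepoints) && nrow(timepoints) > 0) {
    tp <- dplyr::left_join(
      timepoints, sdv[, c("t_s", "step")],
      by = c(onset_s = "t_s")
    )
    p <- p + ggplot2::geom_point(
      data = tp,
      ggplot2::aes(x = .data$onset_s, y = .data$step, shape = .data$kind),
      color = "darkgreen", size = 2
    ) +
      ggplot2::scale_shape_manual(values = c(transition = 24, metastable = 25))
  }
  p + ggplot2::labs(
    x = "time (s)", y = "step distance",
    title = "Mean step distance across embedding repetitions"
  ) +
    ggplot2::theme_minimal()
}

#' Plot a 2-D embedding colored by time
#'
#' Meta-stable periods appear as contiguous, worm-like segments; unstable
#' passages scatter.
#'
#' @param coords [embed_timepoints()] output.
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords) {
  ggplot2::ggplot(coords, ggplot2::aes(.data$dim1, .data$dim2, color = .data$time_s)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_viridis_c(name = "time (s)") +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Plot feature-alignment eta-squared values
#'
#' Filled bars are features aligned to transitions, empty bars to
#' meta-stability; error bars give the bootstrap CI.
#'
#' @param alignment [feature_alignment()] output.
#' @return A ggplot object.
#' @export
plot_alignment <- function(alignment) {
  al <- dplyr::filter(alignment, !.data$flagged)
  al$aligned <- ifelse(al$direction >= 0, "transitions", "meta-stability")
  ggplot2::ggplot(al, ggplot2::aes(
    x = stats::reorder(.data$feature, -.data$eta_sq),
    y = .data$eta_sq, fill = .data$aligned
  )) +
    ggplot2::geom_col(color = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$eta_sq_low, ymax = .data$eta_sq_high),
      width = 0.2
    ) +
    ggplot2::scale_fill_manual(values = c(
      transitions = "grey30",
      `meta-stability` = "white"
    )) +
    ggplot2::labs(x = NULL, y = expression(eta^2), fill = "aligned to") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a parameter sweep
#'
#' @param sweep [sweep_parameter()] output.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$value, .data$mean_rate_per_min)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = unique(sweep$param), y = "mean transitions / min"
    ) +
    ggplot2::theme_minimal()
}
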