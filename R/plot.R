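#' Plot percentile trajectories
#'
#' @param curves output of [trajectory()].
#' @param observed optional [weight_series()] overlaid as points (requires
#'   the curve profile to carry a height so weights convert to BMI).
#' @return a ggplot object.
#' @export
plot_trajectory <- function(curves, observed = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rygb_error("plotting requires the ggplot2 package", "rygb_config_error")
  }
  curves$percentile <- factor(sprintf("%.0fth", 100 * curves$tau))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = months, y = bmi, colour = percentile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Months after surgery", y = "BMI (kg/m²)",
                  colour = "Expected percentile") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    profile <- attr(curves, "profile")
    if (is.null(profile$height)) {
      rygb_error("overlaying observations requires a profile height",
                 "rygb_config_error")
    }
    obs <- data.frame(months = observed$months_post_op,
                      bmi = compute_bmi(observed$weight_kg, profile$height))
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(x = months, y = bmi),
                                 inherit.aes = FALSE)
  }
  p
}

save_trajectory_plot <- function(curves, path, observed = NULL) {
  p <- plot_trajectory(curves, observed = observed)
  ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
  invisible(path)
}
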