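#' Plot a normative growth curve
#'
#' Renders the fitted mean curve with the +/- 2 SD band (the range bounding
#' approximately 95% of individuals) and, when present, the 95% bootstrap
#' confidence band for the mean, optionally overlaying the observed points.
#'
#' @param curve A `reference_curve`.
#' @param points Optional data.frame with `age` and `value` to overlay.
#' @return A ggplot object.
#' @export
plot_reference_curve <- function(curve, points = NULL) {
  ages <- curve$sd_profile$ages
  df <- data.frame(
    age = ages,
    mean = eval_curve(curve$model, ages),
    sd = curve$sd_profile$sd
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                   ymax = .data$mean + 2 * .data$sd),
      fill = "steelblue", alpha = 0.15
    )
  if (!is.null(curve$ci)) {
    ci <- data.frame(age = curve$ci$ages, lower = curve$ci$lower,
                     upper = curve$ci$upper)
    p <- p + ggplot2::geom_ribbon(
      data = ci,
      ggplot2::aes(x = .data$age, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.35
    )
  }
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points, ggplot2::aes(x = .data$age, y = .data$value),
      inherit.aes = FALSE, size = 0.4, alpha = 0.4
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.8,
                       color = "steelblue4") +
    ggplot2::labs(
      title = sprintf("%s (%s), %s reference",
                      gsub("_", " ", curve$measurement), curve$sex,
                      "normative"),
      subtitle = sprintf("%s model, n = %d, %d outlier(s) removed",
                         curve$model$family, curve$n_subjects,
                         curve$outliers_removed),
      x = "age (years)", y = "value (mm)"
    ) +
    ggplot2::theme_minimal()
}
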