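#' Plot a diameter trace with its moving-average baseline
#'
#' @param object A `diameter_trace` (ideally after
#'   [moving_average_baseline()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diameter_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$D_um)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "diameter (µm)",
                  title = attr(object, "vessel_id") %||% NULL)
  if (!is.null(object$d_um)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$d_um),
                                colour = "firebrick", linewidth = 0.6)
  }
  p + ggplot2::theme_minimal()
}

#' Scatter and fitted line for a burden-influx regression
#'
#' @param object A `burden_influx_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burden_influx_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$burden, y = .data$influx)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "amyloid burden (%)", y = "influx signal (a.u.)",
      subtitle = sprintf("slope = %.3g, R² = %.3f, p = %.3g",
                         g$slope, g$r_squared, g$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a linearized cortical profile
#'
#' Mean channel intensity against arclength from the dorsal midline, with
#' region boundaries shaded.
#'
#' @param profile Tibble from [linearize_cortex()].
#' @return A ggplot object.
#' @export
plot_linearized_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$arclength_um, y = .data$mean_intensity,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$region), size = 1.5) +
    ggplot2::labs(x = "arclength from dorsal midline (µm)",
                  y = "mean intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot regional signals across a slice cohort
#'
#' @param table Tibble from [regional_table()] or [make_regional_dataset()].
#' @param value Column to plot (default `"mean_signal"`).
#' @return A ggplot object.
#' @export
plot_regional_signals <- function(table, value = "mean_signal") {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$region, y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    (if ("channel" %in% names(table)) ggplot2::facet_wrap(~channel, scales = "free_y")) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
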