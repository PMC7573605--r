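# Figures: scatter-with-regression, Bland-Altman, and four-quadrant
# plots, coloured by study phase.

phase_palette <- c(pre_bleeding = "#3366BB", bleeding = "#CC3333",
                   post_bleeding = "#339955")

#' Scatter of device vs reference with identity and regression lines
#'
#' @param data A paired-observation dataset.
#' @param variable One variable name.
#' @return A ggplot object.
#' @export
plot_scatter_regression <- function(data, variable) {
  data <- validate_dataset(data)
  dv <- data[data$variable == variable, ]
  ggplot2::ggplot(dv, ggplot2::aes(x = .data$reference_value,
                                   y = .data$device_value,
                                   colour = .data$phase)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "black") +
    ggplot2::scale_colour_manual(values = phase_palette) +
    ggplot2::labs(x = paste("Reference", variable),
                  y = paste("Device", variable), colour = "Phase") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot with bias and limits of agreement
#'
#' @inheritParams plot_scatter_regression
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(data, variable) {
  data <- validate_dataset(data)
  dv <- data[data$variable == variable, ]
  ba <- bland_altman(dv$reference_value, dv$device_value)
  dv$mean_value <- (dv$reference_value + dv$device_value) / 2
  dv$difference <- dv$device_value - dv$reference_value
  ggplot2::ggplot(dv, ggplot2::aes(x = .data$mean_value,
                                   y = .data$difference,
                                   colour = .data$phase)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = phase_palette) +
    ggplot2::labs(x = paste("Mean of methods,", variable),
                  y = "Device - reference", colour = "Phase") +
    ggplot2::theme_minimal()
}

#' Four-quadrant plot of successive changes with exclusion square
#'
#' @param changes A tibble of change pairs for one variable
#'   ([dataset_changes()]).
#' @param zone Exclusion half-width (default per [hv_default_zones]).
#' @return A ggplot object.
#' @export
plot_four_quadrant <- function(changes, zone = NULL) {
  v <- unique(changes$variable)
  if (is.null(zone)) zone <- hv_default_zones[[v]]
  ggplot2::ggplot(changes, ggplot2::aes(x = .data$d_ref, y = .data$d_dev)) +
    ggplot2::annotate("rect", xmin = -zone, xmax = zone,
                      ymin = -zone, ymax = zone,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste("Reference change,", v),
                  y = paste("Device change,", v)) +
    ggplot2::theme_minimal()
}
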