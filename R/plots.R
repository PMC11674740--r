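#' Plot reference and sample illumination curves
#'
#' @param p an [ic_params()] object.
#' @param s a scalar [sample_signals()] object.
#' @param half_span_um plotting range about the peak (µm).
#' @return A ggplot object.
#' @export
plot_illumination_curves <- function(p, s = sample_signals(),
                                     half_span_um = 4 * sqrt(p$sigma_r2)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  x <- seq(p$x0 - half_span_um, p$x0 + half_span_um, length.out = 401)
  df <- rbind(
    data.frame(xbar = x, intensity = ic_reference(x, p), curve = "reference"),
    data.frame(xbar = x, intensity = ic_sample(x, p, s), curve = "sample")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xbar, y = .data$intensity,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample-mask displacement (um)", y = "intensity",
                  colour = NULL)
}

#' Plot per-channel sensitivity curves
#'
#' @param sens data.frame from [sensitivity_curves()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sens) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  long <- data.frame(
    xbar = rep(sens$xbar, 3),
    sensitivity = c(sens$attenuation, sens$refraction, sens$scattering),
    channel = rep(c("attenuation", "refraction", "scattering"),
                  each = nrow(sens))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$xbar, y = .data$sensitivity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample-mask displacement (um)",
                  y = "normalized |Ir - Is|", colour = NULL)
}

#' Plot an ROI-averaged profile with standard-deviation error bars
#'
#' @param profile data.frame from [roi_profile()].
#' @param ylab y-axis label.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, ylab = "signal") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$x_um, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (um)", y = ylab)
}
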