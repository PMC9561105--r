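#' Plot a diffusivity trace with its segmentation
#'
#' Effective diffusivity as a function of time for one particle, coloured by
#' the attributed unbound/bound state, with the two-population structure
#' visible as alternating plateaus.
#'
#' @param states A segmented state tibble from [segment_states()] (a plain
#'   [diffusivity_trace()] output also works; states are then omitted).
#' @param particle Which particle id to show (default: the first).
#' @return A ggplot object.
#' @export
plot_diffusivity_trace <- function(states, particle = NULL) {
  particle <- particle %||% states$particle_id[1]
  d <- dplyr::filter(states, .data$particle_id == particle)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$D_um2_s))
  if ("state" %in% names(d)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$state,
                                             group = 1)) +
      ggplot2::scale_colour_manual(values = c(unbound = "#2166ac",
                                              bound = "#e08214"))
  } else {
    p <- p + ggplot2::geom_line(colour = "#2166ac")
  }
  p + ggplot2::labs(x = "time (s)", y = expression(D ~ (mu * m^2 / s)),
                    title = sprintf("Particle %s", particle))
}

#' Histogram of windowed diffusivities across an ensemble
#'
#' The two-population structure (bound mode at low D, unbound mode at high
#' D) of a particle ensemble.
#'
#' @param trace A [diffusivity_trace()] (or segmented) tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_diffusivity_histogram <- function(trace, bins = 60) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$D_um2_s)) +
    ggplot2::geom_histogram(bins = bins, fill = "#2166ac", colour = NA) +
    ggplot2::labs(x = expression(D ~ (mu * m^2 / s)), y = "windows")
}

#' @method autoplot fbpm_survival
#' @export
autoplot.fbpm_survival <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$survival)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "1 - CDF",
                  title = sprintf("%s state lifetimes (n = %d)",
                                  attr(object, "state"), attr(object, "n")))
}

#' @method autoplot fbpm_hill_fit
#' @export
autoplot.fbpm_hill_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(concentration = exp(seq(log(min(d$concentration)),
                                         log(max(d$concentration)),
                                         length.out = 200)))
  grid$value <- predict(object, grid)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration,
                                       y = .data$value)) +
    ggplot2::geom_point()
  if (any(is.finite(d$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se), width = 0)
  }
  p + ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = object$ec50, linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "response",
                  title = sprintf("EC50 = %.3g [%.3g, %.3g]", object$ec50,
                                  object$ec50_ci[1], object$ec50_ci[2]))
}

#' @method autoplot fbpm_monitor
#' @export
autoplot.fbpm_monitor <- function(object, readout = "activity", ...) {
  s <- object$series
  s$y <- s[[readout]]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$t_mid_min)) +
    ggplot2::geom_col(ggplot2::aes(
      y = max(s$y, na.rm = TRUE) * .data$concentration /
        max(.data$concentration, na.rm = TRUE)),
      fill = "grey85", width = 4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y)) +
    ggplot2::labs(x = "time (min)", y = readout,
                  subtitle = "grey bars: applied concentration (scaled)")
}

#' @method autoplot fbpm_dose_response
#' @export
autoplot.fbpm_dose_response <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$concentration > 0),
                  ggplot2::aes(x = .data$concentration, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$readout), scales = "free_y") +
    ggplot2::labs(x = "concentration", y = "readout")
}
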