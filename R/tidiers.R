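#' Tidy methods for fitted objects
#'
#' Broom-style one-row-per-parameter (`tidy`) and one-row-per-fit (`glance`)
#' summaries for exponential lifetime fits, Hill dose-response fits and
#' relaxation fits.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name fbpm-tidiers
NULL

#' @rdname fbpm-tidiers
#' @method tidy fbpm_exp_fit
#' @export
tidy.fbpm_exp_fit <- function(x, ...) {
  if (nrow(x$components) == 1) {
    tibble(term = "tau", estimate = x$tau_s, std.error = x$se_s)
  } else {
    tibble(term = c("tau1", "tau2", "weight1"),
           estimate = c(x$components$tau_s, x$components$weight[1]),
           std.error = NA_real_)
  }
}

#' @rdname fbpm-tidiers
#' @method glance fbpm_exp_fit
#' @export
glance.fbpm_exp_fit <- function(x, ...) {
  tibble(tau_s = x$tau_s, se_s = x$se_s, n_complete = x$n_complete,
         n_censored = x$n_censored, mode = x$mode,
         n_components = nrow(x$components))
}

#' @rdname fbpm-tidiers
#' @method tidy fbpm_hill_fit
#' @export
tidy.fbpm_hill_fit <- function(x, ...) {
  tibble(term = c("y_min", "y_max", "n", "ec50"),
         estimate = c(x$y_min, x$y_max, x$n, x$ec50),
         conf.low = c(NA, NA, NA, x$ec50_ci[1]),
         conf.high = c(NA, NA, NA, x$ec50_ci[2]))
}

#' @rdname fbpm-tidiers
#' @method glance fbpm_hill_fit
#' @export
glance.fbpm_hill_fit <- function(x, ...) {
  tibble(ec50 = x$ec50, ec50_low = x$ec50_ci[1], ec50_high = x$ec50_ci[2],
         hill_n = x$n, deviance = x$deviance, df.residual = x$df_residual,
         increasing = x$increasing)
}

#' @rdname fbpm-tidiers
#' @method tidy fbpm_relax_fit
#' @export
tidy.fbpm_relax_fit <- function(x, ...) {
  tibble(term = c("tau", "y0", "y_inf"),
         estimate = c(x$tau, x$y0, x$y_inf),
         std.error = c(x$se, NA, NA))
}

#' @rdname fbpm-tidiers
#' @method glance fbpm_relax_fit
#' @export
glance.fbpm_relax_fit <- function(x, ...) {
  tibble(tau = x$tau, se = x$se, y0 = x$y0, y_inf = x$y_inf,
         n = length(x$values))
}
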