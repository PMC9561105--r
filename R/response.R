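#' Fit a sigmoidal (Hill) dose-response curve
#'
#' Weighted least-squares fit of
#' \deqn{y = y_{min} + (y_{max} - y_{min}) \frac{x^n}{EC50^n + x^n}}
#' to a dose-response table. Decreasing responses (competition assays) are
#' handled naturally since \eqn{y_{max} < y_{min}} is allowed. EC50 is
#' log-parameterised internally for positivity and numerical robustness
#' across pM-uM ranges; the 95% confidence interval comes from the
#' linearised covariance (t quantile on log-EC50), with a seeded percentile
#' bootstrap as fallback when the covariance is unavailable or on request.
#'
#' @param curve Tibble with columns `concentration`, `value` and optionally
#'   `se` (uncertainties; weights are `1/max(se, floor)^2` with the floor at
#'   the median `se`). Blank rows (`concentration == 0`) are dropped with a
#'   message (they belong to relaxation fits, not to a log-scale Hill fit).
#' @param fix_n Optional fixed Hill coefficient; default leaves `n` free.
#' @param bootstrap If `TRUE`, force the bootstrap CI (1000 resamples).
#' @param boot_seed Seed for the bootstrap resamples.
#' @return An object of class `fbpm_hill_fit`; see [tidy()] and [glance()].
#' @examples
#' x <- c(10, 30, 100, 300, 1000)
#' curve <- tibble::tibble(concentration = x,
#'                         value = 1 + 4 * x / (100 + x), se = 0.05)
#' fit_hill(curve)
#' @export
fit_hill <- function(curve, fix_n = NULL, bootstrap = FALSE, boot_seed = 1L) {
  if (any(curve$concentration < 0)) abort("Concentrations must be >= 0.")
  if (any(curve$concentration == 0)) {
    inform("Dropping blank (concentration = 0) rows from the Hill fit.")
    curve <- dplyr::filter(curve, .data$concentration > 0)
  }
  curve <- dplyr::arrange(curve, .data$concentration)
  if (dplyr::n_distinct(curve$concentration) < 4) {
    abort("Need at least 4 distinct non-zero concentrations.")
  }
  if (!"se" %in% names(curve) || all(is.na(curve$se))) {
    curve$se <- NA_real_
    w <- rep(1, nrow(curve))
  } else {
    floor_se <- median(curve$se, na.rm = TRUE)
    w <- 1 / pmax(curve$se, floor_se, na.rm = TRUE)^2
    w[is.na(w)] <- 1 / floor_se^2
  }
  rng <- diff(range(curve$value))
  med_se <- median(curve$se, na.rm = TRUE)
  if (rng == 0 || (is.finite(med_se) && rng < 2 * med_se)) {
    abort("Dynamic range below 2x the median uncertainty; EC50 is not identifiable.",
          class = "fbpm_unidentifiable")
  }

  x <- curve$concentration
  y <- curve$value
  increasing <- stats::cor(y, log(x)) >= 0
  free_n <- is.null(fix_n)
  model <- function(p, x) {
    n <- if (free_n) exp(p[["log_n"]]) else fix_n
    ec <- exp(p[["log_ec50"]])
    occ <- x^n / (ec^n + x^n)
    p[["y_min"]] + (p[["y_max"]] - p[["y_min"]]) * occ
  }
  starts_ec <- exp(quantile(log(x), c(0.5, 0.25, 0.75)))
  fit <- NULL
  errs <- character(0)
  for (ec0 in starts_ec) {
    p0 <- c(y_min = if (increasing) min(y) else max(y),
            y_max = if (increasing) max(y) else min(y),
            log_ec50 = log(unname(ec0)))
    if (free_n) p0 <- c(p0, log_n = 0)
    f <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) sqrt(w) * (y - model(p, x)),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) conditionMessage(e))
    if (is.character(f)) { errs <- c(errs, f); next }
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
  }
  if (is.null(fit)) {
    abort(paste0("Hill fit failed to converge from ", length(starts_ec),
                 " starts: ", paste(unique(errs), collapse = "; ")),
          class = "fbpm_fit_error")
  }
  p <- coef(fit)
  n_par <- length(p)
  df_res <- length(y) - n_par
  ec50 <- exp(p[["log_ec50"]])
  hill_n <- if (free_n) exp(p[["log_n"]]) else fix_n

  ci <- c(NA_real_, NA_real_)
  se_log_ec <- tryCatch(
    summary(fit)$coefficients["log_ec50", "Std. Error"],
    error = function(e) NA_real_)
  if (!bootstrap && df_res > 0 && is.finite(se_log_ec)) {
    ci <- exp(p[["log_ec50"]] + c(-1, 1) * qt(0.975, df_res) * se_log_ec)
  } else {
    set.seed(boot_seed)
    boots <- replicate(1000, {
      i <- sample.int(length(y), replace = TRUE)
      if (dplyr::n_distinct(x[i]) < 4) return(NA_real_)
      f <- tryCatch(
        minpack.lm::nls.lm(par = p,
                           fn = function(q) sqrt(w[i]) * (y[i] - model(q, x[i])),
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else exp(coef(f)[["log_ec50"]])
    })
    ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  structure(
    list(y_min = unname(p[["y_min"]]), y_max = unname(p[["y_max"]]),
         n = unname(hill_n), ec50 = unname(ec50),
         ec50_ci = unname(ci), se_log_ec50 = se_log_ec,
         residuals = y - model(p, x), df_residual = df_res,
         deviance = fit$deviance, data = curve,
         increasing = increasing),
    class = "fbpm_hill_fit")
}

#' @export
print.fbpm_hill_fit <- function(x, ...) {
  cat(sprintf(
    "<fbpm_hill_fit> EC50 = %.4g [95%% CI %.4g, %.4g], n = %.3g, y_min = %.4g, y_max = %.4g\n",
    x$ec50, x$ec50_ci[1], x$ec50_ci[2], x$n, x$y_min, x$y_max))
  invisible(x)
}

#' Evaluate a fitted Hill curve
#'
#' @param object A `fbpm_hill_fit`.
#' @param newdata Optional tibble with a `concentration` column; default the
#'   fitted concentrations.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.fbpm_hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration else
    newdata$concentration
  occ <- x^object$n / (object$ec50^object$n + x^object$n)
  object$y_min + (object$y_max - object$y_min) * occ
}

#' Fit an exponential relaxation after a concentration step
#'
#' Least-squares fit of \eqn{y(t) = y_\infty + (y_0 - y_\infty)
#' e^{-t/\tau}} to a readout time series after a concentration step-down,
#' giving the sensor relaxation time.
#'
#' @param times Time points (minutes, or any consistent unit).
#' @param values Readout values at `times`.
#' @return An object of class `fbpm_relax_fit` with elements `tau`, `se`,
#'   `y0`, `y_inf`, `residuals`.
#' @export
fit_relaxation <- function(times, values) {
  if (length(times) < 4) abort("Need at least 4 time points.")
  if (diff(range(values)) == 0) {
    abort("Constant readout; relaxation time is not identifiable.",
          class = "fbpm_unidentifiable")
  }
  d <- tibble(t = times - min(times), y = values)
  start <- list(y_inf = values[which.max(times)],
                y0 = values[which.min(times)],
                log_tau = log(max(diff(range(times)) / 3, 1e-6)))
  f <- tryCatch(
    minpack.lm::nlsLM(y ~ y_inf + (y0 - y_inf) * exp(-t / exp(log_tau)),
                      data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("Relaxation fit failed: ",
                                     conditionMessage(e)),
                              class = "fbpm_fit_error"))
  p <- coef(f)
  tau <- exp(p[["log_tau"]])
  se <- tryCatch(tau * sqrt(vcov(f)["log_tau", "log_tau"]),
                 error = function(e) NA_real_)
  res <- resid(f)
  if (1 - sum(res^2) / sum((values - mean(values))^2) < 0.5) {
    warn(paste0("Relaxation fit explains less than half the variance; ",
                "data may be non-monotone beyond noise. Residual SD: ",
                signif(sd(res), 3)))
  }
  structure(list(tau = tau, se = se, y0 = unname(p[["y0"]]),
                 y_inf = unname(p[["y_inf"]]), residuals = unname(res),
                 times = times, values = values),
            class = "fbpm_relax_fit")
}

#' @export
print.fbpm_relax_fit <- function(x, ...) {
  cat(sprintf("<fbpm_relax_fit> tau = %.3g +/- %.2g, y0 = %.3g -> y_inf = %.3g\n",
              x$tau, x$se, x$y0, x$y_inf))
  invisible(x)
}

#' Analyse a trajectory table into states, kinetics and readouts
#'
#' The standard per-block analysis chain: windowed diffusivity, hysteresis
#' segmentation, quality-control exclusion, dwell-time extraction and
#' exponential lifetime fits, switching activity and bound fraction.
#'
#' @param trajectories Trajectory tibble (`particle_id, frame, t_s, x_um,
#'   y_um[, valid]`).
#' @param seg A [segmentation_config()]; default the 2.8 um cutoff
#'   (0.05 um^2/s).
#' @param window,lags Passed to [diffusivity_trace()].
#' @param qc Apply [qc_filter()] before computing readouts.
#' @param lifetime_mode Censoring mode for [fit_exponential()].
#' @return A list of class `fbpm_analysis`: `states`, `lifetimes`,
#'   `activity`, `bound_fraction`, `fits` (list with `unbound`, `bound`,
#'   possibly `NULL` when too few dwells), `qc` (report or `NULL`).
#' @export
analyze_trajectories <- function(trajectories, seg = segmentation_config(),
                                 window = 30, lags = 5, qc = TRUE,
                                 lifetime_mode = "censored") {
  trace <- diffusivity_trace(trajectories, window = window, lags = lags)
  states <- segment_states(trace, seg)
  qc_rep <- NULL
  if (qc) {
    q <- qc_filter(trajectories, states)
    states <- q$states
    qc_rep <- q$report
  }
  lifetimes <- extract_lifetimes(states)
  fits <- purrr::map(c(unbound = "unbound", bound = "bound"), function(s) {
    lt <- dplyr::filter(lifetimes, .data$state == s)
    tryCatch(fit_exponential(lt, mode = lifetime_mode),
             error = function(e) NULL)
  })
  structure(list(states = states, lifetimes = lifetimes,
                 activity = switching_activity(states),
                 bound_fraction = bound_fraction(states),
                 fits = fits, qc = qc_rep),
            class = "fbpm_analysis")
}

#' @export
print.fbpm_analysis <- function(x, ...) {
  cat(sprintf(
    "<fbpm_analysis> %d particles: activity %.3g/min (SEM %.2g), bound fraction %.3g\n",
    x$activity$n_particles, x$activity$activity_per_min, x$activity$sem,
    x$bound_fraction$bound_fraction))
  for (s in c("unbound", "bound")) {
    f <- x$fits[[s]]
    if (!is.null(f)) cat(sprintf("  %s tau = %.3g +/- %.2g s\n", s, f$tau_s,
                                 f$se_s))
  }
  invisible(x)
}

#' Assemble dose-response curves from per-concentration analyses
#'
#' Collects the four readouts (switching activity, bound fraction, unbound
#' and bound characteristic lifetimes) across concentrations into one tidy
#' table. Duplicate concentration labels are merged by inverse-variance
#' pooling, with a message.
#'
#' @param analyses List of [analyze_trajectories()] results.
#' @param concentrations Concentration per analysis (same length/order).
#' @return A tibble `readout, concentration, value, se` of class
#'   `fbpm_dose_response`.
#' @export
build_dose_response <- function(analyses, concentrations) {
  if (length(analyses) != length(concentrations)) {
    abort("`analyses` and `concentrations` must have the same length.")
  }
  if (length(analyses) < 2) abort("Need at least 2 concentrations.")
  rows <- purrr::map2(analyses, concentrations, function(a, conc) {
    tf <- function(f) {
      if (is.null(f)) c(NA_real_, NA_real_) else c(f$tau_s, f$se_s)
    }
    ub <- tf(a$fits$unbound); bd <- tf(a$fits$bound)
    tibble(readout = c("activity", "bound_fraction", "tau_unbound",
                       "tau_bound"),
           concentration = conc,
           value = c(a$activity$activity_per_min,
                     a$bound_fraction$bound_fraction, ub[1], bd[1]),
           se = c(a$activity$sem, a$bound_fraction$sem, ub[2], bd[2]))
  }) |> purrr::list_rbind()
  dup <- dplyr::count(rows, .data$readout, .data$concentration) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    inform(sprintf("Merging %d duplicated concentration label(s) by inverse-variance pooling.",
                   dplyr::n_distinct(dup$concentration)))
    rows <- rows |>
      dplyr::group_by(.data$readout, .data$concentration) |>
      dplyr::summarise(value = if (all(is.finite(.data$se)) &&
                                   all(.data$se > 0)) {
        sum(.data$value / .data$se^2) / sum(1 / .data$se^2)
      } else mean(.data$value),
      se = if (all(is.finite(.data$se)) && all(.data$se > 0)) {
        sqrt(1 / sum(1 / .data$se^2))
      } else sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop")
  }
  out <- dplyr::arrange(rows, .data$readout, .data$concentration)
  structure(out, class = c("fbpm_dose_response", class(out)))
}

#' Run the continuous-monitoring workflow over recording blocks
#'
#' Analyses each block independently (QC, diffusivity, segmentation,
#' readouts) and assembles the block-level monitoring series: the sensor
#' response as a function of time while the applied concentration changes.
#' Particle ids need not persist across blocks. A block whose particles are
#' all excluded is flagged missing and the pipeline continues.
#'
#' @param trajectories Trajectory tibble with an additional `block` column.
#' @param block_info Tibble `block, t_mid_min, concentration` describing each
#'   block's midpoint time (minutes) and applied concentration.
#' @param ... Passed to [analyze_trajectories()].
#' @return A list of class `fbpm_monitor`: `series` (one row per block:
#'   time, concentration, activity, bound fraction, lifetimes, n_particles)
#'   and `analyses` (per-block [analyze_trajectories()] results).
#' @export
run_monitoring <- function(trajectories, block_info, ...) {
  need <- c("block", "t_mid_min", "concentration")
  if (!all(need %in% names(block_info))) {
    abort("`block_info` needs columns block, t_mid_min, concentration.")
  }
  block_info <- dplyr::arrange(block_info, .data$t_mid_min)
  analyses <- purrr::map(block_info$block, function(b) {
    tr <- dplyr::filter(trajectories, .data$block == b)
    if (nrow(tr) == 0) return(NULL)
    tryCatch(analyze_trajectories(dplyr::select(tr, -"block"), ...),
             error = function(e) {
               warn(sprintf("Block %s failed (%s); flagged missing.", b,
                            conditionMessage(e)))
               NULL
             })
  })
  series <- purrr::map2(analyses, seq_len(nrow(block_info)), function(a, i) {
    base <- block_info[i, ]
    if (is.null(a)) {
      return(dplyr::mutate(base, activity = NA_real_, activity_sem = NA_real_,
                           bound_fraction = NA_real_, bf_sem = NA_real_,
                           tau_unbound_s = NA_real_, tau_bound_s = NA_real_,
                           n_particles = 0L, missing = TRUE))
    }
    dplyr::mutate(base,
                  activity = a$activity$activity_per_min,
                  activity_sem = a$activity$sem,
                  bound_fraction = a$bound_fraction$bound_fraction,
                  bf_sem = a$bound_fraction$sem,
                  tau_unbound_s = a$fits$unbound$tau_s %||% NA_real_,
                  tau_bound_s = a$fits$bound$tau_s %||% NA_real_,
                  n_particles = a$activity$n_particles, missing = FALSE)
  }) |> purrr::list_rbind()
  structure(list(series = series, analyses = analyses),
            class = "fbpm_monitor")
}

#' @export
print.fbpm_monitor <- function(x, ...) {
  cat(sprintf("<fbpm_monitor> %d blocks, %d missing\n", nrow(x$series),
              sum(x$series$missing)))
  print(x$series)
  invisible(x)
}

#' Export an analysis as a structured JSON report
#'
#' @param analysis A [analyze_trajectories()] result.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` (or the JSON string) invisibly.
#' @export
write_analysis_report <- function(analysis, path = NULL) {
  fits <- purrr::map(analysis$fits, function(f) {
    if (is.null(f)) return(NULL)
    list(tau_s = f$tau_s, se_s = f$se_s, n_complete = f$n_complete,
         n_censored = f$n_censored, mode = f$mode)
  })
  rep <- list(activity = as.list(analysis$activity),
              bound_fraction = as.list(analysis$bound_fraction),
              lifetime_fits = fits, qc = analysis$qc)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
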