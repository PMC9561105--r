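#' Extract state dwell times with censoring flags
#'
#' Converts per-frame state traces into dwell times. A dwell that abuts the
#' start or end of an observation window is right-censored: its observed
#' duration is only a lower bound. Contiguous recording blocks (no time gap)
#' form a single observation window, so dwells running across an internal
#' block boundary are not split; blocks separated by a gap censor at their
#' edges.
#'
#' @param states A per-frame state tibble (`particle_id, frame, t_s, state`),
#'   e.g. from [segment_states()] or [as_binary_states()].
#' @param block_starts_s Optional numeric vector of block start times (s),
#'   used only when `split_contiguous = TRUE`.
#' @param split_contiguous If `TRUE`, censor at every block boundary in
#'   `block_starts_s` even when the recording continues without a gap
#'   (strict per-block mode); the default treats a contiguous recording as
#'   one window, which keeps the censored MLE invariant under block
#'   subdivision.
#' @return A tibble `particle_id, state, duration_s, censored`.
#' @examples
#' st <- tibble::tibble(particle_id = 1L, frame = 1:18000,
#'                      t_s = (1:18000) / 60,
#'                      state = rep(c("unbound", "bound", "unbound"),
#'                                  c(600, 600, 16800)))
#' extract_lifetimes(st)
#' @export
extract_lifetimes <- function(states, block_starts_s = NULL,
                              split_contiguous = FALSE) {
  dt <- median(diff(states$t_s[states$particle_id ==
                                 states$particle_id[1]]))
  states |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::arrange(g, .data$frame)
      # observation windows: maximal contiguous runs, optionally also split
      # at stated block starts
      win <- cumsum(c(1L, diff(g$t_s) > 1.5 * dt))
      if (split_contiguous && !is.null(block_starts_s)) {
        blk <- findInterval(g$t_s, sort(block_starts_s) + dt / 4)
        win <- cumsum(c(1L, diff(win) != 0 | diff(blk) != 0))
      }
      purrr::map_dfr(split(g, win), function(w) {
        r <- rle(w$state)
        k <- length(r$lengths)
        tibble(particle_id = key$particle_id, state = r$values,
               duration_s = r$lengths * dt,
               censored = seq_len(k) %in% c(1L, k))
      })
    }) |>
    purrr::list_rbind()
}

#' Collapse ground-truth states to unbound/bound
#'
#' Maps the simulator's four-level ground truth (`unbound`,
#' `bound_specific`, `bound_nonspecific`, `bound_multivalent`) onto the
#' binary segmentation alphabet so the same kinetics functions apply.
#'
#' @param truth Ground-truth tibble from [simulate_fov()].
#' @param dt_s Frame period used to reconstruct `t_s` if absent.
#' @return A tibble `particle_id, frame, t_s, state`.
#' @export
as_binary_states <- function(truth, dt_s = NULL) {
  if (!"t_s" %in% names(truth)) {
    if (is.null(dt_s)) abort("Provide `dt_s` when `truth` lacks `t_s`.")
    truth$t_s <- truth$frame * dt_s
  }
  dplyr::transmute(truth, .data$particle_id, .data$frame, .data$t_s,
                   state = ifelse(.data$true_state == "unbound",
                                  "unbound", "bound"))
}

#' Empirical survival curve of dwell times
#'
#' \eqn{S(t) = 1 - \mathrm{CDF}(t)} over the complete (uncensored) dwells of
#' one state. The number of censored dwells set aside is recorded in the
#' `n_censored` attribute.
#'
#' @param lifetimes Tibble from [extract_lifetimes()]; must contain exactly
#'   one state or be filtered/specified with `state`.
#' @param state Which state to plot when `lifetimes` holds both.
#' @return A tibble of class `fbpm_survival` with `time_s` and `survival`,
#'   starting at `S(0) = 1`.
#' @export
survival_curve <- function(lifetimes, state = NULL) {
  if (!is.null(state)) {
    lifetimes <- dplyr::filter(lifetimes, .data$state == !!state)
  }
  if (dplyr::n_distinct(lifetimes$state) > 1) {
    abort("`lifetimes` holds several states; pick one with `state = `.")
  }
  d <- sort(lifetimes$duration_s[!lifetimes$censored])
  if (length(d) == 0) abort("No complete dwells to build a survival curve.")
  tt <- unique(d)
  out <- tibble(time_s = c(0, tt),
                survival = c(1, vapply(tt, function(t) mean(d > t),
                                       numeric(1))))
  structure(out, class = c("fbpm_survival", class(out)),
            n = length(d), n_censored = sum(lifetimes$censored),
            state = unique(lifetimes$state))
}

#' Exponential lifetime fit with right-censoring
#'
#' Maximum-likelihood characteristic lifetime of an exponential dwell-time
#' distribution. In `"censored"` mode (default) censored dwells contribute
#' exposure but no event:
#' \eqn{\hat\tau = \sum_i t_i / n_{complete}} over all observed durations;
#' standard error \eqn{\hat\tau / \sqrt{n_{complete}}}. In `"naive"` mode
#' censored dwells are treated as complete, reproducing the saturation of
#' fitted lifetimes at the observation-window scale when the true lifetime
#' exceeds the recording length.
#'
#' @param lifetimes Tibble with `duration_s` and `censored` (one state).
#' @param state Optional state filter as in [survival_curve()].
#' @param mode `"censored"` or `"naive"`.
#' @param t_max Optional fit window: dwells longer than `t_max` are truncated
#'   to `t_max` and treated as censored (initial-segment fitting).
#' @param min_complete Minimum number of complete dwells required.
#' @return An object of class `fbpm_exp_fit`; see [tidy()] and [glance()].
#' @export
fit_exponential <- function(lifetimes, state = NULL,
                            mode = c("censored", "naive"),
                            t_max = NULL, min_complete = 10) {
  mode <- match.arg(mode)
  if (!is.null(state)) {
    lifetimes <- dplyr::filter(lifetimes, .data$state == !!state)
  }
  if (dplyr::n_distinct(lifetimes$state) > 1) {
    abort("`lifetimes` holds several states; pick one with `state = `.")
  }
  dur <- lifetimes$duration_s
  cen <- lifetimes$censored
  if (!is.null(t_max)) {
    cen <- cen | dur > t_max
    dur <- pmin(dur, t_max)
  }
  if (mode == "naive") cen <- rep(FALSE, length(cen))
  n_complete <- sum(!cen)
  if (n_complete == 0) {
    abort("All dwells are censored; no exponential rate is identifiable.",
          class = "fbpm_all_censored")
  }
  if (n_complete < min_complete) {
    abort(sprintf("Only %d complete dwells (< %d required).", n_complete,
                  min_complete))
  }
  tau <- sum(dur) / n_complete
  structure(list(tau_s = tau, se_s = tau / sqrt(n_complete),
                 n_complete = n_complete, n_censored = sum(cen),
                 mode = mode, t_max = t_max,
                 state = unique(lifetimes$state) %||% NA_character_,
                 components = tibble(tau_s = tau, weight = 1)),
            class = "fbpm_exp_fit")
}

#' Bi-exponential dwell-time mixture fit
#'
#' Two-component exponential mixture fitted by expectation-maximisation on
#' the complete dwells, for dwell sets containing both short-lived
#' (monovalent) and long-lived (multivalent) bound states. Components are
#' ordered \eqn{\tau_1 < \tau_2}. Non-identifiable fits
#' (\eqn{\tau_2/\tau_1 < 2} or a weight pinned to 0/1) fall back to the
#' single-exponential fit with a warning.
#'
#' @inheritParams fit_exponential
#' @param min_complete Minimum number of complete dwells (default 50).
#' @param max_iter,tol EM iteration controls.
#' @return An object of class `fbpm_exp_fit` whose `components` tibble has
#'   two rows (`tau_s`, `weight`).
#' @export
fit_biexponential <- function(lifetimes, state = NULL, min_complete = 50,
                              max_iter = 500, tol = 1e-10) {
  if (!is.null(state)) {
    lifetimes <- dplyr::filter(lifetimes, .data$state == !!state)
  }
  d <- lifetimes$duration_s[!lifetimes$censored]
  if (length(d) < min_complete) {
    abort(sprintf("Only %d complete dwells (< %d required).", length(d),
                  min_complete))
  }
  m <- mean(d)
  tau1 <- m / 2; tau2 <- m * 2; w <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    f1 <- w * stats::dexp(d, 1 / tau1)
    f2 <- (1 - w) * stats::dexp(d, 1 / tau2)
    g <- f1 / (f1 + f2)
    w <- mean(g)
    tau1 <- sum(g * d) / sum(g)
    tau2 <- sum((1 - g) * d) / sum(1 - g)
    ll <- sum(log(f1 + f2))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (tau1 > tau2) {
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp; w <- 1 - w
  }
  if (tau2 / tau1 < 2 || w < 0.02 || w > 0.98) {
    warn("Bi-exponential fit is degenerate; falling back to a single exponential.")
    return(fit_exponential(lifetimes, min_complete = 1))
  }
  tau <- w * tau1 + (1 - w) * tau2
  structure(list(tau_s = tau, se_s = NA_real_,
                 n_complete = length(d),
                 n_censored = sum(lifetimes$censored),
                 mode = "mixture", t_max = NULL,
                 state = unique(lifetimes$state) %||% NA_character_,
                 components = tibble(tau_s = c(tau1, tau2),
                                     weight = c(w, 1 - w))),
            class = "fbpm_exp_fit")
}

#' @export
print.fbpm_exp_fit <- function(x, ...) {
  if (nrow(x$components) == 1) {
    cat(sprintf("<fbpm_exp_fit> tau = %.3g +/- %.2g s (%s, %d complete / %d censored dwells)\n",
                x$tau_s, x$se_s, x$mode, x$n_complete, x$n_censored))
  } else {
    cat(sprintf("<fbpm_exp_fit> mixture: tau1 = %.3g s (w = %.2f), tau2 = %.3g s (%d complete dwells)\n",
                x$components$tau_s[1], x$components$weight[1],
                x$components$tau_s[2], x$n_complete))
  }
  invisible(x)
}

#' Switching activity of a particle ensemble
#'
#' The average number of binding plus unbinding events per particle per unit
#' time, the primary digital readout of the sensor. Both transition
#' directions count as events; the rate is reported per minute with the
#' standard error of the mean across particles.
#'
#' @param states Per-frame state tibble (`particle_id, t_s, state`).
#' @return A one-row tibble: `activity_per_min, sem, n_particles, n_events,
#'   minutes_per_particle`.
#' @export
switching_activity <- function(states) {
  per <- states |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::summarise(
      n_events = sum(.data$state != dplyr::lag(
        .data$state, default = dplyr::first(.data$state))),
      minutes = (max(.data$t_s) - min(.data$t_s) +
                   median(diff(.data$t_s))) / 60,
      .groups = "drop")
  if (any(per$minutes <= 0)) abort("Zero-duration recording block.")
  rates <- per$n_events / per$minutes
  tibble(activity_per_min = mean(rates),
         sem = sd(rates) / sqrt(nrow(per)),
         n_particles = nrow(per), n_events = sum(per$n_events),
         minutes_per_particle = mean(per$minutes))
}

#' Bound fraction of a particle ensemble
#'
#' Per-particle fraction of analysed frames spent in the bound state,
#' averaged over particles, with the SEM across particles.
#'
#' @inheritParams switching_activity
#' @return A one-row tibble: `bound_fraction, sem, n_particles`.
#' @export
bound_fraction <- function(states) {
  per <- states |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::summarise(frac = mean(.data$state == "bound"), .groups = "drop")
  tibble(bound_fraction = mean(per$frac),
         sem = sd(per$frac) / sqrt(nrow(per)),
         n_particles = nrow(per))
}

#' Read and write lifetime tables
#'
#' CSV schema: `state,duration_s,censored`.
#'
#' @param lifetimes Tibble from [extract_lifetimes()].
#' @param path File path.
#' @export
write_lifetimes <- function(lifetimes, path) {
  readr::write_csv(lifetimes[c("state", "duration_s", "censored")], path)
  invisible(path)
}

#' @rdname write_lifetimes
#' @export
read_lifetimes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(state = readr::col_character(),
                                          duration_s = readr::col_double(),
                                          censored = readr::col_logical()))
}
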