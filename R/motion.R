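#' Mean squared displacement of a trajectory
#'
#' 2D MSD over lags 1..`max_lag` using all overlapping frame pairs. Frames
#' flagged invalid (or absent) contribute to no pair.
#'
#' @param traj A single-particle trajectory tibble with columns
#'   `frame, t_s, x_um, y_um` (and optionally `valid`).
#' @param max_lag Largest lag in frames; must be below the trajectory length.
#' @return A tibble with columns `lag` (frames), `tau_s` (lag time) and
#'   `msd_um2`.
#' @examples
#' tr <- tibble::tibble(frame = 1:100, t_s = (1:100) / 60,
#'                      x_um = 0.1 * (1:100), y_um = 0)
#' msd(tr, max_lag = 4)  # ballistic: msd = (0.1 * lag)^2
#' @export
msd <- function(traj, max_lag) {
  if (dplyr::n_distinct(traj$particle_id %||% 1L) > 1) {
    abort("`msd()` expects a single particle; group or split first.")
  }
  traj <- dplyr::arrange(traj, .data$frame)
  if ("valid" %in% names(traj)) traj <- dplyr::filter(traj, .data$valid)
  n_frames <- max(traj$frame) - min(traj$frame) + 1L
  if (max_lag >= n_frames) {
    abort("`max_lag` must be smaller than the trajectory length.")
  }
  # index by frame so gaps drop out of the pair sums
  idx <- traj$frame - min(traj$frame) + 1L
  x <- rep(NA_real_, n_frames); y <- rep(NA_real_, n_frames)
  x[idx] <- traj$x_um; y[idx] <- traj$y_um
  dt <- median(diff(traj$t_s) / diff(traj$frame))
  purrr::map_dfr(seq_len(max_lag), function(v) {
    dx <- x[(1 + v):n_frames] - x[1:(n_frames - v)]
    dy <- y[(1 + v):n_frames] - y[1:(n_frames - v)]
    tibble(lag = v, tau_s = v * dt,
           msd_um2 = mean(dx^2 + dy^2, na.rm = TRUE))
  })
}

#' Windowed effective-diffusivity trace
#'
#' For every sliding window of `window` frames, the 2D MSD over lags
#' 1..`lags` is fitted through the origin by least squares and the slope / 4
#' reported as the effective diffusivity at the window centre. Small negative
#' slopes (static localization error) are clipped to zero; the number of
#' clipped windows is recorded in the `n_clipped` attribute.
#'
#' @param trajectories Trajectory tibble (`particle_id, frame, t_s, x_um,
#'   y_um[, valid]`), one or many particles.
#' @param window Window length W in frames (default 30, i.e. 0.5 s at 60 Hz).
#' @param lags Number of MSD lags L fitted (default 5); requires
#'   `window > lags >= 1`.
#' @return A tibble `particle_id, frame, t_s, D_um2_s` with one row per
#'   window centre (trace length = trajectory length - W + 1 per particle).
#'   Particles shorter than `window` yield no rows, with a warning.
#' @export
diffusivity_trace <- function(trajectories, window = 30, lags = 5) {
  if (!(window > lags && lags >= 1)) {
    abort("Need `window` > `lags` >= 1.")
  }
  clipped <- 0L
  out <- trajectories |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_map(function(tr, key) {
      tr <- dplyr::arrange(tr, .data$frame)
      n <- nrow(tr)
      if (n < window) {
        warn(sprintf("Particle %s: trajectory (%d frames) shorter than window (%d); empty trace.",
                     key$particle_id, n, window))
        return(NULL)
      }
      x <- tr$x_um; y <- tr$y_um
      if ("valid" %in% names(tr) && !all(tr$valid)) {
        # bridge flagged frames by linear interpolation so windows stay contiguous
        ok <- tr$valid & is.finite(x) & is.finite(y)
        x <- approx(tr$frame[ok], x[ok], xout = tr$frame, rule = 2)$y
        y <- approx(tr$frame[ok], y[ok], xout = tr$frame, rule = 2)$y
      }
      dt <- median(diff(tr$t_s) / diff(tr$frame))
      res <- windowed_diffusivity_cpp(x, y, window, lags, dt)
      clipped <<- clipped + res$n_clipped
      centre <- seq_len(n - window + 1L) + window %/% 2L
      tibble(particle_id = key$particle_id,
             frame = tr$frame[centre], t_s = tr$t_s[centre],
             D_um2_s = res$D)
    }) |>
    purrr::list_rbind()
  attr(out, "n_clipped") <- clipped
  attr(out, "window") <- window
  attr(out, "lags") <- lags
  out
}

#' Two-state segmentation configuration
#'
#' Hysteresis thresholds around the diffusivity cutoff that separates free
#' from confined motion (0.15 um^2/s for 1 um particles, 0.05 um^2/s for
#' 2.8 um particles): a particle enters the bound state when its windowed D
#' drops below `D_lo` and leaves it when D rises above `D_hi`. Dwells shorter
#' than `min_dwell_frames` are merged into the surrounding state (debounce).
#'
#' @param cutoff Diffusivity cutoff in um^2/s.
#' @param D_lo,D_hi Hysteresis thresholds; defaults `0.6 * cutoff` and
#'   `cutoff`.
#' @param min_dwell_frames Minimum dwell in frames (default 3 window lengths
#'   at the default 30-frame window, i.e. 1.5 s at 60 Hz).
#' @return An object of class `fbpm_seg_config`.
#' @examples
#' segmentation_config(cutoff = 0.05)  # 2.8 um particles
#' @export
segmentation_config <- function(cutoff = 0.05, D_lo = 0.6 * cutoff,
                                D_hi = cutoff, min_dwell_frames = 90) {
  if (!(D_lo < D_hi)) abort("Need `D_lo` < `D_hi`.")
  if (min_dwell_frames < 1) abort("`min_dwell_frames` must be >= 1.")
  structure(list(D_lo = D_lo, D_hi = D_hi,
                 min_dwell_frames = min_dwell_frames),
            class = "fbpm_seg_config")
}

# Hysteresis + debounce on one diffusivity vector -> character state vector.
.segment_one <- function(D, cfg) {
  s <- rep(NA_character_, length(D))
  s[D < cfg$D_lo] <- "bound"
  s[D > cfg$D_hi] <- "unbound"
  # forward-fill undecided samples (hysteresis), back-fill the leading run
  filled <- s
  last <- NA_character_
  for (i in seq_along(filled)) {
    if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
  }
  first_set <- which(!is.na(filled))[1]
  if (is.na(first_set)) return(rep("unbound", length(D)))
  if (first_set > 1) filled[seq_len(first_set - 1)] <- filled[first_set]
  # debounce: repeatedly merge sub-minimum dwells into the preceding state
  repeat {
    r <- rle(filled)
    if (length(r$lengths) == 1) break
    short <- which(r$lengths < cfg$min_dwell_frames)
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    filled <- inverse.rle(r)
  }
  filled
}

#' Segment a diffusivity trace into unbound and bound states
#'
#' Hysteresis rule on the windowed diffusivity: enter bound when
#' `D < D_lo`, exit when `D > D_hi`; values between the thresholds keep the
#' current state. Dwells shorter than the minimum dwell are merged into the
#' surrounding state.
#'
#' @param trace Output of [diffusivity_trace()].
#' @param cfg A [segmentation_config()].
#' @return The trace tibble with an added `state` column
#'   (`"unbound"`/`"bound"`).
#' @seealso [state_transitions()] for the transition list.
#' @export
segment_states <- function(trace, cfg) {
  stopifnot(inherits(cfg, "fbpm_seg_config"))
  trace |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(state = .segment_one(.data$D_um2_s, cfg)) |>
    dplyr::ungroup()
}

#' Transition list of a segmented state trace
#'
#' @param states Output of [segment_states()] (or any tibble with
#'   `particle_id, frame, t_s, state`).
#' @return A tibble `particle_id, direction, frame, t_s` with one row per
#'   state change; `direction` is `"bind"` (unbound to bound) or `"unbind"`.
#'   Transition times are reported at the first sample of the new state.
#' @export
state_transitions <- function(states) {
  states |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::filter(.data$state != dplyr::lag(.data$state)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$particle_id,
                     direction = ifelse(.data$state == "bound", "bind",
                                        "unbind"),
                     .data$frame, .data$t_s)
}

#' Quality-control particle exclusion
#'
#' Applies the three exclusion rules used before computing ensemble readouts:
#' (i) stuck particles, mean diffusivity below `stuck_D` um^2/s;
#' (ii) hyperactive particles, switching activity above the ensemble mean
#' plus `hyper_k` standard deviations; (iii) colliding particle pairs whose
#' positions coincide within `collision_dist_um` for longer than
#' `collision_min_s`. A warning is emitted when 10 percent or more of the
#' particles are excluded.
#'
#' @param trajectories Trajectory tibble (for the collision rule).
#' @param states Segmented state tibble from [segment_states()].
#' @param stuck_D Stuck threshold on the mean windowed D (um^2/s).
#' @param hyper_k Multiplier on the activity standard deviation.
#' @param collision_dist_um Distance tolerance for "(partially) identical"
#'   trajectories (default two pixel-equivalents at 0.345 um/px).
#' @param collision_min_s Minimum coincidence run length (s).
#' @return A list of class `fbpm_qc` with elements `states` and
#'   `trajectories` (filtered), `exclusions` (tibble `particle_id, rule`) and
#'   `report` (per-rule counts and excluded fraction).
#' @export
qc_filter <- function(trajectories, states, stuck_D = 0.01, hyper_k = 4,
                      collision_dist_um = 0.69, collision_min_s = 1) {
  per_part <- states |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::summarise(mean_D = mean(.data$D_um2_s),
                     n_events = sum(.data$state != dplyr::lag(
                       .data$state, default = dplyr::first(.data$state))),
                     span_s = max(.data$t_s) - min(.data$t_s) +
                       median(diff(.data$t_s)),
                     .groups = "drop") |>
    dplyr::mutate(activity = .data$n_events / .data$span_s)

  stuck <- per_part$particle_id[per_part$mean_D < stuck_D]
  act_lim <- mean(per_part$activity) + hyper_k * sd(per_part$activity)
  hyper <- if (is.finite(act_lim)) {
    per_part$particle_id[per_part$activity > act_lim]
  } else integer(0)
  colliding <- .find_colliding(trajectories, collision_dist_um,
                               collision_min_s)

  exclusions <- dplyr::bind_rows(
    tibble(particle_id = stuck, rule = "stuck"),
    tibble(particle_id = hyper, rule = "hyperactive"),
    tibble(particle_id = colliding, rule = "colliding"))
  drop_ids <- unique(exclusions$particle_id)
  all_ids <- unique(states$particle_id)
  frac <- length(drop_ids) / length(all_ids)
  if (length(drop_ids) == length(all_ids)) {
    abort("All particles excluded by quality control.", class = "fbpm_qc_empty")
  }
  if (frac >= 0.1) {
    warn(sprintf("QC excluded %.1f%% of particles (>= 10%%).", 100 * frac))
  }
  structure(
    list(states = dplyr::filter(states, !.data$particle_id %in% drop_ids),
         trajectories = dplyr::filter(trajectories,
                                      !.data$particle_id %in% drop_ids),
         exclusions = exclusions,
         report = list(n_total = length(all_ids),
                       n_stuck = length(stuck), n_hyperactive = length(hyper),
                       n_colliding = length(colliding),
                       n_excluded = length(drop_ids), fraction = frac)),
    class = "fbpm_qc")
}

#' @export
print.fbpm_qc <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<fbpm_qc> %d/%d particles excluded (%.1f%%): %d stuck, %d hyperactive, %d colliding\n",
    r$n_excluded, r$n_total, 100 * r$fraction, r$n_stuck, r$n_hyperactive,
    r$n_colliding))
  invisible(x)
}

# Pairs of particles whose positions coincide within `dist` um for more than
# `min_s` seconds. Bounding-box prefilter keeps the pairwise scan cheap.
.find_colliding <- function(trajectories, dist, min_s) {
  bb <- trajectories |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::summarise(xmin = min(.data$x_um), xmax = max(.data$x_um),
                     ymin = min(.data$y_um), ymax = max(.data$y_um),
                     .groups = "drop")
  ids <- bb$particle_id
  if (length(ids) < 2) return(integer(0))
  dt <- trajectories |>
    dplyr::filter(.data$particle_id == ids[1]) |>
    dplyr::pull("t_s") |> diff() |> median()
  min_run <- max(1L, ceiling(min_s / dt))
  by_id <- split(trajectories[c("frame", "x_um", "y_um")],
                 trajectories$particle_id)
  hits <- integer(0)
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq((i + 1), length(ids))) {
      if (bb$xmin[j] > bb$xmax[i] + dist || bb$xmax[j] < bb$xmin[i] - dist ||
          bb$ymin[j] > bb$ymax[i] + dist || bb$ymax[j] < bb$ymin[i] - dist) {
        next
      }
      a <- by_id[[as.character(ids[i])]]
      b <- by_id[[as.character(ids[j])]]
      m <- dplyr::inner_join(a, b, by = "frame", suffix = c("", ".b"))
      if (nrow(m) == 0) next
      close <- sqrt((m$x_um - m$x_um.b)^2 + (m$y_um - m$y_um.b)^2) < dist
      r <- rle(close)
      if (any(r$values & r$lengths >= min_run)) {
        hits <- c(hits, ids[i], ids[j])
      }
    }
  }
  unique(hits)
}
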