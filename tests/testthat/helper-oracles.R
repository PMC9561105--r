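# Independent oracle helpers built from base R only (no package internals).

# Free 2D Brownian random walk at constant diffusivity D (um^2/s).
brownian_walk <- function(n_frames, D, dt = 1 / 60, sigma_loc = 0,
                          particle_id = 1L) {
  step_sd <- sqrt(2 * D * dt)
  x <- cumsum(rnorm(n_frames, 0, step_sd))
  y <- cumsum(rnorm(n_frames, 0, step_sd))
  tibble::tibble(particle_id = particle_id, frame = seq_len(n_frames),
                 t_s = seq_len(n_frames) * dt,
                 x_um = x + rnorm(n_frames, 0, sigma_loc),
                 y_um = y + rnorm(n_frames, 0, sigma_loc),
                 valid = TRUE)
}

# Origin-constrained MSD slope oracle: brute-force over all overlapping pairs.
msd_slope_oracle <- function(x, y, lags, dt) {
  msd <- vapply(lags, function(v) {
    n <- length(x)
    mean((x[(1 + v):n] - x[1:(n - v)])^2 + (y[(1 + v):n] - y[1:(n - v)])^2)
  }, numeric(1))
  tau <- lags * dt
  sum(tau * msd) / sum(tau^2)
}

# Noiseless Gaussian spot ROI centred at (dx, dy) pixels from the ROI centre.
gaussian_roi <- function(dx, dy, sigma = 1.2, n = 7, amplitude = 1,
                         background = 0) {
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(r, co) {
    background + amplitude *
      exp(-((co - c0 - dx)^2 + (r - c0 - dy)^2) / (2 * sigma^2))
  })
}

# Least-squares Gaussian-fit localization oracle on one ROI.
gaussian_fit_oracle <- function(roi, sigma0 = 1.2) {
  obj <- function(p) {
    sum((roi - p[4] * gaussian_roi(p[1], p[2], p[3], n = nrow(roi)) -
           p[5])^2)
  }
  p <- optim(c(0, 0, sigma0, max(roi), min(roi)), obj,
             method = "BFGS", control = list(maxit = 500))$par
  c(dx = p[1], dy = p[2])
}

# Optimal per-frame assignment cost by brute force (<= 4 tracks/detections).
assignment_cost_oracle <- function(px, py, dx, dy) {
  n <- length(px)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  costs <- vapply(perms(seq_len(n)), function(p) {
    sum(sqrt((px - dx[p])^2 + (py - dy[p])^2))
  }, numeric(1))
  min(costs)
}

# A per-frame two-state tibble built directly from dwell specifications.
states_from_runs <- function(run_states, run_frames, dt = 1 / 60,
                             particle_id = 1L) {
  st <- rep(run_states, run_frames)
  tibble::tibble(particle_id = particle_id, frame = seq_along(st),
                 t_s = seq_along(st) * dt, state = st)
}

# Drop each particle's first dwell: dwells opening at the recording start end
# with an observed transition the boundary-censoring convention discards, so
# removing them (exposure and event) restores an unbiased exponential sample.
drop_first_dwells <- function(lifetimes) {
  dplyr::slice(dplyr::group_by(lifetimes, particle_id), -1) |>
    dplyr::ungroup()
}
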