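test_that("MSD is exact for stationary and ballistic motion and consistent for diffusion", {
  still <- tibble::tibble(particle_id = 1L, frame = 1:200,
                          t_s = (1:200) / 60, x_um = 2, y_um = 3,
                          valid = TRUE)
  expect_true(all(msd(still, 10)$msd_um2 == 0))

  v <- 0.3  # um/s along x
  ball <- tibble::tibble(particle_id = 1L, frame = 1:500,
                         t_s = (1:500) / 60, x_um = v * (1:500) / 60,
                         y_um = 0, valid = TRUE)
  m <- msd(ball, 8)
  expect_equal(m$msd_um2, (v * m$tau_s)^2, tolerance = 1e-12)

  expect_error(msd(still, 200))

  set.seed(10)
  walk <- brownian_walk(1e5, D = 0.4)
  m2 <- msd(walk, 5)
  slope <- sum(m2$tau_s * m2$msd_um2) / sum(m2$tau_s^2)
  expect_equal(slope / 4, 0.4, tolerance = 0.02)
})

test_that("windowed diffusivity matches the brute-force MSD slope and the input D", {
  set.seed(11)
  walk <- brownian_walk(3000, D = 0.4)
  tr <- diffusivity_trace(walk, window = 30, lags = 5)
  expect_equal(nrow(tr), 3000 - 30 + 1)

  # brute-force oracle on one specific window
  j <- 500
  seg <- walk[j:(j + 29), ]
  d_oracle <- msd_slope_oracle(seg$x_um, seg$y_um, 1:5, 1 / 60) / 4
  expect_equal(tr$D_um2_s[j], d_oracle, tolerance = 1e-10)

  # estimator consistency: ensemble of 100 particles within 3 SE of D
  set.seed(12)
  ens <- purrr::map_dfr(1:100, function(i) brownian_walk(600, 0.4,
                                                         particle_id = i))
  tre <- diffusivity_trace(ens)
  per <- dplyr::summarise(dplyr::group_by(tre, particle_id),
                          m = mean(D_um2_s))
  se <- sd(per$m) / sqrt(nrow(per))
  expect_lt(abs(mean(per$m) - 0.4), 3 * se)
})

test_that("a stationary noisy particle gives a small non-negative noise floor", {
  set.seed(13)
  noisy <- brownian_walk(2000, D = 0, sigma_loc = 0.02)
  tr <- diffusivity_trace(noisy)
  expect_true(all(tr$D_um2_s >= 0))
  # static-error floor stays far below the 2.8 um unbound cutoff
  expect_lt(mean(tr$D_um2_s), 0.02)
})

test_that("the trace tracks a square-wave diffusivity switch within one window", {
  set.seed(14)
  dt <- 1 / 60
  seg <- function(D, n) {
    cbind(cumsum(rnorm(n, 0, sqrt(2 * D * dt))),
          cumsum(rnorm(n, 0, sqrt(2 * D * dt))))
  }
  pieces <- purrr::map(1:6, function(i) seg(c(0.4, 0.01)[1 + i %% 2], 300))
  xy <- purrr::reduce(pieces, function(a, b) {
    rbind(a, sweep(b, 2, a[nrow(a), ], "+"))
  })
  walk <- tibble::tibble(particle_id = 1L, frame = seq_len(nrow(xy)),
                         t_s = seq_len(nrow(xy)) * dt, x_um = xy[, 1],
                         y_um = xy[, 2], valid = TRUE)
  tr <- diffusivity_trace(walk, window = 30, lags = 5)
  mid <- (0.4 + 0.01) / 2
  for (switch_frame in 300 * (1:5)) {
    around <- dplyr::filter(tr, abs(frame - switch_frame) <= 30)
    going_down <- (switch_frame %/% 300) %% 2 == 1
    if (going_down) {
      expect_true(any(around$D_um2_s < mid))
    } else {
      expect_true(any(around$D_um2_s > mid))
    }
  }
})

test_that("hysteresis segmentation obeys its defining trivial cases", {
  cfg <- segmentation_config(cutoff = 0.05, min_dwell_frames = 3)
  mk <- function(D) tibble::tibble(particle_id = 1L,
                                   frame = seq_along(D),
                                   t_s = seq_along(D) / 60, D_um2_s = D)
  # entirely above D_hi: single unbound state, zero transitions
  st <- segment_states(mk(rep(0.08, 100)), cfg)
  expect_true(all(st$state == "unbound"))
  expect_equal(nrow(state_transitions(st)), 0)

  # one-sample dip below D_lo with minimum dwell 3: debounced away
  D <- rep(0.08, 100); D[50] <- 0.01
  st2 <- segment_states(mk(D), cfg)
  expect_equal(nrow(state_transitions(st2)), 0)

  # a sustained dip is kept and enters/exits at the hysteresis thresholds
  D3 <- rep(0.08, 100); D3[40:60] <- 0.01
  st3 <- segment_states(mk(D3), cfg)
  tx <- state_transitions(st3)
  expect_equal(tx$direction, c("bind", "unbind"))
  expect_equal(tx$frame, c(40, 61))

  # between-threshold values keep the current state (no chatter)
  D4 <- c(rep(0.08, 20), rep(0.04, 20), rep(0.08, 20))
  st4 <- segment_states(mk(D4), cfg)
  expect_true(all(st4$state == "unbound"))
})

test_that("segmentation is idempotent and invariant to unbound padding", {
  set.seed(15)
  cfg <- segmentation_config(cutoff = 0.05, min_dwell_frames = 9)
  D <- c(rep(0.08, 200), rep(0.012, 150), rep(0.07, 200)) *
    exp(rnorm(550, 0, 0.1))
  base <- tibble::tibble(particle_id = 1L, frame = 1:550, t_s = (1:550) / 60,
                         D_um2_s = D)
  st <- segment_states(base, cfg)
  # idempotent: segmenting the already-segmented trace changes nothing
  st2 <- segment_states(st[names(base)], cfg)
  expect_equal(st2$state, st$state)
  # padding with pure-unbound samples leaves the interior labels alone
  padded <- tibble::tibble(particle_id = 1L, frame = 1:650,
                           t_s = (1:650) / 60,
                           D_um2_s = c(rep(0.09, 50), D, rep(0.09, 50)))
  stp <- segment_states(padded, cfg)
  expect_equal(stp$state[51:600], st$state)
  expect_true(all(stp$state[c(1:50, 601:650)] == "unbound"))
})

test_that("segmentation recovers simulator ground truth at the 2.8 um cutoff", {
  sp <- particle_spec(1.4, 1.6)
  sc <- kinetic_scenario("sandwich", k_on_max = 0.05, C_half = 100)
  cfg <- sim_config(n_particles = 25, block_s = 300)
  sim <- simulate_fov(sp, sc, cfg, concentration = 100, seed = 16)
  trace <- diffusivity_trace(sim$trajectories)
  st <- segment_states(trace, segmentation_config(cutoff = 0.05))
  gt <- as_binary_states(sim$truth)
  cmp <- dplyr::inner_join(st, gt, by = c("particle_id", "frame"),
                           suffix = c("", ".gt"))
  expect_gte(mean(cmp$state == cmp$state.gt), 0.95)

  # every true bound dwell of >= 2 s is detected
  long_true <- dplyr::filter(sim$events, state != "unbound",
                             duration_s >= 2)
  det <- dplyr::filter(st, state == "bound")
  hits <- purrr::pmap_lgl(
    long_true[c("particle_id", "start_frame", "end_frame")],
    function(particle_id, start_frame, end_frame) {
      any(det$particle_id == particle_id & det$frame >= start_frame &
            det$frame <= end_frame)
    })
  expect_true(all(hits))
})

test_that("QC excludes stuck, hyperactive and colliding particles and only those", {
  set.seed(17)
  dt <- 1 / 60
  n <- 1200
  mk_walk <- function(id, D) {
    dplyr::mutate(brownian_walk(n, D, particle_id = id),
                  x_um = x_um + 20 * id)  # separated starting positions
  }
  normal <- purrr::map_dfr(1:28, mk_walk, D = 0.08)
  stuck <- mk_walk(29L, D = 0.003)
  dup_a <- mk_walk(30L, D = 0.08)
  dup_b <- dplyr::mutate(dup_a, particle_id = 31L,
                         x_um = x_um + 0.05, y_um = y_um)
  traj <- dplyr::bind_rows(normal, stuck, dup_a, dup_b)
  trace <- diffusivity_trace(traj)
  # fabricate a hyperactive particle by injecting a chattering state trace
  st <- segment_states(trace, segmentation_config(0.05,
                                                  min_dwell_frames = 3))
  hyper <- dplyr::filter(st, particle_id == 28) |>
    dplyr::mutate(state = rep(c("unbound", "bound"),
                              length.out = dplyr::n()) )
  st <- dplyr::bind_rows(dplyr::filter(st, particle_id != 28), hyper)

  q <- suppressWarnings(qc_filter(traj, st))
  rules <- split(q$exclusions$particle_id, q$exclusions$rule)
  expect_equal(sort(rules$stuck), 29)
  expect_equal(sort(rules$hyperactive), 28)
  expect_setequal(rules$colliding, c(30, 31))
  expect_setequal(unique(q$states$particle_id), 1:27)
})

test_that("a clean ensemble passes QC with a small excluded fraction", {
  sp <- particle_spec(1.4, 1.6)
  sc <- kinetic_scenario("sandwich", k_on_max = 0.05)
  cfg <- sim_config(n_particles = 30, block_s = 120)
  sim <- simulate_fov(sp, sc, cfg, concentration = 100, seed = 18)
  trace <- diffusivity_trace(sim$trajectories)
  st <- segment_states(trace, segmentation_config(0.05))
  expect_no_warning(q <- qc_filter(sim$trajectories, st))
  expect_lt(q$report$fraction, 0.10)
})
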