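hill_y <- function(x, ymin, ymax, n, ec50) {
  ymin + (ymax - ymin) * x^n / (ec50^n + x^n)
}

test_that("the fitted Hill curve passes through its own midpoint at EC50", {
  xs <- 10^seq(0.5, 3.5, length.out = 8)
  curve <- tibble::tibble(concentration = xs,
                          value = hill_y(xs, 1, 5, 1.3, 120))
  f <- fit_hill(curve)
  expect_equal(f$ec50, 120, tolerance = 1e-4)
  expect_equal(f$n, 1.3, tolerance = 1e-3)
  mid <- predict(f, tibble::tibble(concentration = f$ec50))
  expect_equal(mid, (f$y_min + f$y_max) / 2, tolerance = 1e-9)
})

test_that("decreasing (competition) responses fit with y_max below y_min", {
  xs <- 10^seq(0.5, 3.5, length.out = 8)
  curve <- tibble::tibble(concentration = xs,
                          value = hill_y(xs, 4, 0.5, 1, 200))
  f <- fit_hill(curve)
  expect_equal(f$ec50, 200, tolerance = 1e-4)
  expect_lt(f$y_max, f$y_min)
  expect_false(f$increasing)
})

test_that("EC50 CIs from noisy fits cover the generative value", {
  set.seed(26)
  xs <- 10^seq(1, 3, length.out = 8)
  yt <- hill_y(xs, 1, 5, 1, 100)
  cover <- replicate(100, {
    y <- yt * (1 + rnorm(8, 0, 0.05))
    f <- fit_hill(tibble::tibble(concentration = xs, value = y,
                                 se = 0.05 * yt))
    f$ec50_ci[1] <= 100 && 100 <= f$ec50_ci[2]
  })
  expect_gte(mean(cover), 0.9)
})

test_that("Hill fitting rejects unusable inputs", {
  xs <- 10^seq(1, 3, length.out = 6)
  expect_error(fit_hill(tibble::tibble(concentration = xs, value = 2)),
               class = "fbpm_unidentifiable")
  expect_error(fit_hill(tibble::tibble(concentration = xs[1:3],
                                       value = c(1, 2, 3))))
  expect_message(
    f <- fit_hill(tibble::tibble(concentration = c(0, xs),
                                 value = c(1, hill_y(xs, 1, 5, 1, 100)))),
    "blank")
  expect_equal(f$ec50, 100, tolerance = 1e-3)
})

test_that("EC50 is exactly scale-equivariant in concentration", {
  set.seed(27)
  xs <- 10^seq(1, 3, length.out = 8)
  y <- hill_y(xs, 1, 5, 1, 100) * (1 + rnorm(8, 0, 0.02))
  f1 <- fit_hill(tibble::tibble(concentration = xs, value = y))
  f2 <- fit_hill(tibble::tibble(concentration = xs * 1e3, value = y))
  expect_equal(f2$ec50, 1e3 * f1$ec50, tolerance = 1e-6)
})

test_that("relaxation fits recover exact decays and reject constants", {
  t <- seq(0, 60, by = 5)
  y <- 2 + 8 * exp(-t / 13)
  f <- fit_relaxation(t, y)
  expect_equal(f$tau, 13, tolerance = 1e-6)
  # offset invariance: constant shifts are absorbed in y_inf
  f2 <- fit_relaxation(t, y + 5)
  expect_equal(f2$tau, f$tau, tolerance = 1e-6)
  expect_equal(f2$y_inf, f$y_inf + 5, tolerance = 1e-5)

  expect_error(fit_relaxation(t, rep(3, length(t))),
               class = "fbpm_unidentifiable")
  expect_error(fit_relaxation(1:3, c(3, 2, 1)))
})

test_that("dose-response assembly produces all four readouts and pools duplicates", {
  sp <- particle_spec(1.4, 1.6)
  sc <- kinetic_scenario("sandwich", k_on_max = 0.1, C_half = 100)
  cfg <- sim_config(n_particles = 12, block_s = 120)
  ans <- purrr::map(c(50, 400), function(cc) {
    sim <- simulate_fov(sp, sc, cfg, concentration = cc, seed = 30 + cc)
    analyze_trajectories(sim$trajectories, segmentation_config(0.05),
                         qc = FALSE)
  })
  dr <- build_dose_response(ans, c(50, 400))
  expect_setequal(unique(dr$readout),
                  c("activity", "bound_fraction", "tau_unbound", "tau_bound"))
  expect_equal(nrow(dr), 8)

  expect_message(
    drd <- build_dose_response(c(ans, ans[2]), c(50, 400, 400)),
    "pooling")
  expect_equal(nrow(drd), 8)

  expect_error(build_dose_response(ans[1], 50))
})

test_that("monitoring follows a step concentration profile and is deterministic", {
  sp <- particle_spec(1.4, 1.6)
  sc <- kinetic_scenario("sandwich", k_on_max = 0.1, C_half = 100)
  cfg <- sim_config(n_particles = 15, block_s = 120)
  blocks <- tibble::tibble(block = 1:3, t_mid_min = c(2.5, 7.5, 12.5),
                           concentration = c(0, 300, 0))
  traj <- purrr::map2(blocks$block, blocks$concentration, function(b, cc) {
    sim <- simulate_fov(sp, sc, cfg, concentration = cc, seed = 100 + b)
    dplyr::mutate(sim$trajectories, block = b)
  }) |> purrr::list_rbind()

  m1 <- run_monitoring(traj, blocks, seg = segmentation_config(0.05),
                       qc = FALSE)
  m2 <- run_monitoring(traj, blocks, seg = segmentation_config(0.05),
                       qc = FALSE)
  expect_equal(m1$series, m2$series)

  a <- m1$series$activity
  expect_gt(a[2], a[1])  # activity rises with the concentration step
  expect_gt(a[2], a[3])  # and relaxes when target is removed
})

test_that("an all-blank profile stays at the non-specific baseline", {
  sp <- particle_spec(1.4, 1.6)
  sc <- kinetic_scenario("sandwich", k_on_max = 0.1, C_half = 100,
                         k_ns = 0.002)
  cfg <- sim_config(n_particles = 15, block_s = 120)
  blocks <- tibble::tibble(block = 1:2, t_mid_min = c(2.5, 7.5),
                           concentration = 0)
  traj <- purrr::map(1:2, function(b) {
    sim <- simulate_fov(sp, sc, cfg, concentration = 0, seed = 200 + b)
    dplyr::mutate(sim$trajectories, block = b)
  }) |> purrr::list_rbind()
  m <- run_monitoring(traj, blocks, seg = segmentation_config(0.05),
                      qc = FALSE)
  # baseline: both binding and unbinding of rare non-specific events,
  # bounded by a few times the non-specific rate per minute
  expect_true(all(m$series$activity < 6 * 0.002 * 60))
  expect_false(any(m$series$missing))
})

test_that("tidy and glance methods summarise the fitted objects", {
  set.seed(28)
  lt <- tibble::tibble(state = "bound", duration_s = rexp(500, 1 / 4),
                       censored = FALSE)
  f <- fit_exponential(lt)
  td <- tidy(f)
  expect_equal(td$term, "tau")
  expect_equal(glance(f)$n_complete, 500)

  xs <- 10^seq(1, 3, length.out = 8)
  hf <- fit_hill(tibble::tibble(concentration = xs,
                                value = hill_y(xs, 1, 5, 1, 100)))
  expect_equal(tidy(hf)$term, c("y_min", "y_max", "n", "ec50"))
  expect_s3_class(glance(hf), "tbl_df")

  rf <- fit_relaxation(seq(0, 60, 5), 2 + 8 * exp(-seq(0, 60, 5) / 13))
  expect_equal(tidy(rf)$estimate[1], 13, tolerance = 1e-5)
})

test_that("autoplot methods return ggplot objects", {
  set.seed(29)
  lt <- tibble::tibble(state = "bound", duration_s = rexp(200, 1 / 4),
                       censored = FALSE)
  expect_s3_class(autoplot(survival_curve(lt)), "ggplot")
  xs <- 10^seq(1, 3, length.out = 8)
  hf <- fit_hill(tibble::tibble(concentration = xs,
                                value = hill_y(xs, 1, 5, 1, 100),
                                se = 0.1))
  expect_s3_class(autoplot(hf), "ggplot")
})

test_that("analysis reports serialise to JSON", {
  sp <- particle_spec(1.4, 1.6)
  sc <- kinetic_scenario("sandwich", k_on_max = 0.1, C_half = 100)
  sim <- simulate_fov(sp, sc, sim_config(n_particles = 8, block_s = 60),
                      concentration = 200, seed = 77)
  an <- analyze_trajectories(sim$trajectories, segmentation_config(0.05),
                             qc = FALSE)
  tf <- withr::local_tempfile(fileext = ".json")
  write_analysis_report(an, tf)
  parsed <- jsonlite::read_json(tf)
  expect_true(all(c("activity", "bound_fraction", "lifetime_fits") %in%
                    names(parsed)))
  expect_equal(parsed$activity$activity_per_min,
               an$activity$activity_per_min, tolerance = 1e-9)
})
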