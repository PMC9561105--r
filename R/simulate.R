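#' Binding kinetics of an assay scenario
#'
#' Describes how the target concentration maps to the effective single-molecule
#' association rate of a particle, plus the dissociation rates of the bound
#' states. In a sandwich assay the association rate increases with
#' concentration (targets bridge particle and surface); in a competition assay
#' it decreases (targets block the particle-side binders). Non-specific
#' surface interactions contribute a short-lived bound channel at rate `k_ns`.
#'
#' Defaults give a specific bound-state lifetime of 4 s (`k_off` = 0.25/s, the
#' single-molecular bond scale seen across assays) and sparse short-lived
#' non-specific events (`k_ns` = 0.002/s, `k_off_ns` = 1/s).
#'
#' @param mode `"sandwich"` or `"competition"`.
#' @param k_on_max Maximal effective association rate (1/s) of the specific
#'   channel, reached at saturating (sandwich) or zero (competition) target.
#' @param C_half Molecular half-saturation concentration (same units as the
#'   concentrations later passed in; the model is unit-agnostic).
#' @param n_mol Molecular cooperativity exponent (dimensionless, > 0).
#' @param k_ns,k_off_ns Non-specific association/dissociation rates (1/s).
#' @param k_off Specific bond dissociation rate (1/s).
#' @param p_multi Rate (1/s, i.e. probability per bound second) of forming a
#'   second bond while specifically bound; 0 disables multivalence.
#' @param k_off_multi Dissociation rate of the multivalent state (1/s); must be
#'   below `k_off` when multivalence is enabled.
#' @return An object of class `fbpm_scenario`.
#' @examples
#' kinetic_scenario("sandwich", C_half = 100)
#' @export
kinetic_scenario <- function(mode = c("sandwich", "competition"),
                             k_on_max = 0.05,
                             C_half = 100,
                             n_mol = 1,
                             k_ns = 0.002,
                             k_off_ns = 1,
                             k_off = 0.25,
                             p_multi = 0,
                             k_off_multi = k_off / 10) {
  mode <- match.arg(mode)
  rates <- c(k_on_max = k_on_max, C_half = C_half, n_mol = n_mol, k_ns = k_ns,
             k_off_ns = k_off_ns, k_off = k_off, k_off_multi = k_off_multi)
  if (any(rates < 0)) abort("All rates must be non-negative.")
  if (p_multi < 0 || p_multi > 1) abort("`p_multi` must be in [0, 1].")
  if (p_multi > 0 && k_off_multi >= k_off) {
    abort("`k_off_multi` must be below `k_off` when multivalence is enabled.")
  }
  structure(list(mode = mode, k_on_max = k_on_max, C_half = C_half,
                 n_mol = n_mol, k_ns = k_ns, k_off_ns = k_off_ns,
                 k_off = k_off, p_multi = p_multi, k_off_multi = k_off_multi),
            class = "fbpm_scenario")
}

#' Recording and integration configuration
#'
#' Study conditions of a simulated recording: 60 Hz sampling in 5-minute
#' blocks, matching the acquisition scheme the analysis is designed around.
#'
#' @param frame_rate_hz Sampling rate (Hz, default 60).
#' @param block_s Duration of one recording block (s, default 300).
#' @param n_blocks Number of contiguous blocks (default 1).
#' @param n_particles Particles per field of view.
#' @param confinement_um Stationary standard deviation \eqn{\ell_c} of the
#'   bound-state confined motion (um).
#' @param tau_confine_s Correlation time of the bound-state mean-reverting
#'   motion (s); short relative to a frame so bound motion plateaus.
#' @param sigma_loc_um Localization noise added to every reported position (um).
#' @param substeps Euler-Maruyama integration substeps per frame.
#' @param fov_um Field-of-view extent `c(width, height)` in um for initial
#'   positions.
#' @param height_gated If `TRUE`, specific binding is only possible when the
#'   gap height is below `reach_um` (physically gated mode); default `FALSE`
#'   folds the height dependence into the effective rate.
#' @param reach_um Molecular reach for the gated mode (um).
#' @return An object of class `fbpm_sim_config`.
#' @export
sim_config <- function(frame_rate_hz = 60,
                       block_s = 300,
                       n_blocks = 1,
                       n_particles = 500,
                       confinement_um = 0.03,
                       tau_confine_s = 0.005,
                       sigma_loc_um = 0.02,
                       substeps = 10,
                       fov_um = c(706, 530),
                       height_gated = FALSE,
                       reach_um = 0.05) {
  if (frame_rate_hz <= 0) abort("`frame_rate_hz` must be positive.")
  if (block_s <= 0) abort("`block_s` must be positive.")
  if (sigma_loc_um < 0) abort("`sigma_loc_um` must be non-negative.")
  if (confinement_um <= 0) abort("`confinement_um` must be positive.")
  if (substeps < 1) abort("`substeps` must be at least 1.")
  structure(list(frame_rate_hz = frame_rate_hz, block_s = block_s,
                 n_blocks = n_blocks, n_particles = n_particles,
                 confinement_um = confinement_um,
                 tau_confine_s = tau_confine_s,
                 sigma_loc_um = sigma_loc_um, substeps = substeps,
                 fov_um = fov_um, height_gated = height_gated,
                 reach_um = reach_um),
            class = "fbpm_sim_config")
}

#' Effective association rate at a target concentration
#'
#' Maps concentration to the effective particle-surface association rate,
#' including the non-specific floor `k_ns`:
#' sandwich \eqn{k_{ns} + k_{on,max} C^n / (C_{half}^n + C^n)} (increasing),
#' competition \eqn{k_{ns} + k_{on,max} C_{half}^n / (C_{half}^n + C^n)}
#' (decreasing).
#'
#' @param concentration Target concentration(s), >= 0; vectorised.
#' @param scenario A [kinetic_scenario()].
#' @return Rate(s) in 1/s.
#' @examples
#' sc <- kinetic_scenario("sandwich", k_on_max = 0.05, C_half = 100)
#' effective_on_rate(c(0, 100, 1e6), sc)
#' @export
effective_on_rate <- function(concentration, scenario) {
  stopifnot(inherits(scenario, "fbpm_scenario"))
  if (any(concentration < 0)) abort("`concentration` must be non-negative.")
  n <- scenario$n_mol
  ch <- scenario$C_half
  occ <- concentration^n / (ch^n + concentration^n)
  occ[is.nan(occ)] <- 1  # C = Inf
  if (scenario$mode == "competition") occ <- 1 - occ
  scenario$k_ns + scenario$k_on_max * occ
}

#' Simulate one particle
#'
#' Brownian dynamics of a single particle hovering over the sensor surface:
#' in the unbound state the gap height diffuses under gravity with
#' wall-hindered perpendicular mobility (reflecting wall at contact; the
#' stationary height law is the exponential barometric distribution) and the
#' in-plane position takes Gaussian steps with variance
#' \eqn{2 D_0 f_\parallel(h, a) \Delta t}; in bound states the in-plane
#' position mean-reverts around the anchor point with stationary sd
#' \eqn{\ell_c}. Binding and unbinding follow a continuous-time Markov chain
#' with the effective association rate of the scenario at `concentration` and
#' the scenario's dissociation rates. Localization noise is added to every
#' reported position; the exact state sequence is returned as ground truth.
#'
#' @param spec A [particle_spec()].
#' @param scenario A [kinetic_scenario()].
#' @param config A [sim_config()].
#' @param concentration Target concentration for this run.
#' @param seed Optional integer seed.
#' @param particle_id Identifier used in the output tables.
#' @param x0,y0 Initial in-plane position (um); default random in the FOV.
#' @param h0 Initial gap height (um); default drawn from the barometric
#'   distribution (equilibrium start).
#' @return A list of class `fbpm_sim` with tibbles `trajectories`
#'   (`particle_id, frame, t_s, x_um, y_um, valid`), `truth`
#'   (`particle_id, frame, true_state, x_true_um, y_true_um, h_um`) and
#'   `events` (`particle_id, state, start_frame, end_frame, t_start_s,
#'   t_end_s, duration_s`).
#' @export
simulate_particle <- function(spec, scenario, config, concentration,
                              seed = NULL, particle_id = 1L,
                              x0 = NULL, y0 = NULL, h0 = NULL) {
  stopifnot(inherits(spec, "fbpm_particle_spec"),
            inherits(scenario, "fbpm_scenario"),
            inherits(config, "fbpm_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  dt_frame <- 1 / config$frame_rate_hz
  n_frames <- round(config$block_s * config$frame_rate_hz) * config$n_blocks

  k_eff <- effective_on_rate(concentration, scenario)
  k_max <- max(k_eff, scenario$k_off, scenario$k_off_ns, scenario$k_off_multi)
  if (k_max * dt_frame > 0.1) {
    warn(sprintf(
      "Fastest rate (%.3g/s) resolves poorly at %.3g s frames (k*dt = %.2g > 0.1).",
      k_max, dt_frame, k_max * dt_frame))
  }

  hB <- boltzmann_mean_height(spec)
  if (is.null(x0)) x0 <- runif(1, 0, config$fov_um[1])
  if (is.null(y0)) y0 <- runif(1, 0, config$fov_um[2])
  if (is.null(h0)) h0 <- rexp(1, 1 / hB)

  raw <- sim_particle_cpp(
    n_frames = n_frames, dt_frame = dt_frame, substeps = config$substeps,
    D0 = stokes_einstein_d0(spec), a = spec$radius_um, hB = hB,
    floor_par = 0.05,
    k_on_specific = max(k_eff - scenario$k_ns, 0), k_ns = scenario$k_ns,
    k_off = scenario$k_off, k_off_ns = scenario$k_off_ns,
    p_multi = scenario$p_multi, k_off_multi = scenario$k_off_multi,
    height_gated = config$height_gated, reach = config$reach_um,
    lc = config$confinement_um, tau_c = config$tau_confine_s,
    sigma_loc = config$sigma_loc_um,
    x0 = x0, y0 = y0, h0 = h0)

  frame <- seq_len(n_frames)
  t_s <- frame * dt_frame
  states <- .state_labels[raw$state + 1L]
  traj <- tibble(particle_id = particle_id, frame = frame, t_s = t_s,
                 x_um = raw$x, y_um = raw$y, valid = TRUE)
  truth <- tibble(particle_id = particle_id, frame = frame, t_s = t_s,
                  true_state = states, x_true_um = raw$x_true,
                  y_true_um = raw$y_true, h_um = raw$h)
  events <- .events_from_states(states, particle_id, dt_frame)
  structure(list(trajectories = traj, truth = truth, events = events,
                 spec = spec, scenario = scenario, config = config,
                 concentration = concentration),
            class = "fbpm_sim")
}

.state_labels <- c("unbound", "bound_specific", "bound_nonspecific",
                   "bound_multivalent")

# Run-length encode a per-frame state vector into a time-ordered event table.
.events_from_states <- function(states, particle_id, dt_frame) {
  r <- rle(states)
  end_frame <- cumsum(r$lengths)
  start_frame <- end_frame - r$lengths + 1L
  tibble(particle_id = particle_id, state = r$values,
         start_frame = start_frame, end_frame = end_frame,
         t_start_s = (start_frame - 1L) * dt_frame,
         t_end_s = end_frame * dt_frame,
         duration_s = r$lengths * dt_frame)
}

#' Simulate a field of view of independent particles
#'
#' Runs [simulate_particle()] for `config$n_particles` independent particles
#' with per-particle seeds derived deterministically from `seed`, so the
#' full output is bit-reproducible.
#'
#' @inheritParams simulate_particle
#' @param seed Master integer seed.
#' @return A list of class `fbpm_sim` with row-bound `trajectories`, `truth`
#'   and `events` tibbles covering all particles.
#' @examples
#' sp <- particle_spec(1.4, 1.6)
#' sim <- simulate_fov(sp, kinetic_scenario("sandwich"),
#'                     sim_config(n_particles = 2, block_s = 5),
#'                     concentration = 100, seed = 1)
#' dplyr::count(sim$truth, true_state)
#' @export
simulate_fov <- function(spec, scenario, config, concentration, seed = 1L) {
  stopifnot(inherits(config, "fbpm_sim_config"))
  n <- config$n_particles
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  x0 <- runif(n, 0, config$fov_um[1])
  y0 <- runif(n, 0, config$fov_um[2])
  sims <- purrr::pmap(
    list(seq_len(n), seeds, x0, y0),
    function(id, s, xi, yi) {
      simulate_particle(spec, scenario, config, concentration,
                        seed = s, particle_id = id, x0 = xi, y0 = yi)
    })
  structure(
    list(trajectories = purrr::list_rbind(purrr::map(sims, "trajectories")),
         truth = purrr::list_rbind(purrr::map(sims, "truth")),
         events = purrr::list_rbind(purrr::map(sims, "events")),
         spec = spec, scenario = scenario, config = config,
         concentration = concentration, seed = seed),
    class = "fbpm_sim")
}

#' @export
print.fbpm_sim <- function(x, ...) {
  n <- dplyr::n_distinct(x$trajectories$particle_id)
  cat(sprintf(
    "<fbpm_sim> %d particle(s) x %d frames at %g Hz; concentration = %g (%s)\n",
    n, max(x$trajectories$frame), x$config$frame_rate_hz, x$concentration,
    x$scenario$mode))
  bf <- mean(x$truth$true_state != "unbound")
  cat(sprintf("  ground-truth bound fraction: %.3f\n", bf))
  invisible(x)
}

#' Read and write trajectory tables
#'
#' CSV schema: `particle_id,frame,t_s,x_um,y_um,valid` (comma-separated,
#' UTF-8, `.` decimal, one row per particle-frame). The simulator's parallel
#' ground truth uses `particle_id,frame,true_state`.
#'
#' @param trajectories A trajectory tibble.
#' @param path File path.
#' @return `read_trajectories()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  cols <- c("particle_id", "frame", "t_s", "x_um", "y_um", "valid")
  readr::write_csv(trajectories[cols], path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          particle_id = readr::col_integer(),
                          frame = readr::col_integer(),
                          t_s = readr::col_double(),
                          x_um = readr::col_double(),
                          y_um = readr::col_double(),
                          valid = readr::col_logical()))
  need <- c("particle_id", "frame", "t_s", "x_um", "y_um", "valid")
  if (!all(need %in% names(tr))) {
    abort(paste0("Trajectory CSV must have columns: ",
                 paste(need, collapse = ", ")))
  }
  tr
}

#' @rdname write_trajectories
#' @param truth A ground-truth tibble (from [simulate_fov()]).
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(truth[c("particle_id", "frame", "true_state")], path)
  invisible(path)
}

#' Read and write run configurations
#'
#' Serialises a particle spec, kinetic scenario and simulation config to a
#' single structured YAML file (keys mirror the constructor arguments, units
#' um/s/K/g-cm3/mPa-s).
#'
#' @param spec,scenario,config The three configuration objects.
#' @param path File path.
#' @return `read_run_config()` returns a list with elements `spec`,
#'   `scenario`, `config`.
#' @export
write_run_config <- function(spec, scenario, config, path) {
  yaml::write_yaml(list(particle = unclass(spec),
                        scenario = unclass(scenario),
                        recording = unclass(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(spec = do.call(particle_spec, raw$particle),
       scenario = do.call(kinetic_scenario, raw$scenario),
       config = do.call(sim_config, raw$recording))
}
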