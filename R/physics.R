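#' Describe a sedimenting microparticle and its medium
#'
#' Bundles the physical parameters from which the free diffusivity and the
#' equilibrium (barometric) height distribution of a particle above the sensor
#' surface derive. Defaults describe water at room temperature (23 degrees C).
#'
#' @param radius_um Particle radius \eqn{a} in micrometres (> 0).
#' @param density_particle Particle density \eqn{\rho_p} in g/cm^3.
#' @param density_medium Medium density \eqn{\rho_m} in g/cm^3; must be below
#'   `density_particle` so the particle sediments.
#' @param viscosity_mPas Dynamic viscosity \eqn{\eta} in mPa s (> 0).
#' @param temperature_K Absolute temperature in kelvin (> 0).
#'
#' @return An object of class `fbpm_particle_spec` (a named list).
#'
#' @examples
#' particle_spec(radius_um = 1.4, density_particle = 1.6)
#' @export
particle_spec <- function(radius_um,
                          density_particle,
                          density_medium = 1.0,
                          viscosity_mPas = 0.93,
                          temperature_K = 296) {
  if (!is.numeric(radius_um) || length(radius_um) != 1 || !is.finite(radius_um) ||
      radius_um <= 0) {
    abort("`radius_um` must be a single positive number.",
          class = "fbpm_invalid_spec")
  }
  if (viscosity_mPas <= 0) {
    abort("`viscosity_mPas` must be positive.", class = "fbpm_invalid_spec")
  }
  if (temperature_K <= 0) {
    abort("`temperature_K` must be positive.", class = "fbpm_invalid_spec")
  }
  if (density_particle <= density_medium) {
    abort(paste0("`density_particle` must exceed `density_medium`: a neutrally ",
                 "or positively buoyant particle has no equilibrium ",
                 "sedimentation height."),
          class = "fbpm_invalid_spec")
  }
  structure(
    list(radius_um = radius_um,
         density_particle = density_particle,
         density_medium = density_medium,
         viscosity_mPas = viscosity_mPas,
         temperature_K = temperature_K),
    class = "fbpm_particle_spec"
  )
}

#' @export
print.fbpm_particle_spec <- function(x, ...) {
  cat(sprintf(
    "<fbpm_particle_spec> a = %g um, rho_p = %g g/cm3, rho_m = %g g/cm3, eta = %g mPa.s, T = %g K\n",
    x$radius_um, x$density_particle, x$density_medium, x$viscosity_mPas,
    x$temperature_K))
  cat(sprintf("  D0 = %.4g um2/s, barometric mean height = %.4g um\n",
              stokes_einstein_d0(x), boltzmann_mean_height(x)))
  invisible(x)
}

#' Stokes-Einstein free diffusivity
#'
#' \eqn{D_0 = k_B T / (6 \pi \eta a)}, the bulk translational diffusivity of the
#' particle far from any wall, in micrometres squared per second.
#'
#' @param spec A [particle_spec()].
#' @return Diffusivity in um^2/s.
#' @examples
#' stokes_einstein_d0(particle_spec(0.5, 1.8, temperature_K = 298,
#'                                  viscosity_mPas = 0.89))
#' @export
stokes_einstein_d0 <- function(spec) {
  stopifnot(inherits(spec, "fbpm_particle_spec"))
  # eta: mPa.s -> Pa.s; a: um -> m; result m2/s -> um2/s
  .kB * spec$temperature_K /
    (6 * pi * spec$viscosity_mPas * 1e-3 * spec$radius_um * 1e-6) * 1e12
}

#' Mean of the barometric height distribution
#'
#' The equilibrium gap height between particle and substrate follows an
#' exponential (barometric) distribution with mean
#' \eqn{h_B = k_B T / (\Delta\rho \, V g)}, the thermal energy divided by the
#' buoyant weight of the particle.
#'
#' @inheritParams stokes_einstein_d0
#' @param g Gravitational acceleration in m/s^2.
#' @return Mean height in micrometres.
#' @examples
#' # 2.8 um diameter bead, density 1.6 g/cm3: mean height ~ 0.06 um
#' boltzmann_mean_height(particle_spec(1.4, 1.6))
#' @export
boltzmann_mean_height <- function(spec, g = 9.81) {
  stopifnot(inherits(spec, "fbpm_particle_spec"))
  a_m <- spec$radius_um * 1e-6
  delta_rho <- (spec$density_particle - spec$density_medium) * 1e3  # kg/m3
  weight <- delta_rho * (4 / 3) * pi * a_m^3 * g                    # N
  .kB * spec$temperature_K / weight * 1e6                          # m -> um
}

#' Barometric height model
#'
#' @param mean_height_um Mean gap height \eqn{h_B} in micrometres (> 0).
#' @param g Gravitational acceleration in m/s^2.
#' @return An object of class `fbpm_height_model`.
#' @seealso [boltzmann_mean_height()] to derive `mean_height_um` from a
#'   [particle_spec()].
#' @export
height_model <- function(mean_height_um, g = 9.81) {
  if (!is.numeric(mean_height_um) || mean_height_um <= 0) {
    abort("`mean_height_um` must be positive.", class = "fbpm_invalid_spec")
  }
  structure(list(mean_height_um = mean_height_um, g = g),
            class = "fbpm_height_model")
}

#' Sample equilibrium gap heights
#'
#' Draws i.i.d. heights from the exponential barometric distribution.
#'
#' @param model An [height_model()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of heights (um), all non-negative.
#' @export
sample_heights <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "fbpm_height_model"))
  if (n < 1) abort("`n` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  rexp(n, rate = 1 / model$mean_height_um)
}

#' Wall-hindered parallel mobility factor
#'
#' Dimensionless reduction of the in-plane diffusivity of a sphere of radius
#' `a` at gap height `h` above a plane wall, from the 5th-order Faxen
#' series in \eqn{\beta = a/(a+h)}:
#' \deqn{f_\parallel = 1 - \tfrac{9}{16}\beta + \tfrac18\beta^3 -
#'   \tfrac{45}{256}\beta^4 - \tfrac1{16}\beta^5.}
#' The series is clamped below at `floor` near contact, where truncated
#' lubrication expansions degrade.
#'
#' @param h Gap height(s) in um (>= 0); vectorised.
#' @param a Particle radius in um (> 0).
#' @param floor Lower clamp on the factor (default 0.05).
#' @return Factor(s) in (0, 1], non-decreasing in `h`.
#' @examples
#' hindered_parallel(h = 1, a = 1)  # beta = 0.5 -> ~0.721
#' @export
hindered_parallel <- function(h, a, floor = 0.05) {
  if (any(h < 0)) abort("`h` must be non-negative.")
  if (a <= 0) abort("`a` must be positive.")
  vapply(h, f_parallel_cpp, numeric(1), a = a, floor_par = floor)
}

#' Wall-hindered perpendicular mobility factor
#'
#' Brenner-type rational approximation for motion normal to the wall,
#' \eqn{f_\perp = (6h^2 + 2ah)/(6h^2 + 9ah + 2a^2)}; used by the simulator's
#' height dynamics, not by the analysis layer.
#'
#' @inheritParams hindered_parallel
#' @return Factor(s) in (0, 1].
#' @export
hindered_perpendicular <- function(h, a) {
  if (any(h < 0)) abort("`h` must be non-negative.")
  if (a <= 0) abort("`a` must be positive.")
  vapply(h, f_perp_cpp, numeric(1), a = a)
}

#' Height-averaged characteristic diffusivity
#'
#' The expected in-plane diffusivity of a particle whose gap height follows the
#' barometric distribution:
#' \eqn{\langle D \rangle = D_0 \, E[f_\parallel(h, a)]} with
#' \eqn{h \sim \mathrm{Exp}(h_B)}, evaluated by adaptive quadrature. This is
#' the single number that characterises the unbound-state mobility of a
#' particle population and is strictly below the bulk \eqn{D_0}.
#'
#' @inheritParams stokes_einstein_d0
#' @param model Optional [height_model()]; defaults to the barometric model
#'   derived from `spec` via [boltzmann_mean_height()].
#' @param floor Near-contact clamp passed to [hindered_parallel()].
#' @return Diffusivity in um^2/s.
#' @examples
#' sp <- particle_spec(1.4, 1.6)
#' characteristic_diffusivity(sp) < stokes_einstein_d0(sp)
#' @export
characteristic_diffusivity <- function(spec, model = NULL, floor = 0.05) {
  stopifnot(inherits(spec, "fbpm_particle_spec"))
  if (is.null(model)) model <- height_model(boltzmann_mean_height(spec))
  d0 <- stokes_einstein_d0(spec)
  hB <- model$mean_height_um
  integrand <- function(h) {
    hindered_parallel(h, spec$radius_um, floor = floor) *
      stats::dexp(h, rate = 1 / hB)
  }
  q <- tryCatch(
    integrate(integrand, lower = 0, upper = Inf, rel.tol = 1e-8),
    error = function(e) {
      abort(paste0("Height-average quadrature failed to converge: ",
                   conditionMessage(e)),
            class = "fbpm_numerical_error")
    }
  )
  d0 * q$value
}
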