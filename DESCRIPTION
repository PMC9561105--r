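Package: fbpm
Title: Simulation and Analysis of Free-Diffusion Particle-Mobility Biosensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for free-diffusion particle-mobility biosensing, in which
    biofunctionalized microparticles hover over a binder-coated sensor surface
    and switch between freely diffusing (unbound) and confined (bound) states
    as single target molecules reversibly bridge particle and surface.
    Provides closed-form particle physics (Stokes-Einstein diffusivity,
    barometric height distributions, wall-hindered mobility), a Brownian
    dynamics simulator with Markov binding kinetics for sandwich and
    competition assays, synthetic image rendering with phasor-based subpixel
    localization and trajectory linking, windowed mean-squared-displacement
    diffusivity estimation with two-state hysteresis segmentation and
    quality-control filters, censored-exponential dwell-time statistics, and
    Hill-equation dose-response calibration (EC50) with monitoring workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
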