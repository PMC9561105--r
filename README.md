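# fbpm

Simulation and analysis of **free-diffusion particle-mobility biosensing**:
a continuous biomolecular sensing method in which biofunctionalized
microparticles (e.g. 1 or 2.8 μm Dynabeads) hover over a binder-coated
sensor surface, held there by gravity, and reversibly switch between free
Brownian motion (unbound) and confined motion (bound) as single target
molecules bridge particle and surface. Counting these switches turns the
particle ensemble into a digital single-molecule sensor that works from
picomolar to micromolar concentrations without consuming reagents.

The package is for assay developers and analysts who need to (a) prototype
and stress-test the analysis chain on physically calibrated synthetic data,
and (b) run the same chain on trajectory tables from any particle tracker.

## What it computes

**Physics.** A particle of radius $a$ has bulk diffusivity
$D_0 = k_BT/(6\pi\eta a)$; its gap height above the surface is
exponentially distributed with barometric mean $h_B = k_BT/(\Delta\rho V g)$,
and the wall reduces its in-plane mobility by the Faxén factor
$f_\parallel(h, a)$. The height-averaged *characteristic diffusivity*
$D_0\,E[f_\parallel]$ is the mobility signature of a bead type.

**Simulation.** Brownian dynamics (wall-hindered heights with reflecting
boundary, hindered lateral steps) plus a continuous-time Markov binding
model whose effective association rate rises (sandwich) or falls
(competition) with concentration; exact ground-truth states are returned.

**Analysis.** Windowed-MSD diffusivity traces ($D$ = origin-constrained
MSD slope / 4 over a sliding 30-frame window), two-state hysteresis
segmentation at per-bead-size cutoffs (0.15 / 0.05 μm²/s for 1 / 2.8 μm
beads), QC exclusion of stuck / hyperactive / colliding particles,
dwell-time extraction with right-censoring, censored-exponential and
bi-exponential lifetime MLEs, switching activity and bound fraction.

**Calibration.** Four-parameter Hill fits
$y = y_{min} + (y_{max}-y_{min})\,x^n/(EC50^n + x^n)$ with 95% CI on EC50,
exponential relaxation-time fits, dose–response assembly and a block-wise
continuous-monitoring workflow. Optional imaging front end: Gaussian spot
rendering to 16-bit TIFF, phasor-based subpixel localization, greedy
nearest-neighbour linking.

## Worked example

Simulate a 2.8 μm sandwich assay at five target concentrations, run the
full analysis chain, and calibrate the activity dose–response:

```r
library(fbpm)
library(dplyr)

sp <- particle_spec(radius_um = 1.4, density_particle = 1.6)  # 2.8 um bead
sp
#> <fbpm_particle_spec> a = 1.4 um, rho_p = 1.6 g/cm3, rho_m = 1 g/cm3, eta = 0.93 mPa.s, T = 296 K
#>   D0 = 0.1665 um2/s, barometric mean height = 0.06041 um

scn <- kinetic_scenario("sandwich", k_on_max = 0.05, C_half = 100)
cfg <- sim_config(n_particles = 60, block_s = 300)

an <- simulate_fov(sp, scn, cfg, concentration = 100, seed = 1)$trajectories |>
  analyze_trajectories(segmentation_config(cutoff = 0.05))
an
#> <fbpm_analysis> 60 particles: activity 2.05/min (SEM 0.11), bound fraction 0.0949
#>   unbound tau = 65.1 +/- 4.1 s
#>   bound tau = 5.63 +/- 0.32 s

levels <- c(10, 30, 100, 300, 1000)
analyses <- purrr::map(seq_along(levels), function(i) {
  simulate_fov(sp, scn, cfg, concentration = levels[i], seed = i)$trajectories |>
    analyze_trajectories(segmentation_config(0.05))
})
fit <- build_dose_response(analyses, levels) |>
  filter(readout == "activity") |>
  fit_hill()
fit
#> <fbpm_hill_fit> EC50 = 82.61 [95% CI 7.717, 884.3], n = 1.15, y_min = 0.1323, y_max = 3.352
```

Reading the output: at the molecular half-saturation concentration (100)
the ensemble switches about twice per particle-minute; the unbound lifetime
(65 s) reflects the effective association rate at that concentration, and
the bound lifetime sits at the single-molecular-bond scale (the 4 s
generative bond lifetime, left-truncated by the 1.5 s segmentation
debounce). The fitted activity EC50 (83) recovers the generative
half-saturation constant (100) well within a factor 2; its CI is wide
because only five concentrations constrain a four-parameter sigmoid.
`autoplot(fit)` draws the calibration curve, and `tidy()`/`glance()` give
broom-style summaries of any fitted object.

A thin command-line wrapper over the same functions is included at
`inst/cli/fbpm.R`, with subcommands `simulate`, `render`, `localize`,
`analyze`, `dose-response` and `monitor`.

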