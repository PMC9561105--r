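---
title: "Models and methods behind fbpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fbpm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbpm)
library(dplyr)
```

## The sensing principle

In free-diffusion particle-mobility biosensing, micrometre-scale particles
functionalised with affinity binders hover over a binder-coated sensor
surface, held near it by gravity rather than by a molecular tether. When a
target molecule bridges particle and surface (sandwich format) or when the
particle binds a surface-bound analogue (competition format), the particle's
motion switches from free Brownian diffusion to confined motion around the
bond anchor. Tracking hundreds of particles at video rate and classifying
each particle's effective diffusivity over time turns single-molecule
binding and unbinding into countable digital events. Three ensemble readouts
carry the concentration signal: the *switching activity* (binding plus
unbinding events per particle per minute), the *bound fraction* (fraction of
particle-time spent bound), and the *characteristic state lifetimes*
(exponential time constants of the unbound and bound dwell-time
distributions).

`fbpm` implements this entire chain: closed-form particle physics, a
Brownian-dynamics simulator with Markov binding kinetics that stands in for
microscopy recordings, an optional imaging front end (rendering, phasor
localization, linking), motion analysis (windowed-MSD diffusivity,
two-state segmentation, quality control), dwell-time kinetics with
censoring, and dose-response calibration.

## Particle physics

A particle of radius $a$ in a medium of viscosity $\eta$ at temperature $T$
has bulk diffusivity $D_0 = k_B T / (6\pi\eta a)$. Sedimentation balances
thermal motion so the particle-surface gap height $h$ is exponentially
distributed (the barometric law) with mean
$h_B = k_B T / (\Delta\rho\, V g)$, the thermal energy over the buoyant
weight. With the default conditions (water at 23 °C, $T = 296$ K,
$\eta = 0.93$ mPa·s, $g = 9.81$ m/s²):

```{r heights}
sp28 <- particle_spec(radius_um = 1.4, density_particle = 1.6)  # M-270 class
sp1  <- particle_spec(radius_um = 0.5, density_particle = 1.8)  # MyOne class
c(h28_nm = boltzmann_mean_height(sp28) * 1000,
  h1_um  = boltzmann_mean_height(sp1))
```

The larger, denser bead hovers tens of nanometres above the surface; the
small bead explores a micrometre-scale layer. Near the wall, hydrodynamic
coupling reduces the in-plane mobility by the factor
$f_\parallel(\beta) = 1 - \tfrac{9}{16}\beta + \tfrac18\beta^3 -
\tfrac{45}{256}\beta^4 - \tfrac1{16}\beta^5$ with $\beta = a/(a+h)$ (the
truncated Faxén series for parallel motion). The series is smooth and
monotone over the whole range and is clamped below at a configurable floor
(default 0.05) as a guard, although the truncated series itself never drops
below ≈ 0.32. Note the truncation also controls the far-field approach to
1, which goes as $(9/16)\,a/(a+h)$ — at $h/a = 10^4$ the factor is still
about $5\times10^{-5}$ short of unity. For the height dynamics of the
simulator we use the standard Brenner-type rational approximation
$f_\perp = (6h^2+2ah)/(6h^2+9ah+2a^2)$, which has the exact lubrication
($h \to 0$) and far-field limits. The exact near-wall mobility curve used
by any particular instrument pipeline may differ slightly; these standard
approximations are a modelling choice, not a transcription.

The single number that characterises a particle population's unbound
mobility is the height-averaged *characteristic diffusivity*
$\langle D\rangle = D_0\, E[f_\parallel(h)]$ with $h \sim \mathrm{Exp}(h_B)$,
computed by adaptive quadrature and cross-checked against Monte-Carlo
averaging in the tests:

```{r chard}
c(D1 = characteristic_diffusivity(sp1),
  D28 = characteristic_diffusivity(sp28),
  ratio = characteristic_diffusivity(sp1) / characteristic_diffusivity(sp28))
```

The two bead types differ by roughly a factor 4-6 depending on the
hindrance law; with the Faxén series above the quadrature gives ≈ 5.6.

## The simulator

`simulate_fov()` generates the study conditions the analysis is designed
for: 60 Hz sampling in contiguous 5-minute blocks, several hundred
particles per field of view. Per particle and frame (10 Euler-Maruyama
substeps by default):

* **Unbound**: the gap height follows overdamped dynamics
  $\mathrm{d}h = [D_\perp'(h) - D_\perp(h)/h_B]\,\mathrm{d}t +
  \sqrt{2 D_\perp(h)\,\mathrm{d}t}\,\xi$ with a reflecting wall at $h = 0$.
  The first drift term is the Itô correction for state-dependent mobility;
  without it the stationary height law would not be the barometric
  exponential (the tests verify the stationary law by a KS test). Lateral
  steps are Gaussian with variance $2 D_0 f_\parallel(h)\,\Delta t$.
* **Bound**: the in-plane position mean-reverts around the anchor
  (Ornstein-Uhlenbeck) with stationary standard deviation
  $\ell_c = 0.03$ μm and correlation time 5 ms, so bound-state windowed
  diffusivity falls well below the segmentation cutoffs; the height is
  frozen at the binding height.
* **Switching** is a continuous-time Markov chain sampled per substep. The
  effective association rate maps concentration through a Hill-shaped
  occupancy: sandwich
  $k_{ns} + k_{on,max}\,C^n/(C_{half}^n + C^n)$ (increasing), competition
  $k_{ns} + k_{on,max}\,C_{half}^n/(C_{half}^n + C^n)$ (decreasing). Real
  assays do not come with a known functional form for the effective
  association rate; this mapping is the generator's modelling choice, with
  the half-saturation constant as the generative "truth" that end-to-end
  EC50 recovery is judged against. Defaults: $k_{off} = 0.25$/s (4 s
  specific bond lifetime, the single-molecular bond scale), non-specific
  channel $k_{ns} = 0.002$/s with 1 s lifetime (sparse, short-lived), and
  an optional multivalent tier (second bond at rate `p_multi` while bound,
  slower dissociation) for long-lived bound populations, off by default.
  Binding is height-independent by default — the hit rate and binder
  densities are folded into the effective rate, which is all the analysis
  layer sees — with an optional height-gated mode (binding only when
  $h <$ 0.05 μm) for physical realism.
* **Localization noise**: $\sigma_{loc} = 0.02$ μm i.i.d. Gaussian on every
  reported position, a realistic subpixel-tracking precision at these
  photon budgets.

Per-particle seeds are derived deterministically from the master seed, so a
field of view is bit-reproducible. The exact state sequence is returned as
ground truth for every particle, which is what segmentation and kinetics
are validated against.

What the generator does *not* emulate: particle-particle hydrodynamics and
steric collisions, electrostatic particle-surface potentials, rotational
diffusion, binder-density heterogeneity across particles, drift and
vibration of the stage, and depth-dependent imaging artefacts. Passing
tests therefore demonstrate correctness of the analysis chain on an
idealised but physically calibrated motion model, not robustness to every
artefact of real video data.

## Motion analysis

The effective diffusivity trace is computed per particle in a sliding
window (default $W = 30$ frames, 0.5 s at 60 Hz, sliding by one frame):
within each window the 2D MSD over lags 1..5 is fitted through the origin
by least squares and $D = \text{slope}/4$. The window and lag counts
balance time resolution against estimator variance for dwells on the
seconds scale; they are configurable. Two numerical details matter:

* Static localization error adds $4\sigma_{loc}^2$ to every MSD lag. The
  origin-constrained slope therefore carries a positive noise floor of
  $\sigma_{loc}^2\,\Sigma_v \tau_v/\Sigma_v \tau_v^2 \approx 0.007$ μm²/s
  at the defaults — negligible against the unbound signal and absorbed into
  the bound-state plateau. Estimator-consistency checks are run at
  $\sigma_{loc} = 0$ where the slope is exactly unbiased.
* Sampling noise can drive small-window slopes negative for nearly
  stationary particles; negative slopes are clipped to zero and counted in
  the `n_clipped` attribute of the trace.

Segmentation uses a hysteresis rule around the per-bead-size diffusivity cutoffs
(0.15 μm²/s for 1 μm beads, 0.05 μm²/s for 2.8 μm beads): enter the bound
state when $D$ falls below $0.6\times$cutoff, leave when it rises above the
cutoff, and merge dwells shorter than three window lengths (1.5 s) into the
surrounding state. Hysteresis suppresses threshold chatter; the debounce
floor sits below the ~4 s bond lifetimes of interest. The consequence,
verified in the tests, is that segmentation recovers ≥ 95% of frames
correctly but *undercounts* events shorter than the debounce floor — so
segmented activity is a lower bound on ground-truth activity, and segmented
bound lifetimes are left-truncated (their mean exceeds the molecular
$1/k_{off}$ by roughly the truncation threshold). Kinetic parameter
recovery at the few-percent level is therefore assessed on dwell sets
extracted from states directly, while pipeline-level checks assert
direction and monotonicity, which truncation preserves.

Quality control mirrors standard practice for this kind of recording:
stuck particles (mean $D < 0.01$ μm²/s), hyperactive particles (activity
more than 4 ensemble standard deviations above the mean; meaningful for the
hundreds-of-particles ensembles it is designed for, not for a handful of
tracks), and colliding pairs, operationalised as centroids within two
pixel-equivalents (0.69 μm) for more than 1 s since no tolerance is
standard. A warning fires if ≥ 10% of particles are excluded.

## Dwell-time kinetics and censoring

Dwells are delimited by segmentation transitions; a dwell abutting the
start or end of an observation window is flagged right-censored and carries
its observed duration as a lower bound. Contiguous recording blocks are
treated as one observation window — a block boundary with no time gap
censors nothing, which keeps the censored estimate invariant under block
subdivision of an uninterrupted recording. The censored maximum-likelihood
estimate for an exponential lifetime is
$\hat\tau = \sum_i t_i / n_{\text{complete}}$ (all observed durations over
the number of uncensored dwells), with standard error
$\hat\tau/\sqrt{n_{\text{complete}}}$.

One bookkeeping subtlety is documented rather than hidden: a dwell that
*opens* at the recording start ends with an observed transition, but the
boundary convention counts it as censored, so its event is lost from the
denominator. For dense recordings this inflates the unbound estimate by
roughly (particles / unbound events). Analyses that need a strictly
unbiased exponential sample can drop each particle's first dwell, which by
memorylessness leaves an exact exponential sample.

A `"naive"` mode treats censored dwells as complete. It exists because
finite recordings saturate naive lifetime estimates at the observation
window scale — with a 3 × 300 s recording and a true lifetime far beyond
it, the naive estimate plateaus near ~850-900 s — and reproducing that
saturation behaviour faithfully requires the uncorrected estimator.
Bi-exponential dwell mixtures (short-lived monovalent plus long-lived
multivalent bonds) are fitted by EM on complete dwells, with a degeneracy
guard (components closer than a factor 2, or a weight pinned to 0/1) that
falls back to the single-exponential fit. Both whole-set and
initial-segment fitting (`t_max`, truncating longer dwells to a censored
bound) are exposed, since a "characteristic lifetime" can legitimately be
attributed to the initial survival-curve segment only.

Switching activity counts both binding and unbinding transitions, per
particle per minute, with the SEM across particles as the uncertainty; the
bound fraction is the per-particle time average, averaged across particles.
Particles are the replication unit throughout — the natural choice when
blocks are few and particles are hundreds.

## Dose-response calibration

All four readouts are fitted with the four-parameter sigmoid
$$y = y_{\min} + (y_{\max} - y_{\min})\,\frac{x^n}{EC50^n + x^n},$$
by weighted least squares (inverse-variance weights floored at the median
SEM, so a single tiny error bar cannot dominate). EC50 and the Hill
coefficient are log-parameterised internally, which enforces positivity and
keeps the optimisation well-conditioned across pM-μM concentration ranges;
decreasing (competition) responses need no special casing because
$y_{\max} < y_{\min}$ is allowed. The Hill coefficient is left free by
default (`fix_n` fixes it). The 95% CI on EC50 comes from the linearised
covariance with a t quantile on the log scale; a seeded percentile
bootstrap (1000 resamples) is the fallback when the covariance is
unavailable, and can be forced. Blank (zero-concentration) points cannot
sit on a log axis and are dropped from Hill fits with a message; they
belong to the relaxation analysis, where
$y(t) = y_\infty + (y_0-y_\infty)e^{-t/\tau}$ is fitted to the readout
after a concentration step to give the sensor relaxation time.

Because activity, bound fraction and lifetimes weight the underlying
kinetics differently, their EC50s need not coincide with each other or with
the molecular half-saturation constant; end-to-end validation therefore
asserts recovery of the generative half-saturation within a factor 2 for
the activity readout, plus correct monotonic direction for both assay
formats.

## Problem sizes and reproducibility

The test suite validates estimator consistency on ensembles of 100
particles × 300 s, segmentation fidelity on 100 particles at the 2.8 μm
cutoff, lifetime recovery on more than 10⁴ simulated bond events, EC50
coverage on 200 replicate noisy fits, and a five-level dose series of 60
particles per level through the complete pipeline — sizes chosen so each
property is measured well inside its sampling error while the whole suite
runs in a few minutes. Every stochastic step is seeded, and
`scripts/acceptance.R` recomputes the analytic headline quantities (the two
barometric heights and the characteristic-diffusivity ratio) from scratch.

## Known limitations

* The two-state segmentation is a threshold/hysteresis classifier; it does
  not attempt the harder problem of classifying sub-second events or
  distinguishing mono- from multivalent bound states frame by frame.
* Dwell-time estimates inherit the debounce truncation discussed above.
* The simulator's binding is memoryless; real binder depletion, surface
  heterogeneity and matrix effects (e.g. plasma) appear only as effective
  rate changes.
* The imaging front end assumes symmetric Gaussian spots and greedy
  nearest-neighbour linking, adequate at the particle densities simulated
  here but not a general-purpose multi-target tracker.
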