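---
title: "Growth phases of a simulated hyphal network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth phases of a simulated hyphal network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycelia)
set.seed(1)
```

## The model

`mycelia` simulates the two-dimensional growth of a filamentous-fungus
mycelium (the system is calibrated on *Podospora anserina* growing on a
standard dextrin medium, called M2 below) as a lattice-free binary tree
with lateral branches. Three elementary processes generate the network:

1. **Tip elongation.** Every hypha grows by adding material at its apex,
   which advances at a tip speed along a continuously perturbed heading.
2. **Apical (subapical) branching.** A growing tip periodically splits.
   The arc distance between consecutive branch points on the same hypha
   is `L0 + X` where `L0 = 180` µm is the apical dominance (latency)
   length and `X` is base-2 exponential with rate `alpha = 10.4e-3`
   µm^-1 (survival `2^(-alpha x)`). The branch point sits a subapical
   offset `L_api ~ N(41, 11)` µm (truncated at 0) behind the tip. The
   daughter making the widest angle with the mother projection is the
   *operating* branch, the one continuing closest to the mother
   direction the *exploratory* branch.
3. **Lateral branching.** New branches also emerge from the flank of a
   hypha, but only at least `L_dominance = 480` µm behind the owning
   apex. Events are a superposition of *isolated* nucleations, uniform
   in position on the newly eligible flank within a 90-min aging window,
   and *burst* trains clustered near existing laterals, with spacing
   density proportional to `2^(-gamma1 dL)` (`gamma1 = 2.3e-3` µm^-1)
   and base-2 exponential waiting times at rate `41e-3` min^-1. Trains
   continue with probability `1 - uniform_fraction = 0.78` after each
   event, so isolated events are 22% of the mix.

Branch sides are not symmetric relative to the mother's local bending:
the new branch emerges on the side *opposite* the local curvature with
probability 0.82 (subapical) and 0.72 (lateral). Because turning angles
are symmetric, the global clockwise/counterclockwise frequency remains
1/2: the side preference is local and creates no global chirality.

### Spontaneous curvature

Between branchings, the heading of a tip is perturbed once per
`step_length = 20` µm of advance by a turning angle drawn from the
shifted-Beta density proportional to
`(theta0 - theta)^a (theta + theta0)^b` on `(-theta0, theta0)`. (The
factor `(theta0 - theta)^a` is required for the expression to be a
nonnegative density; chirality would be broken by `a != b`, and the
defaults use `a = b = 2` so the mean turning angle is zero.) Sampling
uses the exact representation `theta = theta0 (2U - 1)`,
`U ~ Beta(b + 1, a + 1)`, whose mean `theta0 (b - a)/(a + b + 2)` also
serves as a closed-form test oracle.

A pure random walk of the heading cannot simultaneously reproduce two
observed features: the small global tortuosity (arc-chord measure
`alpha = (L_tot - L_p)/(L_tot + L_p) ≈ 0.038`, which for a worm-like
chain forces a persistence length of a few hundred µm) and the
ballistic, radial spreading of the thallus (the principal lengths of
the apex cloud grow linearly in time). Real hyphae wiggle locally but
keep a growth axis. The turning update therefore includes a weak
restoring drift toward the hypha's axis
(`axis_reversion = 0.2` per step): heading deviations mean-revert over
about 100 µm, giving locally wiggly, globally directed growth. With
`theta0 = 0.9` rad this reproduces tortuosity ≈ 0.039 while keeping the
colony radial. Both `theta0` and `axis_reversion` are calibration
knobs: the turning-law parameters are not measured directly, only the
tortuosity and the zero-mean constraint are.

### Tip velocity

Two velocity modes exist.

* The **germination ramp** (`elongation_velocity()`),
  `v(t) = v_asym (1 - 2^(-t/tau))` with `v_asym = 4.5` µm/min and `tau`
  solved from the constraint that a germination hypha accumulates
  500 µm in its first 7 h (`tau ≈ 7.47` h). This describes the measured
  acceleration of the leading hyphae out of the ascospore and is
  available with `germination_params(use_ramp = TRUE)`.
* The **reference mode** (default) advances all tips at a constant mean
  speed `v_tip = 2.2` µm/min.

The reference speed is a derived calibration, not a printed value, and
the reasoning deserves a paragraph because it is the single most
consequential choice in the simulator. The leading-hyphae asymptote
(4.5 µm/min) combined with the measured branch spacing (mean ≈ 319 µm)
would imply that every apex branches every ~1.2 h, i.e. an apex-count
doubling frequency `omega ≈ 0.9` h^-1 — far above both the calibrated
simulation value (0.59 h^-1) and the experimental ones (0.46–0.49
h^-1). In reality not every tip advances at the leading-edge speed. The
effective mean advance consistent with the observed growth rate is
`v_tip = omega ln2 <spacing> ≈ 132` µm/h ≈ 2.2 µm/min, and a constant
speed also makes the principal lengths of the apex cloud grow linearly
from germination, as observed for the calibrated simulation. Running
the reference with the full 4.5 µm/min ramp instead delays the density
minimum to ~9.5 h and makes the early surface growth quadratic; the
ramp mode is therefore kept for studying the early experimental phase,
not for the reference conditions.

### Lateral nucleation intensity

The printed isolated-branch rate (`p = 6e-3` µm^-1 per 90-min window)
is a *local* law: it is what fixes the 80 µm length at which the
probability of an isolated branch in one window reaches 1/2
(`isolated_halflength()`). Applied naively as a hazard over the whole
newly-eligible flank of every hypha, with burst trains of mean size
`1/0.22 ≈ 4.5`, it would produce several lateral branches per hypha per
hour — two orders of magnitude above the apical rate, which contradicts
both the observed event counts and the exponential growth rate. The
per-hypha nucleation intensity is therefore scaled by a calibration
factor `activity` (default 0.1), chosen once so that laterals remain
the minority contribution to apex production and the reference growth
rate lands in the measured band. The spacing and timing laws of the
trains are kept at their measured values; the burst/isolated mix is
22/78 by construction.

## The density observable and the growth phases

For each snapshot the package counts the one-body vertices
`N1 = #V1 + #V1l` (tips of main and lateral branches) and builds the
inertia tensor of their locations from centred coordinates, normalised
by the number of points, so the eigenvalues `lambda1 >= lambda2` are
per-point dispersions (µm²) and `r_i = sqrt(lambda_i)` are lengths.
(The raw second-moment sums would grow with the count as well as the
spread; the per-point normalisation is what makes `r_i` grow linearly
while `N1` grows exponentially, and the density below scale as
`2^(omega t)/t^2`.) The surface proxy is `r1 r2` and the density
observable is

    rho_o(t) = N1(t) / (r1(t) r2(t)).

With `N1 = C 2^(omega t)` and `r_i = B_i t`, the model form is
`rho = D 2^(omega t) / t^n` with `D = C/(B1 B2)` and `n = 2`, so the
density diverges at both ends and has its minimum at

    t_min = n / (omega ln 2),

depending only on the growth rate. The minimum separates an extension
phase (density falls as tips explore), a stationary phase, and a
densification phase driven by lateral branching. Two configuration
variants probe the mechanism: `variant_dense_config()` (tenfold lateral
activity, operating angle 120°) moves the minimum earlier, and
`variant_sparse_config()` (no laterals, exploratory angle 10°) moves it
later; the reference sits between them.

Uncertainties on `rho_o` come from a bootstrap over apex locations
combined with Poisson noise on the count, reflecting the
counting-process character of `N1`. The minimum is located as the
argmin of a local-quadratic smooth of `log rho` versus time (window of
5 points; the counting noise is multiplicative, hence the log), refined
to sub-grid precision by the vertex of the quadratic around the
discrete argmin; a series whose smoothed argmin falls on either end is
flagged as having no interior minimum. On the analytic curve
`D 2^(omega t)/t^n` the detector recovers `n/(omega ln2)` to better
than 0.1 h across a grid of `(omega, n)`.

## Numerical choices

* Time step `dt = 0.1` h; curvature is applied per 20 µm of *arc*, so
  turning statistics are independent of `dt` (verified by a refinement
  test on the discretised advance).
* Branch points are placed at the exact sampled arc distances along the
  hypha and snapped to the nearest polyline node for the graph
  representation; the recorded inter-branch distances are the exact
  draws, so distribution-level tests probe the law, not the spatial
  discretisation (node spacing is at most `v dt ≈ 13` µm).
* Snapshots are taken every 18 min, the cadence of the imaging series
  the model is compared against.
* Snapshots with fewer than 3 apexes or a collinear cloud
  (`lambda2 <= 1e-6 lambda1`) are dropped from density series with a
  warning; with two germination hyphae this covers roughly the first
  3–4 h.
* Crossings (`V3i`) are computed on demand by exact segment-pair
  orientation tests (with a uniform-grid prefilter above 200 segments)
  and never stored as nodes; collinear overlaps count zero, as a
  measure-zero configuration of the continuous model. Anastomosis
  (true hyphal fusion) is not modelled.
* The two-step mixture fit (exponential first, then exponential plus
  flat level with the decay frozen) is iterated up to three times on
  the floor-subtracted histogram: at large sample sizes the uniform
  floor otherwise biases the log-linear decay estimate. At
  experiment-like sample sizes (n ≈ 150) the estimator remains noisy
  and downward-biased — consistent with the wide printed uncertainty of
  the uniform share (±11%) — and the package makes no quantitative
  claim at that scale.
* All exponential laws are base-2 throughout; natural-log factors
  appear only inside closed forms (`ln 2`).

## What the generator does and does not emulate

The synthetic conditions reproduce: the branch-spacing laws, the
lateral dominance and mixture structure, the side-versus-curvature
preferences with a balanced global orientation, tortuosity ≈ 0.038, an
apex-count doubling frequency in the measured band (≈ 0.45 h^-1 for the
reference), near-linear growth of `r1, r2`, and a density minimum near
6 h bracketed by the two variants.

They do **not** emulate: anastomosis, septation, tip death or
stalling, nutrient fields and tropisms, hyphal diameter, 3-D aerial
escape, or the image-acquisition noise of real data. Image-level
quantities (per-replicate growth rates, eigenvalue slopes of a given
experiment, the sphericity 0.88 of the imaged colony) are therefore not
reproduction targets; they enter only as configuration defaults or
qualitative bands, and passing tests show internal consistency of the
model under its stated laws — not agreement with unseen imaging data.

## Design choices on genuinely open points

* **Initial hyphae.** Two germination hyphae with near-opposite
  headings; the observation of six initial hyphae across three
  replicates reads most naturally as two per spore.
* **Crossings in the one-body ratio.** `V3i` are included in the
  junction denominator by default (they are present in images and
  indistinguishable there from junctions); `one_body_ratio()` exposes a
  flag to exclude them.
* **Lateral spacing metric.** `Delta L` between successive lateral
  events is planar (Euclidean) by default, with an along-hypha option,
  since the observed quantity is the distance between event locations.
* **Which daughter is which.** At a subapical branching the existing
  tip continues as the exploratory branch (deflecting by the small
  angle towards the side opposite the new branch) and the new apex is
  the operating branch at the wide angle.
* **Apex count in the density.** `N1` counts tips of both main and
  lateral branches throughout.

## Problem sizes used by the shipped checks

The test suite runs reference and variant ensembles of 10 seeds at 15 h
of model time with 20 bootstrap replicates per snapshot, and the
reproduction script uses 40 seeded replicates for the measured minimum;
law-recovery checks use 10^4 draws. These sizes put Monte-Carlo error
comfortably below the tolerances being checked while keeping a full run
in minutes on a single core.

## A minimal session

```{r example, eval = FALSE}
cfg <- reference_config(t_end = 15, seed = 1)
traj <- run_growth(cfg)
traj

ds <- density_series(traj, B = 200)
mn <- detect_density_minimum(ds)
mn$t_min

fit <- fit_density_series(ds)
c(omega = fit$count_fit$omega, D = fit$density_model$D,
  t_min_model = fit$density_model$t_min)
```

## Known limitations

* The minimum of the measured density sits in a shallow valley; its
  per-replicate location scatters by more than an hour, which is why
  ensemble means over many seeds are reported.
* Small-sample mixture fits (n below a few hundred) are indicative
  only.
* The simulator's graphs are planar polylines with straight segments
  between nodes ~13 µm apart; curvature below that scale is not
  represented.
* With two germination hyphae the apex cloud stays anisotropic for
  several hours; per-snapshot sphericity is strongly seed-dependent
  even late in growth.
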