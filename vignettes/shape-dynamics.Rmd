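---
title: "Shape dynamics of C. elegans larval growth from large-particle cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape dynamics of C. elegans larval growth from large-particle cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stretcher)
```

## The scientific problem

*C. elegans* grows through four larval stages separated by molts, during
which the collagen-rich cuticle is shed and resynthesized. Because the
cuticle is elastic, it constrains how the body can change shape between
molts. The Stretcher model formalizes this: while the cuticle stretches
linearly under internal growth pressure, the ratio of width change to length
change,

$$ r(t) \;=\; \frac{dW/dt}{dL/dt} \;=\; \frac{dW}{dL}, $$

is constant within a larval stage; when the cuticle is stretched beyond its
linear range near the end of a stage it stiffens anisotropically and $r(t)$
rises; and immediately after the molt the animal relaxes into its new,
unstressed cuticle — length jumps while width slightly decreases (or, in
genotypes with altered cuticle mechanics, the reverse). Cuticle-collagen
mutants (Dpy: short and wide; Lon: long) are natural probes of this
mechanism.

This package implements the full measurement-to-inference pipeline for
large-particle flow cytometer (COPAS BIOSORT) growth assays: per-object
records of TOF (time of flight, an axial length proxy), EXT (integrated
optical extinction; EXT/TOF is a width proxy) and red fluorescence from
ingested beads (a feeding proxy) are gated, summarized per well, calibrated
to micrometres, and analyzed for molt timing and slope-ratio shape dynamics.
A seeded synthetic-data generator with planted ground truth makes every
stage of the pipeline testable without instrument data.

## Pipeline and model components

### Synthetic data generator

`strain_profile()` encodes one genotype: molt times, per-stage length growth
rates (µm/h), baseline aspect slopes $c_k = dW/dL$, the nonlinear-stiffening
onset (fraction of stage duration) and slope gain, the post-molt relaxation
direction and magnitude, and the feeding dip at each molt.
`default_strain_profiles()` ships four profiles encoding the study
contrasts: N2 and *lon-3(e2175)* on near-identical schedules, both *dpy*
mutants delayed with *dpy-1(e1)* molting last at every transition, *dpy*
strains shorter and wider, *dpy-1* with a weak nonlinear regime and reduced
relaxation, and *dpy-5(e61)* relaxing in the opposite direction (length
decreases at the molt while width moves up).

Model choices, made once and used everywhere:

* **Growth law.** Within a stage, length grows linearly in time — the
  simplest law producing the observed ramps, and one that keeps closed forms
  available for oracle tests. Growth pauses during a lethargus window of
  ±`feeding_dip_halfwidth` (default 2 h) around each molt: animals neither
  feed nor grow while molting. Without this pause a post-molt size *decrease*
  could never appear in hourly population medians, because two hours of
  growth would swamp any relaxation step; with it, the relaxation step is
  the only size change near the molt, which is exactly the regime in which
  relaxation is observable in real populations.
* **Width law.** Width follows length through the stage-wise ratio: $dW/dL =
  c_k$ up to the nonlinear onset, then rising linearly to $c_k \cdot
  \mathrm{gain}$ at the stage end. The trajectory is evaluated in closed form
  (piecewise quadratic in time), so finite-difference checks against the
  analytic ratio are exact to numerical tolerance.
* **Relaxation step.** At each molt the decreasing dimension steps by
  $-$`relaxation_magnitude` (this matches how the analysis measures
  magnitude) and the complementary dimension steps $+2\times$ (length jump
  after a length-relax) or $+0.3\times$ (width change after a width-relax)
  the magnitude. Defaults: 5 µm width decrease for N2 and *lon-3*, 2 µm for
  *dpy-1* (its reduced relaxation), 10 µm length decrease for *dpy-5*.
* **Population desynchronization.** Per-animal molt-time jitter with SD
  0.3 / 0.6 / 1.0 h for molts 1–3, growing with stage as populations
  desynchronize with age.
* **Measurement model.** `tof = tof_per_pixel × 3.2937 px/µm × length`,
  `norm_ext` analogously from width, `ext = tof × norm_ext`, and red
  fluorescence proportional to feeding rate × pixel area, all with
  configurable Gaussian noise (defaults: 10 µm length, 1.5 µm width, 15%
  fluorescence). The imaging conversion factor of 3.2937 pixels/µm is the
  package default throughout.
* **Contaminants.** Two instrument-unit log-normal classes: dense small
  "blobs" (bacterial clumps: small TOF, high extinction density) and faint
  elongated "streaks" (shed cuticles: animal-scale TOF, ~10% of animal
  extinction density). Their rate and parameters are configurable; the
  defaults were chosen to overlap the animal cloud realistically. Counts per
  well are Poisson with mean $n_\text{animals}\,\rho/(1-\rho)$ so the
  expected contaminant fraction equals `contaminant_rate` for any rate in
  $[0,1)$.
* **Seeding.** One master seed; each well draws from a counter-derived
  stream (`split_seed()`), so identical configurations are bit-identical
  and changing the number of wells never reshuffles other wells.

What the generator does *not* emulate: bacterial food dynamics, optical
artifacts of the imager, density-dependent instrument effects, non-Gaussian
measurement error, or per-animal growth-rate heterogeneity beyond molt-time
jitter. Passing planted-truth tests therefore demonstrates correctness of
the inference machinery under the stated statistical structure, not
robustness to every failure mode of real cytometer data.

### Gating

`gate_animals()` separates animals from contaminants per (strain, hour)
pool on `(log TOF, log EXT)`: a Gaussian mixture with 1–4 components
(`mclust`), with removal only when a multi-component model beats a single
Gaussian by more than 10 BIC units. The largest component is taken as
animal — animals dominate every pool — and components within 0.8 log units
of the animal cloud (in both dimensions, transitively) are merged back, so
the pre-/post-molt size sub-clusters that straddle a molt are never
half-discarded; remaining points better explained by a discarded component
are trimmed. Small pools fall back to a 1.5·IQR rule; single objects pass
through; after hour 30 a TOF floor removes next-generation larvae, which are
genuine (small) animals no shape rule can separate. Each pool iterates to a
fixed point, making gating idempotent, and the whole rule is deterministic.
EM is capped at 200 iterations per fit — the estimates are long converged
for classification purposes well before that; an unbounded EM can crawl on
degenerate pools.

### Summaries and calibration

`summarize_wells()` computes per-(strain, well, hour) medians of TOF,
norm.EXT and area-normalized fluorescence (`red/(tof × norm_ext)`; the
product of the length and width proxies is the natural optical-area proxy
for BIOSORT records, and the normalization is applied per object before the
median). `fit_calibration()` converts manual image measurements (pixels, at
3.2937 px/µm) to micrometres and regresses them through the origin on the
matched instrument medians — a zero-length object has zero TOF, and the
no-intercept form avoids extrapolation artifacts at small L1 sizes.
`convert_units()` applies the fitted slopes, keeping the raw columns so the
conversion is invertible.

### Molt detection

`detect_molts()` smooths the population median of normalized fluorescence
(local-linear kernel regression, bandwidth 1.5 h — feeding dips are broad
structures) and reports local minima with topographic prominence of at
least 15% of the smoothed dynamic range, separated by at least 5 h (stages
are more than 7 h apart in all profiles; the more prominent dip wins), at
most three minima in the 1–42 h span. Prominence is range-relative, so
detection is invariant to affine rescaling of the fluorescence units.
Detection operates on population medians; per-well molt calling is out of
scope.

### The Stretcher fit

`stretcher()` is the package's central fitting function. For each
(strain, stage) growth window it:

1. selects well-level observations (`select_window()`); the shipped
   `stage_windows()` are the study's windows — L1 1–10 h for all strains,
   L2 16–22 (N2, *lon-3*), 19–26 (*dpy-1*), 19–24 (*dpy-5*), L3 27–31 (N2),
   27–32 (*lon-3*), 31–35 (*dpy-1*), 30–34 (*dpy-5*), and no L4 window (the
   population is too variable in L4). Windows derived from detected molts
   (`windows_from_molts()`) are available as an alternative;
2. smooths length and width on a 0.25 h grid by local-linear Gaussian
   kernel regression, taking derivatives from the local slope coefficient
   (lines are reproduced exactly, and the derivative estimator equals a
   per-point weighted least-squares fit to machine precision);
3. quantifies uncertainty by a cluster bootstrap: whole wells are resampled
   with replacement (1000 replicates by default) and the smoothing repeated,
   with the same resamples for length and width;
4. forms $r(t) = W'(t)/L'(t)$ *within each replicate*, reporting the
   replicate mean as the central curve and the replicate SD as the band, so
   the band reflects ratio variability rather than a ratio of averaged
   derivatives. Grid points where the length slope falls below 5% of the
   window's median absolute slope are masked to avoid ratio blow-up;
5. segments the window: the linear baseline is the median of $r$ over the
   first third of the window (the linear regime sits at the start of a
   stage), and the nonlinear onset is the earliest grid time after which
   $r(t) - \text{baseline} > z\,\mathrm{SD}(t)$ at every later point
   ($z = 2$). Nonlinear labels therefore always form a suffix of the
   window, and raising $z$ can only move the onset later;
6. characterizes post-molt relaxation (`characterize_relaxation()`):
   population medians in ±2 h windows on either side of each molt give
   $\Delta L$ and $\Delta W$; $\Delta L > 0,\ \Delta W < 0$ is a
   length-relax, $\Delta L < 0,\ \Delta W > 0$ a width-relax, the magnitude
   is the decreasing component's absolute value, and any other sign pattern
   is flagged ambiguous rather than forced into a direction. Signed
   $\Delta L$ and $\Delta W$ are always reported alongside the label, since
   the direction vocabulary in the literature is ambiguous (a "relaxation
   in width" can describe either the decreasing or the changing dimension).

The fit returns a classed object with `print`, `summary`, `coef` (the
linear-regime slope ratio $\hat c_k$ and onset per window) and `plot`
(slope-ratio curves with SD shading, or the length–width phase plane)
methods.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `h_bw` (fit) | 0.5 | h | kernel bandwidth for shape curves |
| `h_bw` (molts) | 1.5 | h | bandwidth for fluorescence smoothing |
| `grid_step` | 0.25 | h | evaluation grid |
| `n_boot` | 1000 | – | bootstrap replicates |
| `z` | 2 | SD | regime-segmentation threshold |
| `deriv_floor_frac` | 0.05 | – | slope-ratio masking floor |
| `relax_margin` | 2 | h | half-window around molts |
| `min_prominence` | 0.15 | of range | molt dip threshold |
| `min_separation` | 5 | h | minimum molt spacing |

**Why a 0.5 h bandwidth for the fit.** Kernel smoothing spreads the
post-onset rise of $r(t)$ backwards in time by roughly one bandwidth. With
well-replicated data the bootstrap band is narrow, so the $z\cdot$SD rule
crosses as soon as that smoothing-biased rise is resolvable — i.e. up to a
bandwidth *before* the true kink. At a 1.5 h bandwidth this misplaces a
kink planted at 70% of an L2-like window by ~1.5 h; at 0.5 h — matched to
the hourly sampling, which supplies a full population median per hour — the
onset estimate is essentially unbiased while lines are still reproduced
exactly. Fluorescence smoothing keeps the wider 1.5 h bandwidth because
feeding dips are several hours wide and dip *location*, not onset, is the
estimand there.

### Numerical choices and degenerate inputs

Local-linear solves return an error when a grid point has no effective
kernel mass (bandwidth far too small). Ratio masking uses both the relative
floor and a tiny absolute floor so that windows with no length growth at
all raise an error instead of returning noise ratios. Windows shorter than
3 h are returned unclassified and flagged. Ties in molt-timing ranks are
shared and flagged, with display order broken by strain label. Quartiles in
all Tukey box statistics use the linear-interpolation convention (R type 7),
with whiskers at the most extreme points within 1.5 IQR of the quartiles.

## Problem sizes used by the tests

The test-suite and acceptance-script simulations use 5–30 wells per hour
and 12–25 animals per well — enough for population medians to be stable
while keeping each seeded replicate small; the full-scale assay
(hourly sampling for 42 h, dozens of wells, thousands of animals) is the
generator's default and runs in seconds. Bootstrap sizes in tests are
100–200 replicates; the fit default remains 1000. Recovery studies use
10–50 seeded replicates per check, matching the sampling depth at which the
planted effects (molt times to ±1 h, $c_k$ to 10%, onset to ±1 h,
relaxation direction) are resolvable at the generator's default noise.

## Known limitations

* The gate cannot, by construction, separate contaminants whose optical
  signature falls inside the animal cloud; next-generation larvae are
  handled only by the late-hour size floor.
* Onset detection assumes a single linear-to-nonlinear transition per
  window that persists to the window end (a suffix); transient excursions
  are labeled linear.
* Relaxation characterization assumes hourly sampling and a growth pause
  around molts of at least the margin width; with fast post-molt regrowth
  the growth term would re-enter the ±2 h medians and bias $\Delta L$
  upward.
* The slope-ratio analysis is descriptive: no mechanical elasticity
  constants are estimated, and no between-strain hypothesis tests are
  performed.
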