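---
title: "Methods: movement and trophic ecology of central-place foraging seabirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement and trophic ecology of central-place foraging seabirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seaforage)
```

`seaforage` implements the full analysis chain used in sympatric-seabird
foraging studies that combine GPS tracking with stable-isotope sampling:
behavioural annotation of tracks, kernel utilization-distribution (UD)
overlap with a randomization null, environmental gradient predictors,
variance-components repeatability, isotopic niche metrics, and Bayesian
diet mixing. This vignette explains each model, its assumptions, the
parameters that matter, and the design choices made where the methodology
was genuinely open. All numerical claims below are the ones the package's
own test suite computes.

## The synthetic-data generator

Field data of this kind (multi-season GPS deployments plus plasma isotope
panels) are rarely released, so the package ships a seeded generator whose
output has the statistical structure every downstream module assumes. It is
first-class, tested code, not a fixture.

**Tracks.** `simulate_tracks()` produces central-place foraging trips from a
colony (default: Raso Islet, Cabo Verde, 16.6113°N, 24.5877°W) at a 5-minute
fix interval. Movement is a state-switching correlated random walk over four
behavioural states with quadrant semantics on the (speed, turn) plane — LL
rest, LH intensive foraging, HL travel, HH relocate. The state sequence is a
first-order Markov chain initialized at its stationary distribution; per
state, speed is normal and the heading is updated by a wrapped normal turn.
Default kinematics (travel ≈ N(35, 5) km/h with small turns, foraging ≈
N(8, 3) km/h with large turns, rest ≈ N(1, 0.5) km/h, relocation ≈ N(30, 5)
km/h with large turns) are stand-ins chosen to be separable by the behaviour
module while remaining ornithologically plausible; published studies report
the quadrant semantics, not per-state kinematic distributions, so these
defaults are documented stand-ins rather than field estimates. Trip closure
is achieved by a heading attraction towards the colony whose weight grows
after a bird-specific outbound phase; a per-bird lognormal effect on the
outbound length (SD 0.35 on the log scale, residual 0.18) is what makes
trip-level metrics repeatable within individuals.

**Rasters.** `simulate_environment()` builds one static depth layer and
monthly SST, CHLA, SSH and OMLT layers on a 0.08° grid (the analysis grid
used throughout) as sums of low-order spatial harmonics plus mild noise —
smooth enough to be realistic, rough enough that moving-window gradients are
non-trivial. A `constant` mode yields flat fields whose gradients are zero
everywhere, used for degenerate-input tests.

**Isotopes.** `simulate_isotopes()` draws prey samples from the three prey
source groups used in the diet analyses (epipelagic fish: δ¹³C −16.98 ±
0.50‰, δ¹⁵N 10.05 ± 0.78‰; juvenile fish: −18.47 ± 0.24‰, 8.38 ± 0.43‰;
squid: −17.02 ± 1.56‰, 11.66 ± 2.18‰) and consumer plasma values from the
mixing-model forward equations: mean Σₖ pₖ(μₖⱼ + cⱼ) and variance
Σₖ pₖ²(σₖⱼ² + σ_c,j²) + ε², with c the trophic discrimination factor and
ε = 0.2‰ residual noise, the order of the analytic precision of isotope-ratio
mass spectrometry. Because consumers are generated by exactly the forward
model the mixing module inverts, simulation-based calibration of the
posterior is meaningful.

What the generator does *not* emulate: GPS position error, device failure,
irregular sampling gaps, tides/wind, or spatial prey fields coupling
movement to the rasters. Passing tests therefore demonstrate correctness of
the estimators under their own assumptions, not robustness to the
idiosyncrasies of real deployments.

All randomness flows from one master seed through fixed per-module offsets,
so each generator is independently reproducible.

## Trip segmentation and metrics

`split_trips()` keeps maximal runs of fixes farther than 1 km from the
colony (padded with the adjacent at-colony fix on each side) and discards
runs shorter than 30 minutes; both values are configurable — the radius
matches the colony-attendance scale of boobies, the minimum duration
prevents logger jitter from forming spurious trips. Speeds use the
haversine distance (sphere radius 6371 km); turning angles are the absolute
smallest difference of successive headings in [0, π], sign-agnostic to
match the low/high-turn cluster semantics. Trip proportions are computed
over fix counts, which equal time shares at a uniform fix interval. The
distal bearing is the initial great-circle bearing from the colony to the
most distant fix.

## Behavioural annotation

`fit_embc()` fits a 4-component bivariate Gaussian mixture by EM over
(log speed, turn). Log speed tames the right skew of speeds; delimiters are
reported back on the natural scale. After convergence (log-likelihood gain
< 1e-6, at most 300 iterations; the monotone-likelihood EM guarantee is
asserted every iteration), per-axis delimiters are placed midway between
the two lower and two upper component means, and components are assigned to
the four quadrants by a minimum-cost bijection against the quadrant
archetypes implied by the delimiters. Initialization splits the data at the
per-axis medians into archetype cells; restarts (up to 5, jittered) handle
EM degeneracies. The model is fitted pooled across individuals — pooling
stabilizes small per-bird samples — and labelling is a separate step, so a
per-bird or per-season fit is a configuration choice, not a code change.
This module guarantees the quadrant-semantics contract; it does not aim for
bit-compatibility with any particular published implementation of
binary-delimited clustering.

## Space use and overlap

`fit_kernel_ud()` evaluates a bivariate Gaussian kernel at the centers of
the 0.08° analysis grid and normalizes to unit mass. Kernels are geographic
(degrees); at ~16.6°N the lon/lat anisotropy is about 4%, and an
equirectangular rescaling toggle (`equirect = TRUE`) removes it for
sensitivity analyses. The bandwidth comes from least-squares
cross-validation (`lscv_bandwidth()`, exact closed form for Gaussian
kernels, minimized on a log-scale bracket around the bivariate-normal
reference rule); LSCV famously degenerates towards h → 0 with duplicated
points, in which case the reference bandwidth is returned and flagged. One
bandwidth, estimated on a designated reference dataset, is reused for every
group so that overlap differences reflect distribution, not smoothing.

Isopleths are the smallest sets of highest-mass cells reaching the stated
mass (50% = core foraging region, 95% = home range; ties included
together). `ba_overlap()` computes Bhattacharyya's affinity Σ√(p₁p₂); with
a level given, each UD is first restricted to its own isopleth and
renormalized — this makes the 50% and 95% comparisons genuinely different
quantities, which is why both are reported; whether published BA tables
used full or isopleth-restricted UDs is typically unstated, so both are
available (`level = NULL` gives the full-UD affinity).

`ud_permutation_test()` reassigns whole individuals to groups (group sizes
preserved), recomputing both UDs and the BA with the same bandwidth and
grid; p is the proportion of permuted BA values strictly below the observed
one (small p = segregation). The exchangeable unit is the individual, not
the trip, because trips within a bird are strongly autocorrelated —
permuting trips would overstate significance; a point-level mode exists for
sensitivity analysis. Under the null the p-value is approximately uniform
(mean p over 50 seeded null runs falls in [0.35, 0.65] in the test suite),
and well-separated foraging centers are detected at p ≤ 0.05 in ≥ 95% of
seeded runs.

## Environmental predictors

Gradients use the proportional-change formula PC = (max − min) × 100 / max
over a 3×3 moving window, truncated at edges so coastal cells keep a
gradient. The formula is undefined when the window maximum is not positive
(possible for SSH, and for depth conventions with negative values): such
cells are masked, and a documented `offset` mode shifts the layer positive
first. Depth is treated as positive metres for this reason. Regridding is
block-mean aggregation when coarsening and bilinear interpolation when
refining; extraction is nearest-cell (not bilinear), matching
raster-resolution habitat analysis. `vif_screen()` iteratively drops the
highest-VIF covariate until all VIFs ≤ 3, with ties broken by name so the
result is independent of column order; the pipeline ends at the
model-ready covariate table — GAMM/GLMM fitting is intentionally out of
scope and left to the modeller.

Because no GeoTIFF-capable R package is assumed, rasters travel as ESRI
ASCII grids (plain text, GIS-readable) via `write_ascii_grid()` /
`read_ascii_grid()`.

## Repeatability

The printed definitions of individual- and population-level repeatability
in the behavioural-ecology literature are often typeset without
parentheses; the package implements the only reading bounded in [0, 1],
the intraclass-correlation ratios

R_ind = S²_A / (S²_ind + S²_A),   R_pop = S²_A / (S² + S²_A),

with S²_A the between-individual variance from the unbalanced one-way
ANOVA moment estimator (negative estimates truncated to zero), S²_ind the
unweighted mean of per-individual variances and S² the pooled
within-individual variance. Moment estimators keep the module transparent
and dependency-light; a REML mixed-model route would give near-identical
answers at these sample sizes but hides the variance components. Bands
follow the conventional rule: low < 0.25 ≤ moderate < 0.5 ≤ high.
"Adjusted" repeatability is repeatability of the residuals of a
least-squares fixed-effects fit (e.g. sex, season), mirroring the
with/without fixed-effect comparison. Uncertainty is a bootstrap over
individuals. The suite verifies recovery at R ∈ {0, 0.5, 1} (200
individuals × 20 trips; a single draw of that design has sampling SD
≈ 0.027 on the estimate).

## Isotopic niche

`body_condition_index()` is the residual of mass on wing length per group.
`layman_metrics()` computes the six community metrics (CR, NR, convex-hull
TA, CD, NND, SDNND) exactly as defined on the δ¹³C–δ¹⁵N bi-plot.
`standard_ellipse()` returns the 1-σ covariance ellipse: SEA = π√(λ₁λ₂),
SEAc = SEA·(n−1)/(n−2). For a bivariate normal the standard ellipse covers
1 − e^(−1/2) ≈ 39.35% of future draws — the "40% ellipse" of the isotope
literature; the test suite measures this coverage empirically. The Bayesian
variant `sea_bayes()` uses a conjugate normal–inverse-Wishart prior
(ν₀ = 3, κ₀ = 1, prior scale = sample covariance, prior mean = sample
mean): weakly informative, proper, and with a closed-form posterior — no
MCMC needed; published ellipse frameworks defer on priors, so this choice
is the package's own. Ellipse overlap uses 720-vertex polygon clipping
(Sutherland–Hodgman; both polygons convex), a vertex count at which the
polygonal area error is far below the Monte-Carlo oracle tolerance used in
tests; the overlap is reported as area, as a proportion of the combined
niche (intersection / union), and as the posterior probability that one
group is narrower — published overlap tables are ambiguous about which is
meant, so all three are emitted.

## Diet mixing

The mixing model treats each consumer's (δ¹³C, δ¹⁵N) as normal with mean
Σₖ pₖ(μₖⱼ + cⱼ) and variance Σₖ pₖ²(σₖⱼ² + σ_c,j²) + εⱼ² — the
process-error formulation in which source and discrimination uncertainty
propagate weighted by pₖ². The trophic discrimination factor defaults to
plasma values of −0.18‰ (δ¹³C) and +1.72‰ (δ¹⁵N) with an SD of 1.0‰ per
isotope; the TEF variance is *added* to the source variance (not
substituted), the conservative reading of "accounting for" discrimination
uncertainty. The prior is Dirichlet(1,…,1) on p — the "no prior diet
information" choice — and half-Normal(0, 1‰) on each residual ε, a weakly
informative scale for plasma data; both are configurable. Sampling is
random-walk Metropolis on additive-log-ratio coordinates of p and log ε:
during burn-in (half of the run) the proposal adapts both its global scale
(Robbins–Monro towards 25% acceptance) and its covariance (adaptive
Metropolis, 2.38²/d × the running covariance), then freezes, so the kept
draws come from a valid fixed-kernel chain. Four chains by default;
split-R̂ > 1.05 fails loudly rather than returning a doubtful posterior.
Simulation-based calibration in the test suite (50 replicates of 40
consumers forward-simulated at p = (0.6, 0.3, 0.1)) requires ≥ 90%
coverage of each true proportion by the 95% credible intervals. Note that
with realistic source spreads and a ±1‰ TEF SD the posterior is wide:
three sources separated by ~1–3‰ against ~1–2.4‰ combined SDs is a weakly
identified problem, and honest uncertainty is the point of the Bayesian
treatment.

## Orchestration

`run_pipeline()` chains simulate (or load) → segment → annotate → trip
metrics → UDs and overlap test → predictors and VIF screen → repeatability
→ niche metrics → diet mixing, writing tidy CSVs, ASCII-grid UDs and a
JSON manifest (seed, config hash, package version, per-stage log). Given a
seed the run is bit-reproducible; any stage failure writes a `FAILED`
marker naming the stage and keeps completed outputs. A thin command-line
wrapper (`inst/scripts/seaforage-pipeline.R`, YAML-configured) exposes the
same entry point to shell users; the R functions remain the primary
interface.

## Problem sizes and numerical choices

Default test and demonstration sizes are deliberately desk-scale: a few
birds × a few trips for end-to-end runs, hundreds of points per UD, 200 ×
20 designs for repeatability recovery, 50-replicate calibration loops for
the permutation test and the mixing model, 4 × 4000–6000 MCMC iterations.
These sizes were chosen so that each estimator's sampling noise is small
against the property being asserted. Ties in isopleth masses are included
together; EM covariance updates carry a 1e-8 ridge; LSCV brackets
[h_ref/8, 8·h_ref]; the `isopleth(level = 1)` boundary case returns the
full positive support directly rather than relying on a cumulative-sum
epsilon.

## Known limitations

- The generator's per-state kinematics and transition matrix are plausible
  defaults, not field estimates; absolute values of trip metrics should
  not be read as predictions for any real colony.
- Kernel UDs are fixed-bandwidth and ignore temporal autocorrelation;
  Brownian-bridge or autocorrelated kernel estimators are out of scope.
- The mixing model has no concentration dependence and assumes normal
  sources; strongly non-normal prey pools would need a different
  likelihood.
- Field results that depend on unreleased tracking/isotope data cannot be
  reproduced; the package reproduces the *machinery* and verifies it
  against analytic and brute-force oracles plus printed constants.
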