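# seaforage

Movement and trophic ecology of central-place foraging seabirds, as one
tested R pipeline. The package implements the analysis chain used in
sympatric-seabird studies that combine GPS tracking and stable isotopes —
for example two booby species sharing a tropical colony — and ships a
seeded synthetic-data generator so the whole chain can be exercised and
verified without access to (typically unreleased) field data.

The chain, module by module:

1. **Simulation** — state-switching correlated-random-walk foraging trips
   from a colony at a 5-min fix interval; monthly oceanographic rasters
   (DEP, SST, CHLA, SSH, OMLT) on a 0.08° grid; consumer/prey isotope
   tables generated from the mixing-model forward equations.
2. **Trajectories** — central-place trip segmentation; per-step speed and
   turning angle; trip metrics (duration, maximum colony distance, distal
   bearing, behaviour-time proportions).
3. **Behaviour** — expectation–maximization clustering of (log-speed,
   turn) into four quadrant-semantic modes: LL resting, LH intensive
   foraging, HL travelling, HH relocating.
4. **Space use** — kernel utilization distributions (LSCV bandwidth), 50%
   core-foraging-region and 95% home-range isopleths, Bhattacharyya's
   affinity BA = Σ√(p₁p₂) ∈ [0, 1], and a randomization test that permutes
   whole individuals between groups (p = proportion of permuted overlaps
   below the observed one).
5. **Environmental predictors** — moving-window proportional-change
   gradients PC = (max − min) × 100 / max on a 3×3 window, regridding to
   0.08°, nearest-cell extraction, and iterative VIF screening (threshold 3).
6. **Repeatability** — variance-components intraclass ratios
   R_ind = S²_A/(S²_ind + S²_A) and R_pop = S²_A/(S² + S²_A), with
   bootstrap uncertainty and the low/moderate/high bands at 0.25 and 0.5.
7. **Isotopic niche** — body condition index (mass-on-wing residuals),
   Layman metrics (CR, NR, TA, CD, NND, SDNND), standard ellipse areas
   SEA/SEAc (the ~40% ellipse), a Bayesian SEA_B via a conjugate
   normal–inverse-Wishart posterior, and pairwise ellipse overlaps.
8. **Diet mixing** — Bayesian mixing model with likelihood
   x_ij ~ N(Σₖ pₖ(μₖⱼ+cⱼ), Σₖ pₖ²(σₖⱼ²+σ_c,j²) + εⱼ²), Dirichlet(1) prior
   on diet proportions, trophic discrimination c = (−0.18‰, +1.72‰) ± 1.0‰
   for plasma, adaptive random-walk Metropolis with split-R̂ diagnostics.
9. **Orchestration** — `run_pipeline()` chains everything into a report
   directory with a seed/config-hash manifest; a thin CLI lives at
   `inst/scripts/seaforage-pipeline.R`.

## Worked example

```r
library(seaforage)

cfg    <- sim_config(groups = c(female = 4L, male = 4L),
                     trips_per_bird = 3L, seed = 42)
tracks <- simulate_tracks(cfg)
trips  <- split_trips(tracks$fixes, cfg$colony_lonlat)
steps  <- do.call(rbind, lapply(unique(trips$trip_id), function(id)
  step_features(trips[trips$trip_id == id, , drop = FALSE])))
model  <- fit_embc(steps, seed = 42)
model
#> Four-mode behaviour model (EM Gaussian mixture on log-speed x turn)
#>   delimiters: speed 17.02 km/h, turn 0.22 rad
#>   comp 1 -> LL  weight 0.257  mean (log-speed 0.97, turn 0.20)
#>   comp 2 -> LH  weight 0.318  mean (log-speed 2.25, turn 1.12)
#>   comp 3 -> HL  weight 0.195  mean (log-speed 3.43, turn 0.02)
#>   comp 4 -> HH  weight 0.230  mean (log-speed 3.55, turn 0.23)
```

The fitted delimiters split the plane at 17 km/h and 0.22 rad; the
low-speed/high-turn component (8–9 km/h, ~64° mean turn) is labelled LH —
intensive foraging. Trip metrics and the space-use overlap test:

```r
labels  <- label_fixes(trips, model)
metrics <- trip_metrics_table(trips, labels, cfg$colony_lonlat)
head(metrics[, c("bird_id", "trip_id", "duration_h",
                 "max_dist_colony_km", "prop_forage")], 4)
#>     bird_id       trip_id duration_h max_dist_colony_km prop_forage
#> 1 female_01 female_01_T01       2.92               42.6       0.111
#> 2 female_01 female_01_T02       2.25               13.6       0.393
#> 3 female_01 female_01_T03       2.42               18.8       0.100
#> 4 female_02 female_02_T01       1.92               18.1       0.417

forage <- trips[!is.na(labels) & labels == "LH", ]
h  <- as.numeric(lscv_bandwidth(forage[, c("lon", "lat")]))
ov <- ud_permutation_test(forage, level = 0.95, h = h,
                          n_perm = 200, seed = 42)
ov
#> BA overlap at 95% UD: observed 0.712, permuted 0.712 +/- 0.039, p = 0.535 (n_perm = 200)
```

Here both simulated groups forage from the same colony with the same
kinematics, so the observed home-range overlap (0.712) sits in the middle
of its permutation null — no segregation, p = 0.535. Diet reconstruction
for the female group:

```r
iso  <- simulate_isotopes(cfg)
post <- fit_mixing(iso$consumers[iso$consumers$group == "female", ],
                   cfg$source_groups, seed = 42)
summarize_posterior(post)
#>       source mean median   q25  q75   q2.5 q97.5
#> 1 epipelagic 0.39   0.40 0.246 0.52 0.0505  0.72
#> 2   juvenile 0.44   0.44 0.356 0.51 0.2050  0.67
#> 3      squid 0.18   0.16 0.085 0.26 0.0087  0.40
```

Posterior means are diet proportions (rows sum to 1); the wide credible
intervals are honest — with three isotopically close sources and a ±1‰
discrimination SD the problem is weakly identified by design. The full
chain in one call: `run_pipeline(pipeline_config(sim = cfg), "out/")`.

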