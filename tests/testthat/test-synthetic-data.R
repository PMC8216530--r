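# The generator must reproduce the study conditions the analyses assume:
# 5-min fixes, closed central-place trips, Markov state structure, printed
# prey moments, and the mixing forward model.

test_that("degenerate configs give empty but well-formed output", {
  cfg <- sim_config(trips_per_bird = 0L)
  tr <- simulate_tracks(cfg)
  expect_s3_class(tr$fixes, "data.frame")
  expect_equal(nrow(tr$fixes), 0)
  expect_named(tr$fixes, c("bird_id", "group", "trip_id", "timestamp", "lon", "lat"))
})

test_that("config invariants are enforced", {
  bad_tm <- default_transition_matrix(); bad_tm[1, 1] <- 0.5
  expect_error(sim_config(transition = bad_tm), "row-stochastic")
  expect_error(sim_config(true_diet = list(g = c(0.5, 0.6, 0.1))), "simplex")
  expect_error(sim_config(fix_interval_min = 0))
})

test_that("fixes are at a constant 5-min interval within trips and time-ordered per bird", {
  cfg <- sim_config(groups = c(f = 3L), trips_per_bird = 3L, seed = 9)
  fx <- simulate_tracks(cfg)$fixes
  dts <- unlist(lapply(split(fx, fx$trip_id), function(tr)
    diff(as.numeric(tr$timestamp))))
  expect_true(all(dts == 300))
  for (b in split(fx$timestamp, fx$bird_id))
    expect_false(is.unsorted(b, strictly = TRUE))
})

test_that("trips start and end within the colony radius", {
  cfg <- sim_config(groups = c(f = 3L), trips_per_bird = 3L, seed = 4)
  fx <- simulate_tracks(cfg)$fixes
  for (tr in split(fx, fx$trip_id)) {
    d <- gc_dist_km(tr$lon[c(1, nrow(tr))], tr$lat[c(1, nrow(tr))],
                    cfg$colony_lonlat[["lon"]], cfg$colony_lonlat[["lat"]])
    expect_true(all(d <= cfg$colony_radius_km))
  }
})

test_that("state frequencies converge to the analytic stationary distribution", {
  cfg <- sim_config(groups = c(f = 4L), trips_per_bird = 25L, seed = 2)
  tr <- simulate_tracks(cfg)
  freq <- table(tr$truth$states) / length(tr$truth$states)
  pi0 <- stationary_distribution(cfg$transition)
  expect_true(length(tr$truth$states) > 5000)
  expect_true(all(abs(as.numeric(freq) - as.numeric(pi0)) < 0.02))
})

test_that("same seed reproduces identical tracks, rasters and isotopes", {
  cfg <- sim_config(groups = c(f = 2L), trips_per_bird = 2L, seed = 123)
  expect_identical(simulate_tracks(cfg), simulate_tracks(cfg))
  e1 <- simulate_environment(months = 2, config = cfg)
  e2 <- simulate_environment(months = 2, config = cfg)
  expect_identical(e1, e2)
  expect_identical(simulate_isotopes(cfg), simulate_isotopes(cfg))
})

test_that("environmental grid has 0.08-degree cells; constant mode is flat", {
  cfg <- sim_config(seed = 5)
  st <- simulate_environment(months = 1, config = cfg)
  expect_equal(diff(st$DEP$lon[1:2]), 0.08)
  expect_equal(diff(st$DEP$lat[1:2]), 0.08)
  flat <- simulate_environment(months = 1, config = cfg, constant = TRUE)
  g <- gradient_pc(flat$SST_01)
  expect_true(all(g$values == 0, na.rm = TRUE))
  expect_error(simulate_environment(months = 0, config = cfg))
})

test_that("prey draws reproduce the printed source moments at large n", {
  cfg <- sim_config(seed = 31)
  iso <- simulate_isotopes(cfg, n_prey = c(epipelagic = 5000, juvenile = 5000,
                                           squid = 5000))
  epi <- iso$prey[iso$prey$group == "epipelagic", ]
  expect_equal(mean(epi$d13C), -16.98, tolerance = 0.02)
  expect_equal(mean(epi$d15N), 10.05, tolerance = 0.02)
  expect_equal(sd(epi$d13C), 0.50, tolerance = 0.05)
})

test_that("noise-free single-source consumers sit exactly at mean plus TEF", {
  src <- default_source_groups()
  src$sd_d13C <- src$sd_d15N <- 0
  cfg <- sim_config(source_groups = src,
                    true_diet = list(g = c(1, 0, 0)),
                    tef = tef(sd_d13C = 0, sd_d15N = 0),
                    isotope_eps = 0, seed = 8)
  iso <- simulate_isotopes(cfg)
  expect_true(all(iso$consumers$d13C == -16.98 - 0.18))
  expect_true(all(iso$consumers$d15N == 10.05 + 1.72))
})

test_that("consumer variance matches the closed form for a pure diet", {
  cfg <- sim_config(true_diet = list(g = c(1, 0, 0)), n_consumers = 20000L,
                    seed = 13)
  iso <- simulate_isotopes(cfg)
  s <- cfg$source_groups[1, ]
  v_expect <- s$sd_d13C^2 + cfg$tef$sd[["d13C"]]^2 + cfg$isotope_eps^2
  expect_equal(var(iso$consumers$d13C), v_expect, tolerance = 0.05)
})

test_that("forward moments follow the mixing equations", {
  src <- default_source_groups()
  p <- c(0.6, 0.3, 0.1)
  mom <- mixing_forward_moments(p, src, tef(), eps = 0.2)
  expect_equal(mom$mean[1], sum(p * (src$mean_d13C - 0.18)))
  expect_equal(mom$var[2], sum(p^2 * (src$sd_d15N^2 + 1)) + 0.04)
})
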