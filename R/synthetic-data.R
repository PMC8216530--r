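# Synthetic tracking, raster and isotope data with the statistical structure
# the downstream analyses assume. The generator stands in for unreleased
# field data: it emulates 5-min central-place foraging trips from Raso Islet,
# monthly oceanographic rasters on a 0.08 degree grid, and plasma isotope
# values produced by the mixing-model forward equations.

# Canonical behavioural state order used throughout: quadrants of the
# (speed, turn) plane. LL rest, LH intensive foraging, HL travel, HH relocate.
STATE_LEVELS <- c("LL", "LH", "HL", "HH")

#' Behavioural quadrant semantics
#'
#' @return named character vector mapping quadrant codes to behaviour names.
#' @export
behaviour_semantics <- function() {
  c(LL = "resting", LH = "intensive_foraging",
    HL = "travelling", HH = "relocating")
}

#' Default prey source groups
#'
#' The three prey groups used in the diet analyses, as muscle-tissue
#' delta13C / delta15N moments: epipelagic fish, juvenile fish (fingerlings
#' of epipelagic species) and squid.
#'
#' @return data.frame with columns `name`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N`, `n`.
#' @export
default_source_groups <- function() {
  data.frame(
    name      = c("epipelagic", "juvenile", "squid"),
    mean_d13C = c(-16.98, -18.47, -17.02),
    sd_d13C   = c(0.50, 0.24, 1.56),
    mean_d15N = c(10.05, 8.38, 11.66),
    sd_d15N   = c(0.78, 0.43, 2.18),
    n         = c(35L, 10L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration shared by the three generators.
#' Defaults encode the study conditions: a colony at Raso Islet, fixes every
#' 5 minutes, four behavioural states with separable kinematics, the three
#' printed prey source groups, and isotope noise at the order of analytic
#' precision (0.2 permil).
#'
#' @param colony_lonlat numeric length-2, colony position (lon, lat).
#' @param fix_interval_min GPS fix interval in minutes (> 0).
#' @param groups named integer vector: birds per group.
#' @param trips_per_bird trips simulated per bird (0 allowed).
#' @param state_speed_mean,state_speed_sd named numeric over LL/LH/HL/HH,
#'   per-state speed distribution in km/h.
#' @param state_turn_sd named numeric, per-state SD of the signed turning
#'   angle in degrees (small = low-turn state).
#' @param transition named 4x4 row-stochastic matrix over states.
#' @param individual_effect_sd SD of the per-bird random effect on log trip
#'   extent (drives between-individual repeatability).
#' @param residual_sd SD of the per-trip residual on log trip extent.
#' @param colony_radius_km radius within which a bird counts as at-colony.
#' @param source_groups data.frame as [default_source_groups()].
#' @param true_diet named list: per consumer group, a simplex over sources.
#' @param n_consumers consumers sampled per group for isotope tables.
#' @param tef trophic discrimination factors, see [tef()].
#' @param isotope_eps residual isotope noise SD in permil.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(colony_lonlat = c(-24.5877, 16.6113),
                       fix_interval_min = 5,
                       groups = c(female = 5L, male = 5L),
                       trips_per_bird = 3L,
                       state_speed_mean = c(LL = 1, LH = 8, HL = 35, HH = 30),
                       state_speed_sd = c(LL = 0.5, LH = 3, HL = 5, HH = 5),
                       state_turn_sd = c(LL = 10, LH = 65, HL = 8, HH = 60),
                       transition = default_transition_matrix(),
                       individual_effect_sd = 0.35,
                       residual_sd = 0.18,
                       colony_radius_km = 1,
                       source_groups = default_source_groups(),
                       true_diet = list(
                         female = c(epipelagic = 0.50, juvenile = 0.30, squid = 0.20),
                         male   = c(epipelagic = 0.40, juvenile = 0.30, squid = 0.30)
                       ),
                       n_consumers = 12L,
                       tef = seaforage::tef(),
                       isotope_eps = 0.2,
                       seed = 1L) {
  stopifnot(length(colony_lonlat) == 2, fix_interval_min > 0,
            trips_per_bird >= 0, colony_radius_km > 0,
            individual_effect_sd >= 0, residual_sd >= 0, isotope_eps >= 0)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named vector of bird counts")
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(4, 4)) ||
      any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0))
    stop("`transition` must be a 4x4 row-stochastic matrix")
  dimnames(transition) <- list(STATE_LEVELS, STATE_LEVELS)
  for (nm in c("state_speed_mean", "state_speed_sd", "state_turn_sd")) {
    v <- get(nm)
    if (!all(STATE_LEVELS %in% names(v))) stop(nm, " must name all of LL/LH/HL/HH")
    if (any(v[STATE_LEVELS] < 0)) stop(nm, " must be non-negative")
  }
  for (p in true_diet) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("each `true_diet` entry must lie on the simplex")
    if (length(p) != nrow(source_groups))
      stop("`true_diet` entries must have one proportion per source group")
  }
  if (any(source_groups$sd_d13C < 0) || any(source_groups$sd_d15N < 0))
    stop("source SDs must be non-negative")
  structure(list(
    colony_lonlat = c(lon = colony_lonlat[[1]], lat = colony_lonlat[[2]]),
    fix_interval_min = fix_interval_min,
    groups = groups, trips_per_bird = as.integer(trips_per_bird),
    state_speed_mean = state_speed_mean[STATE_LEVELS],
    state_speed_sd = state_speed_sd[STATE_LEVELS],
    state_turn_sd = state_turn_sd[STATE_LEVELS],
    transition = transition,
    individual_effect_sd = individual_effect_sd, residual_sd = residual_sd,
    colony_radius_km = colony_radius_km,
    source_groups = source_groups, true_diet = true_diet,
    n_consumers = as.integer(n_consumers), tef = tef,
    isotope_eps = isotope_eps, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default behavioural state transition matrix
#'
#' Row-stochastic over LL (rest), LH (forage), HL (travel), HH (relocate),
#' with moderate state persistence and relocation feeding back into foraging.
#'
#' @return 4x4 matrix.
#' @export
default_transition_matrix <- function() {
  m <- rbind(
    LL = c(0.80, 0.08, 0.10, 0.02),
    LH = c(0.06, 0.80, 0.06, 0.08),
    HL = c(0.06, 0.08, 0.82, 0.04),
    HH = c(0.06, 0.30, 0.14, 0.50)
  )
  colnames(m) <- STATE_LEVELS
  m
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalized to a probability vector.
#'
#' @param transition row-stochastic square matrix.
#' @return named probability vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  setNames(v / sum(v), rownames(transition))
}

# Derive a reproducible sub-seed for one module from the master seed.
module_seed <- function(seed, k) {
  (as.integer(seed) + 99991L * as.integer(k)) %% 2147483647L
}

#' Simulate central-place foraging GPS tracks
#'
#' State-switching correlated random walk: per fix, a behavioural state from
#' a Markov chain (initialized at its stationary distribution), a speed drawn
#' from the state's normal, and a heading updated by the state's wrapped
#' turning distribution. After a bird-specific outbound phase the heading is
#' attracted towards the colony with a weight growing in time, so every trip
#' starts and ends within the colony radius.
#'
#' @param config a [sim_config()].
#' @return list with `fixes` (data.frame: bird_id, group, trip_id, timestamp,
#'   lon, lat) and `truth` (per-fix generating state plus per-bird effects
#'   and per-group true diets).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(module_seed(config$seed, 1L))
  colony <- config$colony_lonlat
  dt_h <- config$fix_interval_min / 60
  pi0 <- stationary_distribution(config$transition)
  empty <- data.frame(bird_id = character(), group = character(),
                      trip_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(),
                      stringsAsFactors = FALSE)
  fixes <- list(); states <- list(); bird_effects <- list()
  t0 <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  bird_no <- 0L
  for (g in names(config$groups)) {
    for (b in seq_len(config$groups[[g]])) {
      bird_no <- bird_no + 1L
      bird_id <- sprintf("%s_%02d", g, b)
      eff <- rnorm(1, 0, config$individual_effect_sd)
      bird_effects[[bird_id]] <- eff
      t_cur <- t0 + (bird_no - 1L) * 86400
      for (tr in seq_len(config$trips_per_bird)) {
        trip_id <- sprintf("%s_t%02d", bird_id, tr)
        outbound <- max(6L, round(24 * exp(eff + rnorm(1, 0, config$residual_sd))))
        sim <- simulate_one_trip(config, colony, outbound, pi0, dt_h)
        n <- nrow(sim$fixes)
        fixes[[trip_id]] <- data.frame(
          bird_id = bird_id, group = g, trip_id = trip_id,
          timestamp = t_cur + (seq_len(n) - 1L) * config$fix_interval_min * 60,
          lon = sim$fixes$lon, lat = sim$fixes$lat,
          stringsAsFactors = FALSE)
        states[[trip_id]] <- sim$states
        # at-colony gap before the next departure, kept on the fix raster
        gap_min <- config$fix_interval_min *
          (n + round(runif(1, 24, 60)))
        t_cur <- t_cur + gap_min * 60
      }
    }
  }
  if (!length(fixes)) {
    return(list(fixes = empty,
                truth = list(states = character(),
                             bird_effects = unlist(bird_effects),
                             true_diet = config$true_diet,
                             stationary = pi0)))
  }
  out <- do.call(rbind, fixes)
  rownames(out) <- NULL
  list(fixes = out,
       truth = list(states = factor(unlist(states), levels = STATE_LEVELS),
                    bird_effects = unlist(bird_effects),
                    true_diet = config$true_diet,
                    stationary = pi0))
}

# One trip: returns fixes (lon/lat) and the generating state per fix.
simulate_one_trip <- function(config, colony, outbound, pi0, dt_h) {
  max_steps <- 2000L
  lon <- colony[["lon"]]; lat <- colony[["lat"]]
  heading <- runif(1, 0, 360)
  s <- sample(STATE_LEVELS, 1, prob = pi0)
  lons <- lon; lats <- lat; sts <- s   # first fix at the colony
  for (i in seq_len(max_steps)) {
    sp <- max(rnorm(1, config$state_speed_mean[[s]], config$state_speed_sd[[s]]), 0.05)
    turn <- rnorm(1, 0, config$state_turn_sd[[s]])
    heading <- (heading + turn) %% 360
    if (i > outbound) {
      w <- min(1, (i - outbound) / max(1, 0.6 * outbound))
      home <- gc_bearing(lon, lat, colony[["lon"]], colony[["lat"]])
      delta <- (home - heading + 180) %% 360 - 180
      heading <- (heading + w * delta) %% 360
      # make the return phase brisk so trips close even from rest states
      if (w >= 1) sp <- max(sp, config$state_speed_mean[["HL"]] * 0.6)
    }
    p <- advance_point(lon, lat, heading, sp * dt_h)
    lon <- p[[1]]; lat <- p[[2]]
    lons <- c(lons, lon); lats <- c(lats, lat); sts <- c(sts, s)
    if (i > outbound &&
        gc_dist_km(lon, lat, colony[["lon"]], colony[["lat"]]) <= config$colony_radius_km)
      break
    s <- sample(STATE_LEVELS, 1, prob = config$transition[s, ])
  }
  list(fixes = data.frame(lon = lons, lat = lats), states = sts)
}

#' Simulate monthly environmental rasters
#'
#' One static depth layer (positive metres) plus monthly SST, CHLA, SSH and
#' OMLT layers on a 0.08 degree grid. Fields are sums of low-order spatial
#' harmonics with a seasonal drift and a small noise term, so moving-window
#' gradients are non-trivial. Same seed, same rasters.
#'
#' @param extent numeric length-4: lonmin, lonmax, latmin, latmax.
#' @param months number of monthly layers per dynamic variable.
#' @param config a [sim_config()]; supplies the seed.
#' @param res grid resolution in degrees.
#' @param constant if TRUE every layer is spatially constant (gradients are
#'   then zero everywhere downstream).
#' @return named list of [env_raster] layers: `DEP` plus `VAR_mm` per month;
#'   class `env_stack`.
#' @export
simulate_environment <- function(extent = NULL, months = 12, config = sim_config(),
                                 res = 0.08, constant = FALSE) {
  if (months < 1) stop("`months` must be >= 1")
  if (is.null(extent)) {
    extent <- c(config$colony_lonlat[["lon"]] - 2, config$colony_lonlat[["lon"]] + 2,
                config$colony_lonlat[["lat"]] - 2, config$colony_lonlat[["lat"]] + 2)
  }
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent")
  lon <- grid_centers(extent[1], extent[2], res)
  lat <- grid_centers(extent[3], extent[4], res)
  specs <- list(
    DEP  = list(base = 3000, amp = 1200, lo = 10,   hi = Inf, static = TRUE),
    SST  = list(base = 24,   amp = 1.8,  lo = -Inf, hi = Inf, static = FALSE),
    CHLA = list(base = 0.18, amp = 0.10, lo = 0.01, hi = Inf, static = FALSE),
    SSH  = list(base = 0.35, amp = 0.15, lo = -Inf, hi = Inf, static = FALSE),
    OMLT = list(base = 45,   amp = 18,   lo = 5,    hi = Inf, static = FALSE)
  )
  out <- list()
  k <- 10L
  for (v in names(specs)) {
    sp <- specs[[v]]
    n_m <- if (sp$static) 1L else as.integer(months)
    for (m in seq_len(n_m)) {
      k <- k + 1L
      set.seed(module_seed(config$seed, k))
      vals <- if (constant) {
        matrix(sp$base, nrow = length(lat), ncol = length(lon))
      } else {
        harmonic_field(lon, lat, sp$base, sp$amp,
                       season = if (sp$static) 0 else sin(2 * pi * m / 12))
      }
      vals <- pmin(pmax(vals, sp$lo), sp$hi)
      nm <- if (sp$static) v else sprintf("%s_%02d", v, m)
      out[[nm]] <- env_raster(vals, lon, lat, var = v,
                              month = if (sp$static) NA_integer_ else m)
    }
  }
  structure(out, class = "env_stack")
}

# Smooth random field: low-order sinusoids + mild noise, on cell centers.
harmonic_field <- function(lon, lat, base, amp, season = 0) {
  G <- expand.grid(lon = lon, lat = lat)
  f <- rep(base * (1 + 0.05 * season), nrow(G))
  for (j in 1:3) {
    fr <- runif(2, 0.3, 1.6)       # cycles per degree
    ph <- runif(1, 0, 2 * pi)
    a <- amp * runif(1, 0.3, 1) / j
    f <- f + a * sin(2 * pi * (fr[1] * G$lon + fr[2] * G$lat) + ph)
  }
  f <- f + rnorm(nrow(G), 0, amp * 0.02)
  matrix(f, nrow = length(lat), ncol = length(lon), byrow = TRUE)
}

# Cell-center sequence on a grid registered to multiples of `res`.
grid_centers <- function(lo, hi, res) {
  start <- (floor(lo / res) + 0.5) * res
  seq(start, hi, by = res)
}

#' Simulate consumer and prey isotope tables
#'
#' Prey samples are drawn from each source group's normal moments. Consumer
#' plasma values follow the mixing-model forward equations for the group's
#' true diet p: mean_j = sum_k p_k (mu_kj + c_j) and
#' variance_j = sum_k p_k^2 (sigma_kj^2 + sigma_cj^2) + eps^2, where c is the
#' trophic discrimination factor.
#'
#' @param config a [sim_config()].
#' @param n_prey optional named vector overriding per-source prey sample sizes.
#' @return list with `consumers`, `prey` (data.frames) and `truth`.
#' @export
simulate_isotopes <- function(config, n_prey = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(module_seed(config$seed, 2L))
  src <- config$source_groups
  nk <- if (is.null(n_prey)) setNames(src$n, src$name) else n_prey
  prey <- do.call(rbind, lapply(seq_len(nrow(src)), function(k) {
    n <- nk[[src$name[k]]]
    data.frame(group = src$name[k],
               d13C = rnorm(n, src$mean_d13C[k], src$sd_d13C[k]),
               d15N = rnorm(n, src$mean_d15N[k], src$sd_d15N[k]),
               stringsAsFactors = FALSE)
  }))
  consumers <- do.call(rbind, lapply(names(config$true_diet), function(g) {
    p <- config$true_diet[[g]]
    mom <- mixing_forward_moments(p, src, config$tef, config$isotope_eps)
    n <- config$n_consumers
    data.frame(individual = sprintf("%s_%02d", g, seq_len(n)), group = g,
               d13C = rnorm(n, mom$mean[1], sqrt(mom$var[1])),
               d15N = rnorm(n, mom$mean[2], sqrt(mom$var[2])),
               stringsAsFactors = FALSE)
  }))
  rownames(prey) <- rownames(consumers) <- NULL
  list(consumers = consumers, prey = prey,
       truth = list(true_diet = config$true_diet))
}

#' Forward moments of the mixing model
#'
#' @param p simplex of diet proportions over sources.
#' @param sources source-group data.frame (see [default_source_groups()]).
#' @param tef discrimination factors, see [tef()].
#' @param eps residual SD in permil (scalar or length 2).
#' @return list with `mean` and `var`, each length 2 (d13C, d15N).
#' @export
mixing_forward_moments <- function(p, sources, tef = seaforage::tef(), eps = 0) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  eps <- rep_len(eps, 2)
  mu <- cbind(sources$mean_d13C + tef$mean[1], sources$mean_d15N + tef$mean[2])
  s2 <- cbind(sources$sd_d13C^2 + tef$sd[1]^2, sources$sd_d15N^2 + tef$sd[2]^2)
  list(mean = as.numeric(p %*% mu),
       var = as.numeric((p^2) %*% s2) + eps^2)
}
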