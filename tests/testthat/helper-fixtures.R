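# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Step features drawn at the four quadrant archetypes (well separated).
make_quadrant_steps <- function(n_per = 400, seed = 1) {
  set.seed(seed)
  gen <- function(n, sp_m, sp_s, t_m, t_s) data.frame(
    speed_kmh = pmax(rnorm(n, sp_m, sp_s), 0.05),
    turn_rad = pmin(pmax(rnorm(n, t_m, t_s), 0), pi))
  f <- rbind(gen(n_per, 1, 0.3, 0.10, 0.05),
             gen(n_per, 8, 2.0, 2.20, 0.30),
             gen(n_per, 35, 4.0, 0.10, 0.05),
             gen(n_per, 30, 4.0, 2.20, 0.30))
  list(features = f, truth = rep(c("LL", "LH", "HL", "HH"), each = n_per))
}

# Clustered foraging points around one or two centers.
make_points <- function(n = 100, center = c(-24.5, 16.6), spread = 0.2,
                        seed = 1) {
  set.seed(seed)
  data.frame(lon = rnorm(n, center[1], spread),
             lat = rnorm(n, center[2], spread))
}

# Multi-individual two-group foraging point sets for the overlap test.
# `shift` displaces group B's center (0 = exchangeable null).
make_group_points <- function(n_birds = 4, n_pts = 25, shift = 0, seed = 1,
                              spread = 0.15) {
  set.seed(seed)
  rows <- list()
  for (g in c("A", "B")) for (b in seq_len(n_birds)) {
    cx <- if (g == "B") shift else 0
    cen <- c(-24.5 + cx + rnorm(1, 0, 0.05), 16.6 + rnorm(1, 0, 0.05))
    rows[[paste(g, b)]] <- data.frame(
      lon = rnorm(n_pts, cen[1], spread), lat = rnorm(n_pts, cen[2], spread),
      bird_id = sprintf("%s%02d", g, b), group = g,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# A hand-built trip data.frame at 5-min intervals along given lon/lat.
make_trip <- function(lon, lat, start = "2019-06-01 00:00:00") {
  data.frame(
    bird_id = "b1", trip_id = "b1_T01",
    timestamp = as.POSIXct(start, tz = "UTC") + 300 * (seq_along(lon) - 1),
    lon = lon, lat = lat, stringsAsFactors = FALSE)
}

# Independent spherical law-of-cosines distance oracle (km).
slc_dist_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  6371 * acos(pmin(1, pmax(-1,
    sin(lat1 * r) * sin(lat2 * r) +
      cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r))))
}

# Naive Gaussian-mixture density oracle for the kernel UD.
naive_ud <- function(points, grid, h) {
  out <- matrix(0, length(grid$lat), length(grid$lon))
  for (i in seq_along(grid$lat)) for (j in seq_along(grid$lon)) {
    s <- 0
    for (p in seq_len(nrow(points))) {
      s <- s + exp(-0.5 * ((points$lon[p] - grid$lon[j])^2 +
                             (points$lat[p] - grid$lat[i])^2) / h^2)
    }
    out[i, j] <- s
  }
  out / sum(out)
}

# Simulated repeatability data: k individuals x m trips.
make_repeat_data <- function(k = 200, m = 20, sd_ind = 1, sd_res = 1, seed = 1) {
  set.seed(seed)
  data.frame(id = rep(seq_len(k), each = m),
             value = rep(rnorm(k, 0, sd_ind), each = m) + rnorm(k * m, 0, sd_res))
}
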