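# Raster gradients, regridding, extraction, VIF screening, ASCII-grid I/O.

make_raster <- function(v, res = 0.1, var = "X") {
  env_raster(v, lon = res * (seq_len(ncol(v)) - 0.5),
             lat = res * (seq_len(nrow(v)) - 0.5), var = var)
}

test_that("a constant raster has zero gradient everywhere", {
  r <- make_raster(matrix(7, 6, 8))
  g <- gradient_pc(r)
  expect_true(all(g$values == 0))
  expect_equal(g$var, "GX")
})

test_that("a 0..8 window gives PC = 100 at its center", {
  r <- make_raster(matrix(0:8, 3, 3))
  g <- gradient_pc(r)
  expect_identical(g$values[2, 2], 100)
})

test_that("gradients match a naive nested-loop window oracle", {
  set.seed(1)
  v <- matrix(runif(12 * 9, 1, 10), 9, 12)
  v[3, 4] <- NA
  g <- gradient_pc(make_raster(v))
  naive <- matrix(NA_real_, 9, 12)
  for (i in 1:9) for (j in 1:12) {
    w <- v[max(1, i - 1):min(9, i + 1), max(1, j - 1):min(12, j + 1)]
    w <- w[!is.na(w)]
    if (length(w) && max(w) > 0) naive[i, j] <- (max(w) - min(w)) * 100 / max(w)
  }
  expect_equal(g$values, naive, tolerance = 1e-12)
})

test_that("non-positive window maxima are masked; offset mode recovers them", {
  v <- matrix(c(-3, -1, -2, -5), 2, 2)
  g <- gradient_pc(make_raster(v))
  expect_true(all(is.na(g$values)))
  g2 <- gradient_pc(make_raster(v), offset = TRUE)
  expect_true(all(is.finite(g2$values)))
  expect_true(all(g2$values >= 0 & g2$values <= 100))
})

test_that("PC lies in [0, 100] for non-negative fields", {
  set.seed(2)
  g <- gradient_pc(make_raster(matrix(runif(80, 0, 5), 8, 10)))
  ok <- !is.na(g$values)
  expect_true(all(g$values[ok] >= 0 & g$values[ok] <= 100))
})

test_that("regrid to the source grid is the identity", {
  set.seed(3)
  r <- make_raster(matrix(rnorm(48), 6, 8), res = 0.08)
  r2 <- regrid(r, target = list(lon = r$lon, lat = r$lat))
  expect_identical(r2$values, r$values)
})

test_that("block-mean coarsening conserves the domain mean of complete data", {
  set.seed(4)
  r <- make_raster(matrix(rnorm(40 * 40), 40, 40), res = 0.02)
  r2 <- regrid(r, target_res = 0.08)
  expect_equal(diff(r2$lon[1:2]), 0.08)
  expect_equal(mean(r2$values), mean(r$values), tolerance = 1e-12)
})

test_that("refining interpolates smoothly between cell centers", {
  v <- outer(1:10, 1:12, function(i, j) i + 2 * j)
  r <- make_raster(v, res = 0.16)
  r2 <- regrid(r, target_res = 0.08)
  # the field is affine in lon/lat, so bilinear refinement is exact away
  # from the clamped border
  inner_lat <- r2$lat > min(r$lat) & r2$lat < max(r$lat)
  inner_lon <- r2$lon > min(r$lon) & r2$lon < max(r$lon)
  expected <- outer(r2$lat[inner_lat] / 0.16 + 0.5,
                    r2$lon[inner_lon] / 0.16 + 0.5,
                    function(i, j) i + 2 * j)
  expect_equal(r2$values[inner_lat, inner_lon], expected, tolerance = 1e-9)
})

test_that("extraction returns exact values at cell centers and NA outside", {
  cfg <- sim_config(seed = 6)
  st <- simulate_environment(months = 2, config = cfg)
  r <- st$SST_01
  fx <- data.frame(lon = r$lon[c(3, 10)], lat = r$lat[c(5, 2)],
                   timestamp = as.POSIXct("2019-01-15 12:00:00", tz = "UTC"))
  out <- extract_at(fx, st)
  expect_equal(out$SST, c(r$values[5, 3], r$values[2, 10]))
  far <- data.frame(lon = 50, lat = -40,
                    timestamp = as.POSIXct("2019-01-15", tz = "UTC"))
  expect_warning(out2 <- extract_at(far, st), "outside")
  expect_true(is.na(out2$SST))
})

test_that("a constant layer extracts to a constant column", {
  cfg <- sim_config(seed = 7)
  st <- simulate_environment(months = 1, config = cfg, constant = TRUE)
  fx <- data.frame(lon = runif(20, -26, -23), lat = runif(20, 15, 18),
                   timestamp = as.POSIXct("2019-01-10", tz = "UTC"))
  out <- extract_at(fx, st)
  expect_equal(length(unique(out$OMLT)), 1)
})

test_that("VIF screening keeps orthogonal covariates with VIF 1", {
  set.seed(8)
  X <- qr.Q(qr(matrix(rnorm(200 * 4), 200, 4)))
  X <- scale(X, center = TRUE, scale = FALSE)   # orthogonal to the intercept
  df <- as.data.frame(X); names(df) <- c("a", "b", "c", "d")
  v <- vif_screen(df)
  expect_setequal(v$retained, c("a", "b", "c", "d"))
  expect_true(all(v$vif < 1.05))
})

test_that("a duplicated column is dropped exactly once", {
  set.seed(9)
  df <- data.frame(a = rnorm(50), b = rnorm(50))
  df$a_copy <- df$a
  v <- vif_screen(df)
  expect_length(v$dropped, 1)
  expect_true(v$dropped %in% c("a", "a_copy"))
  expect_length(v$retained, 2)
})

test_that("VIF screening result does not depend on column order", {
  set.seed(10)
  n <- 120
  z <- rnorm(n)
  df <- data.frame(x1 = z + rnorm(n, 0, 0.1), x2 = z + rnorm(n, 0, 0.1),
                   x3 = rnorm(n), x4 = z + rnorm(n, 0, 0.1))
  v1 <- vif_screen(df)
  v2 <- vif_screen(df[, c(3, 1, 4, 2)])
  expect_identical(v1$retained, v2$retained)
  expect_identical(v1$dropped, v2$dropped)
})

test_that("default VIF threshold is 3", {
  expect_identical(formals(vif_screen)$threshold, 3)
})

test_that("ASCII grid files round-trip values, grid and missing cells", {
  set.seed(11)
  v <- matrix(rnorm(30), 5, 6); v[2, 3] <- NA
  r <- make_raster(v, res = 0.08, var = "SST")
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(r, p, digits = 12)
  r2 <- read_ascii_grid(p, var = "SST")
  expect_equal(r2$values, r$values, tolerance = 1e-10)
  expect_equal(r2$lon, r$lon, tolerance = 1e-10)
  expect_equal(r2$lat, r$lat, tolerance = 1e-10)
  unlink(p)
})
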