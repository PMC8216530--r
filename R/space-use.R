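# Kernel utilization distributions on the 0.08 degree analysis grid,
# isopleths, Bhattacharyya-affinity overlap, and the individual-level
# randomization test of spatial segregation.
#
# Kernels are geographic (unprojected) bivariate Gaussians in degrees. At
# the study latitude (~16.6 N) a degree of longitude is ~4% shorter than a
# degree of latitude times cos(lat); `equirect` optionally rescales
# longitudes by cos(mean latitude) before smoothing to remove that
# anisotropy.

#' Build a UD analysis grid
#'
#' Cell centers registered to multiples of `res` (matching the
#' environmental grid), covering the points plus a margin.
#'
#' @param points data.frame/matrix with lon, lat columns.
#' @param res cell size in degrees.
#' @param margin margin around the point extent, degrees.
#' @return list with `lon`, `lat` center vectors and `res`.
#' @export
ud_grid <- function(points, res = 0.08, margin = 0.5) {
  lon <- points[["lon"]]; lat <- points[["lat"]]
  list(lon = grid_centers(min(lon) - margin, max(lon) + margin, res),
       lat = grid_centers(min(lat) - margin, max(lat) + margin, res),
       res = res)
}

#' Fit a kernel utilization distribution
#'
#' Bivariate Gaussian kernel density with a single bandwidth `h` (degrees)
#' evaluated at the grid cell centers and normalized to unit total mass
#' over the grid.
#'
#' @param points data.frame with lon, lat (foraging locations).
#' @param grid grid from [ud_grid()]; defaults to one built on the points.
#' @param h kernel bandwidth in degrees (> 0).
#' @param equirect if TRUE, rescale longitudes by cos(mean lat) before
#'   smoothing (isotropic kernels in km rather than degrees).
#' @return object of class `ud` with `mass` (matrix lat x lon), the grid
#'   and `h`.
#' @export
fit_kernel_ud <- function(points, grid = NULL, h, equirect = FALSE) {
  stopifnot(h > 0)
  if (nrow(points) < 5) stop("need at least 5 points for a kernel UD")
  if (is.null(grid)) grid <- ud_grid(points)
  sx <- if (equirect) cos(mean(points$lat) * pi / 180) else 1
  klon <- exp(-0.5 * (outer(points$lon * sx, grid$lon * sx, "-") / h)^2)
  klat <- exp(-0.5 * (outer(points$lat, grid$lat, "-") / h)^2)
  dens <- t(crossprod(klon, klat))   # lat x lon
  tot <- sum(dens)
  if (tot <= 0) stop("all points fall outside the grid extent")
  structure(list(mass = dens / tot, lon = grid$lon, lat = grid$lat,
                 res = grid$res, h = h, equirect = equirect, n = nrow(points)),
            class = "ud")
}

#' Least-squares cross-validation bandwidth
#'
#' Minimizes the LSCV score CV(h) = int f-hat^2 - (2/n) sum_i f-hat_{-i}(x_i)
#' (closed form for Gaussian kernels) over a log-scale bracket around the
#' bivariate normal reference bandwidth. If the score is monotone on the
#' bracket (the classic LSCV degeneracy with duplicated points), the
#' reference bandwidth is returned with attribute `degenerate = TRUE`.
#'
#' @param points data.frame with lon, lat; at least 10 rows.
#' @param bracket multiplicative half-width of the search bracket.
#' @return bandwidth in degrees, with attributes `score` and `degenerate`.
#' @export
lscv_bandwidth <- function(points, bracket = 8) {
  n <- nrow(points)
  if (n < 10) stop("need at least 10 points for LSCV")
  dx <- outer(points$lon, points$lon, "-")
  dy <- outer(points$lat, points$lat, "-")
  d2 <- dx^2 + dy^2
  if (all(d2 == 0)) stop("degenerate input: all points identical")
  off <- d2[row(d2) != col(d2)]
  score <- function(h) {
    t1 <- sum(exp(-d2 / (4 * h^2))) / (4 * pi * h^2 * n^2)
    t2 <- sum(exp(-off / (2 * h^2))) / (2 * pi * h^2 * n * (n - 1))
    t1 - 2 * t2 + 0 # int f^2 minus twice the leave-one-out mean
  }
  h_ref <- reference_bandwidth(points)
  opt <- optimize(function(lh) score(exp(lh)),
                  interval = log(c(h_ref / bracket, h_ref * bracket)), tol = 1e-6)
  h <- exp(opt$minimum)
  degen <- h <= h_ref / bracket * 1.05 || h >= h_ref * bracket * 0.95
  if (degen) {
    h <- h_ref
    warning("LSCV score monotone on bracket; falling back to reference bandwidth")
  }
  structure(h, score = score(h), degenerate = degen)
}

#' Bivariate normal reference bandwidth
#'
#' h = sigma * n^(-1/6) with sigma the root mean of the two marginal
#' variances — the 2-D normal-reference rule.
#'
#' @param points data.frame with lon, lat.
#' @return bandwidth in degrees.
#' @export
reference_bandwidth <- function(points) {
  s <- sqrt((var(points$lon) + var(points$lat)) / 2)
  s * nrow(points)^(-1 / 6)
}

#' Isopleth cell set of a UD
#'
#' Smallest set of highest-mass cells whose cumulative mass first reaches
#' `level`; cells tied with the last included mass are included together.
#' 50% is read as the core foraging region (FR), 95% as the home range (HR).
#'
#' @param ud a [fit_kernel_ud()] object.
#' @param level fraction of UD mass in (0, 1].
#' @return logical matrix (lat x lon) with attribute `enclosed_mass`.
#' @export
isopleth <- function(ud, level) {
  stopifnot(level > 0, level <= 1)
  m <- as.vector(ud$mass)
  if (level == 1) {           # full support: every cell with positive mass
    sel <- matrix(m > 0, nrow(ud$mass), ncol(ud$mass))
    attr(sel, "enclosed_mass") <- sum(m[m > 0])
    return(sel)
  }
  o <- order(m, decreasing = TRUE)
  cs <- cumsum(m[o])
  k <- which(cs >= level - 1e-12)[1]
  thr <- m[o[k]]
  inc <- m >= thr & m > 0
  sel <- matrix(inc, nrow(ud$mass), ncol(ud$mass))
  attr(sel, "enclosed_mass") <- sum(m[inc])
  sel
}

#' Bhattacharyya affinity between two UDs
#'
#' BA = sum over cells of sqrt(p1 * p2); 0 = no overlap, 1 = identical
#' distributions. With `level` given, each UD is first restricted to its own
#' isopleth cell set and renormalized (so the FR and HR comparisons differ);
#' with `level = NULL` the full UDs are compared.
#'
#' @param ud1,ud2 UDs on the same grid.
#' @param level isopleth level, or NULL for full-UD affinity.
#' @return BA index in \[0, 1\].
#' @export
ba_overlap <- function(ud1, ud2, level = NULL) {
  if (!isTRUE(all.equal(ud1$lon, ud2$lon)) || !isTRUE(all.equal(ud1$lat, ud2$lat)))
    stop("UDs must share the same grid")
  p1 <- ud1$mass; p2 <- ud2$mass
  if (!is.null(level)) {
    s1 <- isopleth(ud1, level); s2 <- isopleth(ud2, level)
    p1 <- p1 * s1; p2 <- p2 * s2
    p1 <- p1 / sum(p1); p2 <- p2 / sum(p2)
  }
  sum(sqrt(p1 * p2))
}

#' Randomization test of space-use overlap
#'
#' Observed BA between the two groups' UDs, against a null built by
#' reassigning whole individuals (all their locations together) to groups
#' with group sizes preserved, recomputing both UDs and the BA with the same
#' bandwidth and grid. The p-value is the proportion of permuted BA values
#' strictly below the observed one (low p = less overlap than expected by
#' chance, i.e. segregation).
#'
#' @param points data.frame with bird_id, group (two levels), lon, lat —
#'   typically intensive-foraging fixes.
#' @param level isopleth level for the BA (0.50 FR or 0.95 HR).
#' @param h bandwidth (degrees); one value reused for every UD.
#' @param grid shared grid; defaults to one built on all points.
#' @param n_perm number of randomizations.
#' @param seed integer seed.
#' @param unit exchangeable unit: "individual" (default; trips within a bird
#'   are autocorrelated) or "point" for a sensitivity check.
#' @return object of class `overlap_result`: observed BA, permuted BA
#'   vector, p-value, level.
#' @export
ud_permutation_test <- function(points, level = 0.95, h, grid = NULL,
                                n_perm = 1000, seed = 1,
                                unit = c("individual", "point")) {
  unit <- match.arg(unit)
  if (n_perm < 1) stop("n_perm must be >= 1")
  groups <- unique(points$group)
  if (length(groups) != 2) stop("exactly two groups required")
  if (is.null(grid)) grid <- ud_grid(points)
  birds <- unique(points[, c("bird_id", "group")])
  if (any(table(birds$group) < 2)) stop("need >= 2 individuals per group")
  fit_pair <- function(assign_g) {
    uds <- lapply(groups, function(g) {
      ids <- birds$bird_id[assign_g == g]
      fit_kernel_ud(points[points$bird_id %in% ids, , drop = FALSE], grid, h)
    })
    ba_overlap(uds[[1]], uds[[2]], level)
  }
  observed <- fit_pair(birds$group)
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(i) {
    if (unit == "individual") {
      fit_pair(sample(birds$group))
    } else {
      pts <- points; pts$group <- sample(points$group)
      uds <- lapply(groups, function(g)
        fit_kernel_ud(pts[pts$group == g, , drop = FALSE], grid, h))
      ba_overlap(uds[[1]], uds[[2]], level)
    }
  }, numeric(1))
  structure(list(observed_BA = observed, permuted_BA = permuted,
                 p_value = mean(permuted < observed), level = level,
                 n_perm = n_perm, seed = seed, h = h, groups = groups),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("BA overlap at %.0f%% UD: observed %.3f, permuted %.3f +/- %.3f, p = %.3f (n_perm = %d)\n",
              100 * x$level, x$observed_BA, mean(x$permuted_BA),
              sd(x$permuted_BA), x$p_value, x$n_perm))
  invisible(x)
}

#' Convert a UD to an environmental raster layer
#'
#' @param ud a [fit_kernel_ud()] object.
#' @return an [env_raster] holding the UD mass (useful for ASCII-grid export).
#' @export
ud_as_raster <- function(ud) {
  env_raster(ud$mass, ud$lon, ud$lat, var = "UD", month = NA_integer_)
}
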