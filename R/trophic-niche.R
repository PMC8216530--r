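# Body condition, Layman community metrics, and standard-ellipse isotopic
# niche areas with a Bayesian variant and pairwise ellipse overlaps.

#' Body condition index
#'
#' Residuals of the ordinary least-squares regression of body mass on wing
#' length (a structural-size proxy), fitted per group: positive BCI = heavier
#' than expected for structural size.
#'
#' @param mass_g body mass in grams.
#' @param wing_mm wing length in mm.
#' @param group optional grouping (e.g. species); one regression per group.
#' @return object of class `bci`: data.frame with `bci` residuals plus the
#'   per-group slope/intercept.
#' @export
body_condition_index <- function(mass_g, wing_mm, group = NULL) {
  stopifnot(length(mass_g) == length(wing_mm), all(mass_g > 0), all(wing_mm > 0))
  if (is.null(group)) group <- rep("all", length(mass_g))
  group <- as.character(group)
  bci <- rep(NA_real_, length(mass_g))
  coefs <- list()
  for (g in unique(group)) {
    i <- group == g
    if (sum(i) < 3) stop("need at least 3 birds per fitted group: ", g)
    if (var(wing_mm[i]) == 0) stop("zero wing-length variance in group: ", g)
    fit <- lm(mass_g[i] ~ wing_mm[i])
    bci[i] <- resid(fit)
    coefs[[g]] <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  }
  structure(list(
    table = data.frame(group = group, mass_g = mass_g, wing_mm = wing_mm, bci = bci),
    coefficients = coefs), class = "bci")
}

#' Layman community metrics of an isotope sample
#'
#' The six community-level niche descriptors on the d13C-d15N bi-plot:
#' carbon range (CR), nitrogen range (NR), convex-hull total area (TA),
#' mean distance to centroid (CD), mean nearest-neighbour distance (NND)
#' and its SD (SDNND). Nearest-neighbour distances exclude self.
#'
#' @param d13C,d15N isotope values in permil.
#' @return named numeric vector CR, NR, TA, CD, NND, SDNND.
#' @export
layman_metrics <- function(d13C, d15N) {
  stopifnot(length(d13C) == length(d15N), length(d13C) >= 2,
            all(is.finite(d13C)), all(is.finite(d15N)))
  P <- cbind(d13C, d15N)
  cr <- max(d13C) - min(d13C)
  nr <- max(d15N) - min(d15N)
  ta <- if (nrow(unique(P)) >= 3) convex_hull_area(P) else 0
  cen <- colMeans(P)
  cd <- mean(sqrt(rowSums(sweep(P, 2, cen)^2)))
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  nnd <- apply(D, 1, min)
  if (all(nnd == 0)) warning("duplicate-only data: nearest-neighbour distances are 0")
  c(CR = cr, NR = nr, TA = ta, CD = cd, NND = mean(nnd), SDNND = sd(nnd))
}

# Convex hull area by the shoelace formula on the chull vertices.
convex_hull_area <- function(P) {
  h <- chull(P)
  x <- P[h, 1]; y <- P[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Standard ellipse of a bivariate isotope sample
#'
#' The 1-sigma ellipse of the sample covariance: area SEA = pi * sqrt(l1*l2)
#' with l the covariance eigenvalues, centered at the mean with axes along
#' the eigenvectors. For a bivariate normal this ellipse has ~39.35%
#' probability of containing a subsequently sampled datum (the "40%"
#' standard ellipse). SEAc = SEA * (n-1)/(n-2) corrects small-sample bias.
#'
#' @param d13C,d15N isotope values in permil (n >= 3).
#' @return object of class `standard_ellipse`: SEA, SEAc, center,
#'   semi-axes `a`, `b` (permil), rotation matrix `axes`, `n`.
#' @export
standard_ellipse <- function(d13C, d15N) {
  n <- length(d13C)
  stopifnot(n >= 3, length(d15N) == n)
  S <- cov(cbind(d13C, d15N))
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 0) stop("singular covariance: ellipse undefined")
  sea <- pi * sqrt(prod(e$values))
  structure(list(SEA = sea, SEAc = sea * (n - 1) / (n - 2),
                 center = c(d13C = mean(d13C), d15N = mean(d15N)),
                 a = sqrt(e$values[1]), b = sqrt(e$values[2]),
                 axes = e$vectors, cov = S, n = n),
            class = "standard_ellipse")
}

#' Test points against a standard ellipse
#'
#' @param ellipse a [standard_ellipse()].
#' @param d13C,d15N points to test.
#' @param scale Mahalanobis radius of the ellipse boundary (1 = the
#'   standard ellipse).
#' @return logical: inside (or on) the ellipse.
#' @export
in_ellipse <- function(ellipse, d13C, d15N, scale = 1) {
  X <- cbind(d13C - ellipse$center[[1]], d15N - ellipse$center[[2]])
  md2 <- rowSums((X %*% solve(ellipse$cov)) * X)
  md2 <= scale^2
}

#' Bayesian standard ellipse area
#'
#' Posterior of the covariance under a conjugate normal-inverse-Wishart
#' prior (weakly informative: nu0 = 3, kappa0 = 1, prior scale = sample
#' covariance, prior mean = sample mean); each posterior covariance draw
#' yields an area draw pi * sqrt(l1*l2).
#'
#' @param d13C,d15N isotope values (n >= 4).
#' @param n_draws posterior draws.
#' @param seed integer seed.
#' @return object of class `sea_b`: numeric vector `draws` of areas
#'   (permil^2) plus the point SEAc for reference.
#' @export
sea_bayes <- function(d13C, d15N, n_draws = 4000, seed = 1) {
  n <- length(d13C)
  stopifnot(n >= 4, length(d15N) == n)
  set.seed(seed)
  X <- cbind(d13C, d15N)
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2, xbar))      # sum of squares, (n-1) * cov
  nu0 <- 3; kappa0 <- 1
  Lambda0 <- cov(X)
  if (min(eigen(Lambda0, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("singular sample covariance")
  # prior mean at the sample mean, so the NIW cross term vanishes
  Lambda_n <- Lambda0 + S
  nu_n <- nu0 + n
  W <- rWishart(n_draws, df = nu_n, Sigma = solve(Lambda_n))
  draws <- vapply(seq_len(n_draws), function(i) {
    Sigma <- solve(W[, , i])
    pi * sqrt(det(Sigma))
  }, numeric(1))
  se <- standard_ellipse(d13C, d15N)
  structure(list(draws = draws, SEAc = se$SEAc, n = n), class = "sea_b")
}

#' Probability that one group's niche is narrower
#'
#' Fraction of paired posterior draws with SEA_B(A) < SEA_B(B).
#'
#' @param a,b `sea_b` objects (equal draw counts are paired; otherwise the
#'   shorter is recycled against the longer's head).
#' @return probability in \[0, 1\].
#' @export
prob_narrower <- function(a, b) {
  m <- min(length(a$draws), length(b$draws))
  mean(a$draws[seq_len(m)] < b$draws[seq_len(m)])
}

#' Ellipse overlap area and proportion
#'
#' Both ellipses are approximated by `n_vertices`-gon polygons; their
#' intersection (convex) is computed by Sutherland-Hodgman clipping and the
#' shoelace formula. The proportion is intersection / union, i.e. overlap
#' relative to the total niche width of both groups combined.
#'
#' @param e1,e2 [standard_ellipse()] objects.
#' @param n_vertices polygon vertices per ellipse.
#' @param scale Mahalanobis radius (1 = standard ellipse; use
#'   `sqrt(qchisq(0.95, 2))` for a 95% ellipse).
#' @return list with `area` (permil^2), `proportion`, `area1`, `area2`.
#' @export
ellipse_overlap <- function(e1, e2, n_vertices = 720, scale = 1) {
  p1 <- ellipse_polygon(e1, n_vertices, scale)
  p2 <- ellipse_polygon(e2, n_vertices, scale)
  a1 <- polygon_area(p1); a2 <- polygon_area(p2)
  if (a1 <= 0 || a2 <= 0) stop("degenerate (zero-area) ellipse")
  inter <- clip_convex(p1, p2)
  ai <- if (is.null(inter) || nrow(inter) < 3) 0 else polygon_area(inter)
  list(area = ai, proportion = ai / (a1 + a2 - ai), area1 = a1, area2 = a2)
}

#' Polygon approximation of a standard ellipse
#'
#' @inheritParams ellipse_overlap
#' @param ellipse a [standard_ellipse()].
#' @return matrix of xy vertices, counter-clockwise.
#' @export
ellipse_polygon <- function(ellipse, n_vertices = 720, scale = 1) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  unit <- rbind(scale * ellipse$a * cos(th), scale * ellipse$b * sin(th))
  t(ellipse$axes %*% unit + ellipse$center)
}

# Shoelace area of a simple polygon (vertices in order).
polygon_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman: clip convex polygon `subject` by convex polygon
# `clip` (both counter-clockwise). Returns NULL when empty.
clip_convex <- function(subject, clip) {
  # ensure counter-clockwise orientation of the clip polygon
  if (signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= 0
    inp <- out; out <- matrix(numeric(0), 0, 2)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      P <- inp[j, ]; Q <- inp[if (j == np) 1 else j + 1, ]
      pin <- inside(P); qin <- inside(Q)
      if (pin) out <- rbind(out, P)
      if (xor(pin, qin)) out <- rbind(out, segment_line_intersect(P, Q, a, b))
    }
  }
  if (nrow(out) < 3) NULL else out
}

signed_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Intersection of segment PQ with the infinite line through A-B.
segment_line_intersect <- function(P, Q, A, B) {
  d1 <- Q - P; d2 <- B - A
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((A[1] - P[1]) * d2[2] - (A[2] - P[2]) * d2[1]) / denom
  P + t * d1
}

#' Niche metrics table per group
#'
#' @param samples data.frame with group, d13C, d15N.
#' @param n_draws,seed passed to [sea_bayes()].
#' @return data.frame keyed by group: Layman metrics, SEA, SEAc and the
#'   posterior median SEA_B.
#' @export
niche_metrics_table <- function(samples, n_draws = 2000, seed = 1) {
  out <- do.call(rbind, lapply(unique(samples$group), function(g) {
    s <- samples[samples$group == g, ]
    lm_ <- layman_metrics(s$d13C, s$d15N)
    se <- standard_ellipse(s$d13C, s$d15N)
    sb <- sea_bayes(s$d13C, s$d15N, n_draws = n_draws, seed = seed)
    data.frame(group = g, t(as.data.frame(lm_)), SEA = se$SEA, SEAc = se$SEAc,
               SEA_B_median = median(sb$draws), n = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
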