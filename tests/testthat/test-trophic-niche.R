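# Body condition, Layman metrics, standard ellipses, Bayesian areas and
# ellipse overlaps.

test_that("BCI is zero for perfectly linear mass-wing data and sums to zero", {
  wing <- seq(380, 420, length.out = 10)
  mass <- 200 + 2.5 * wing
  b <- body_condition_index(mass, wing)
  expect_equal(b$table$bci, rep(0, 10), tolerance = 1e-10)
  set.seed(1)
  mass2 <- mass + rnorm(10, 0, 30)
  b2 <- body_condition_index(mass2, wing)
  expect_equal(sum(b2$table$bci), 0, tolerance = 1e-9)
})

test_that("BCI regression matches the closed-form normal equations", {
  set.seed(2)
  wing <- rnorm(25, 400, 15)
  mass <- 300 + 2 * wing + rnorm(25, 0, 40)
  b <- body_condition_index(mass, wing)
  slope <- cov(wing, mass) / var(wing)
  intercept <- mean(mass) - slope * mean(wing)
  expect_equal(unname(b$coefficients$all["slope"]), slope, tolerance = 1e-10)
  expect_equal(unname(b$coefficients$all["intercept"]), intercept, tolerance = 1e-10)
})

test_that("BCI with two species fits separate regressions", {
  set.seed(3)
  wing <- c(rnorm(10, 400, 10), rnorm(10, 360, 10))
  mass <- c(1200 + 2 * wing[1:10], 900 + 1.5 * wing[11:20]) + rnorm(20, 0, 20)
  sp <- rep(c("BRBO", "RFBO"), each = 10)
  b <- body_condition_index(mass, wing, sp)
  expect_equal(sum(b$table$bci[sp == "BRBO"]), 0, tolerance = 1e-9)
  expect_equal(sum(b$table$bci[sp == "RFBO"]), 0, tolerance = 1e-9)
  expect_error(body_condition_index(c(1, 2, 3), c(5, 5, 5)), "variance")
})

test_that("Layman metrics are exact on the unit square", {
  m <- layman_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(unname(m["CR"]), 1)
  expect_equal(unname(m["NR"]), 1)
  expect_equal(unname(m["TA"]), 1)
  expect_equal(unname(m["NND"]), 1)
  expect_equal(unname(m["CD"]), sqrt(0.5))
})

test_that("CD equals the common radius for centro-symmetric points", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  m <- layman_metrics(2 * cos(th), 2 * sin(th))
  expect_equal(unname(m["CD"]), 2, tolerance = 1e-12)
})

test_that("Layman metrics match naive geometry oracles on random clouds", {
  set.seed(4)
  for (rep in 1:3) {
    x <- rnorm(12, -17, 1); y <- rnorm(12, 11, 1.5)
    m <- layman_metrics(x, y)
    P <- cbind(x, y)
    expect_equal(unname(m["CR"]), max(x) - min(x))
    expect_equal(unname(m["NR"]), max(y) - min(y))
    D <- as.matrix(dist(P)); diag(D) <- Inf
    nnd <- apply(D, 1, min)
    expect_equal(unname(m["NND"]), mean(nnd), tolerance = 1e-12)
    expect_equal(unname(m["SDNND"]), sd(nnd), tolerance = 1e-12)
    cen <- colMeans(P)
    expect_equal(unname(m["CD"]),
                 mean(sqrt((x - cen[1])^2 + (y - cen[2])^2)), tolerance = 1e-12)
    # hull area oracle: fan triangulation from the hull centroid
    h <- chull(P); hp <- P[h, ]
    ref <- colMeans(hp); area <- 0
    for (i in seq_len(nrow(hp))) {
      a <- hp[i, ] - ref; b <- hp[if (i == nrow(hp)) 1 else i + 1, ] - ref
      area <- area + abs(a[1] * b[2] - a[2] * b[1]) / 2
    }
    expect_equal(unname(m["TA"]), unname(area), tolerance = 1e-10)
  }
})

test_that("SEAc applies the exact (n-1)/(n-2) correction", {
  set.seed(5)
  for (n in c(4, 10, 40)) {
    e <- standard_ellipse(rnorm(n), rnorm(n))
    expect_equal(e$SEAc / e$SEA, (n - 1) / (n - 2), tolerance = 1e-12)
  }
})

test_that("SEA approaches pi for a large isotropic unit-variance sample", {
  set.seed(6)
  e <- standard_ellipse(rnorm(20000), rnorm(20000))
  expect_equal(e$SEA, pi, tolerance = 0.03)
})

test_that("metrics are translation invariant; SEA is rotation invariant", {
  set.seed(7)
  x <- rnorm(15, 0, 1.2); y <- rnorm(15, 0, 0.7)
  m1 <- layman_metrics(x, y)
  m2 <- layman_metrics(x - 17.3, y + 11.1)
  expect_equal(m1[c("TA", "CD", "NND", "SDNND")], m2[c("TA", "CD", "NND", "SDNND")],
               tolerance = 1e-10)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  P <- cbind(x, y) %*% t(R)
  expect_equal(standard_ellipse(x, y)$SEA,
               standard_ellipse(P[, 1], P[, 2])$SEA, tolerance = 1e-10)
})

test_that("the standard ellipse contains ~40% of fresh draws", {
  set.seed(8)
  S <- matrix(c(1.3, 0.6, 0.6, 0.9), 2)
  L <- chol(S)
  train <- matrix(rnorm(2000), 1000, 2) %*% L
  test <- matrix(rnorm(2e5), 1e5, 2) %*% L
  e <- standard_ellipse(train[, 1], train[, 2])
  cover <- mean(in_ellipse(e, test[, 1], test[, 2]))
  # analytic coverage of the 1-sigma ellipse: 1 - exp(-1/2) = 0.3935
  expect_equal(cover, 1 - exp(-0.5), tolerance = 0.02)
})

test_that("Bayesian SEA is consistent with SEAc at large n", {
  set.seed(9)
  x <- rnorm(400, -17, 0.8); y <- rnorm(400, 11, 1.1)
  sb <- sea_bayes(x, y, n_draws = 3000, seed = 2)
  expect_equal(median(sb$draws), sb$SEAc, tolerance = 0.05)
  expect_true(all(sb$draws > 0))
})

test_that("identical groups are narrower with probability ~0.5", {
  set.seed(10)
  x <- rnorm(60); y <- rnorm(60)
  a <- sea_bayes(x, y, 4000, seed = 3)
  b <- sea_bayes(x, y, 4000, seed = 4)
  expect_equal(prob_narrower(a, b), 0.5, tolerance = 0.05)
})

test_that("a group with half the true area is detected as narrower", {
  set.seed(11)
  hits <- 0
  small <- sea_bayes(rnorm(50, 0, sqrt(0.5)), rnorm(50, 0, sqrt(0.5)), 2000, seed = 5)
  large <- sea_bayes(rnorm(50, 0, 1), rnorm(50, 0, 1), 2000, seed = 6)
  expect_gt(prob_narrower(small, large), 0.9)
})

test_that("ellipse overlap is 1 on itself, 0 when disjoint", {
  set.seed(12)
  e <- standard_ellipse(rnorm(30), rnorm(30))
  self <- ellipse_overlap(e, e)
  expect_equal(self$proportion, 1, tolerance = 1e-6)
  far <- e; far$center <- e$center + 100
  expect_equal(ellipse_overlap(e, far)$area, 0)
})

test_that("ellipse overlap matches a Monte-Carlo point-in-ellipse oracle", {
  set.seed(13)
  for (rep in 1:3) {
    mk <- function() {
      X <- matrix(rnorm(80), 40, 2) %*% matrix(runif(4, -1, 1), 2) +
        matrix(runif(2, -1, 1), 40, 2, byrow = TRUE)
      standard_ellipse(X[, 1], X[, 2])
    }
    e1 <- mk(); e2 <- mk()
    ov <- ellipse_overlap(e1, e2)
    # MC oracle over the joint bounding box
    box <- rbind(ellipse_polygon(e1), ellipse_polygon(e2))
    n_mc <- 1e6
    px <- runif(n_mc, min(box[, 1]), max(box[, 1]))
    py <- runif(n_mc, min(box[, 2]), max(box[, 2]))
    box_area <- diff(range(box[, 1])) * diff(range(box[, 2]))
    in1 <- in_ellipse(e1, px, py); in2 <- in_ellipse(e2, px, py)
    inter_mc <- mean(in1 & in2) * box_area
    union_mc <- mean(in1 | in2) * box_area
    expect_equal(ov$area, inter_mc, tolerance = 0.02)
    expect_equal(ov$proportion, inter_mc / union_mc, tolerance = 0.02)
  }
})

test_that("the niche metrics table reports one row per group", {
  set.seed(14)
  s <- data.frame(group = rep(c("a", "b"), each = 15),
                  d13C = rnorm(30, -17), d15N = rnorm(30, 11))
  tab <- niche_metrics_table(s, n_draws = 500, seed = 1)
  expect_equal(tab$group, c("a", "b"))
  expect_true(all(tab$SEAc >= tab$SEA))
})
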