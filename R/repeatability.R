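# Individual- and population-level repeatability of trip-level foraging
# parameters from one-way random-effects variance components.
#
# Printed without parentheses in the source literature, the two indices are
# implemented as intraclass-correlation ratios (the only reading bounded in
# [0, 1]):
#   R_ind = S2_A / (S2_ind + S2_A)   with S2_ind the unweighted mean of the
#                                    per-individual variances, and
#   R_pop = S2_A / (S2 + S2_A)       with S2 the pooled within-individual
#                                    variance.
# S2_A comes from the unbalanced one-way ANOVA moment estimator
# (MS_A - MS_W) / n0, truncated at zero.

#' Estimate repeatability of a trip-level trait
#'
#' @param values numeric trait, one value per trip.
#' @param ids individual identifier per trip.
#' @param n_boot bootstrap resamples (over individuals, with replacement)
#'   for SEs and percentile CIs; 0 disables the bootstrap.
#' @param seed integer seed for the bootstrap.
#' @param conf CI coverage.
#' @return object of class `repeatability`: R_ind, R_pop, variance
#'   components, bootstrap SE and CI per index, counts and classification
#'   band (low < 0.25 <= moderate < 0.5 <= high).
#' @export
estimate_repeatability <- function(values, ids, n_boot = 1000, seed = 1,
                                   conf = 0.95) {
  ok <- is.finite(values) & !is.na(ids)
  values <- values[ok]; ids <- as.character(ids)[ok]
  counts <- table(ids)
  if (length(counts) < 2) stop("need at least 2 individuals")
  keep <- names(counts)[counts >= 2]
  if (length(keep) < 2) stop("need at least 2 individuals with >= 2 trips")
  sel <- ids %in% keep
  values <- values[sel]; ids <- ids[sel]
  est <- repeatability_point(values, ids)
  if (est$degenerate)
    warning("zero total variance: repeatability undefined")
  boot <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    uid <- unique(ids)
    by_id <- split(values, ids)[uid]
    draws <- t(vapply(seq_len(n_boot), function(b) {
      pick <- sample(uid, replace = TRUE)
      v <- unlist(by_id[pick], use.names = FALSE)
      g <- rep(seq_along(pick), lengths(by_id[pick]))
      r <- repeatability_point(v, g)
      c(r$R_ind, r$R_pop)
    }, numeric(2)))
    a <- (1 - conf) / 2
    boot <- list(
      se = apply(draws, 2, sd, na.rm = TRUE),
      ci = apply(draws, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(
    R_ind = est$R_ind, R_pop = est$R_pop,
    S2_A = est$S2_A, S2_ind = est$S2_ind, S2 = est$S2,
    se = if (is.null(boot)) c(NA_real_, NA_real_) else setNames(boot$se, c("R_ind", "R_pop")),
    ci = if (is.null(boot)) NULL else boot$ci,
    band = c(R_ind = classify_repeatability(est$R_ind),
             R_pop = classify_repeatability(est$R_pop)),
    n_individuals = length(unique(ids)), n_trips = length(values),
    degenerate = est$degenerate
  ), class = "repeatability")
}

# Moment estimators for one sample; no input checks (hot path in bootstrap).
repeatability_point <- function(values, ids) {
  ids <- as.character(ids)
  ni <- tapply(values, ids, length)
  mi <- tapply(values, ids, mean)
  vi <- tapply(values, ids, var)
  k <- length(ni); N <- sum(ni)
  gm <- mean(values)
  ss_a <- sum(ni * (mi - gm)^2)
  ss_w <- sum((ni - 1) * vi, na.rm = TRUE)
  ms_a <- ss_a / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)      # unbalanced-design group size
  s2_a <- max((ms_a - ms_w) / n0, 0)
  s2_ind <- mean(vi, na.rm = TRUE)         # unweighted mean within-variance
  s2 <- ms_w                               # pooled within-variance
  degenerate <- (s2_a + s2) <= 0
  list(R_ind = if (degenerate) NA_real_ else s2_a / (s2_ind + s2_a),
       R_pop = if (degenerate) NA_real_ else s2_a / (s2 + s2_a),
       S2_A = s2_a, S2_ind = s2_ind, S2 = s2, degenerate = degenerate)
}

#' Classify a repeatability value
#'
#' Bands: low (R < 0.25), moderate (0.25 <= R < 0.5), high (R >= 0.5).
#'
#' @param R repeatability value(s).
#' @return character vector of bands.
#' @export
classify_repeatability <- function(R) {
  out <- rep(NA_character_, length(R))
  out[!is.na(R) & R < 0.25] <- "low"
  out[!is.na(R) & R >= 0.25 & R < 0.5] <- "moderate"
  out[!is.na(R) & R >= 0.5] <- "high"
  out
}

#' Adjusted repeatability after removing fixed effects
#'
#' Repeatability of the residuals of a least-squares fit of the trait on
#' the fixed effects (e.g. sex, season) — the "with fixed effects" model of
#' the with/without comparison.
#'
#' @param values numeric trait per trip.
#' @param ids individual per trip.
#' @param fixed data.frame of fixed-effect covariates, one row per trip.
#' @param ... passed to [estimate_repeatability()].
#' @return a `repeatability` object.
#' @export
adjusted_repeatability <- function(values, ids, fixed, ...) {
  stopifnot(nrow(fixed) == length(values))
  res <- resid(lm(values ~ ., data = fixed))
  estimate_repeatability(res, ids, ...)
}

#' Repeatability table over several traits
#'
#' @param metrics trip-metrics data.frame (from [trip_metrics_table()]).
#' @param traits character vector of metric columns.
#' @param id_col column holding the individual id.
#' @param ... passed to [estimate_repeatability()].
#' @return data.frame: trait, R_ind, R_pop, SEs, bands, counts.
#' @export
repeatability_table <- function(metrics, traits, id_col = "bird_id", ...) {
  out <- do.call(rbind, lapply(traits, function(tr) {
    r <- estimate_repeatability(metrics[[tr]], metrics[[id_col]], ...)
    data.frame(trait = tr, R_ind = r$R_ind, R_pop = r$R_pop,
               se_R_ind = r$se[["R_ind"]], se_R_pop = r$se[["R_pop"]],
               band_R_ind = r$band[["R_ind"]], band_R_pop = r$band[["R_pop"]],
               n_individuals = r$n_individuals, n_trips = r$n_trips,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability (%d individuals, %d trips)\n", x$n_individuals, x$n_trips))
  cat(sprintf("  R_ind = %.3f (SE %.3f, %s)\n", x$R_ind, x$se[["R_ind"]], x$band[["R_ind"]]))
  cat(sprintf("  R_pop = %.3f (SE %.3f, %s)\n", x$R_pop, x$se[["R_pop"]], x$band[["R_pop"]]))
  invisible(x)
}
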