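# Unsupervised four-mode behavioural annotation of (speed, turn) steps.
#
# An expectation-maximization fit of a 4-component bivariate Gaussian
# mixture over (log-speed, turn), followed by quadrant semantics: per-axis
# delimiters split the plane into low/high speed x low/high turn, and each
# component is assigned to one quadrant (LL rest, LH intensive foraging,
# HL travel, HH relocate) by a minimum-cost bijection. This guarantees the
# quadrant-semantics contract of the original binary-clustering method
# without reproducing its exact delimited likelihood.

#' Fit the four-mode behaviour model
#'
#' EM on a 4-component bivariate Gaussian mixture over (log speed, turn).
#' After convergence, per-axis delimiters are set to the midpoint between
#' the two lower and the two upper component means, and components are
#' mapped onto quadrants by the minimum-cost bijection between component
#' means and the quadrant archetypes implied by the delimiters.
#'
#' @param features data.frame with `speed_kmh` and `turn_rad` per step;
#'   non-finite rows are ignored for fitting.
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the log-likelihood gain.
#' @param n_restarts maximum restarts on EM degeneracy (singular covariance).
#' @param seed integer seed for initialization.
#' @param speed_floor_kmh small constant added before the log transform so
#'   zero speeds stay finite; delimiters are reported on the natural scale.
#' @return object of class `embc_model`: component means/covariances/weights,
#'   delimiters (`speed_kmh`, `turn_rad`), component-to-quadrant assignment,
#'   and the log-likelihood trace (non-decreasing by construction).
#' @export
fit_embc <- function(features, max_iter = 300, tol = 1e-6, n_restarts = 5,
                     seed = 1, speed_floor_kmh = 0.1) {
  X <- cbind(log(features$speed_kmh + speed_floor_kmh), features$turn_rad)
  X <- X[is.finite(X[, 1]) & is.finite(X[, 2]), , drop = FALSE]
  if (nrow(X) < 50) stop("need at least 50 finite (speed, turn) steps")
  fit <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(em_gmm4(X, max_iter, tol, seed = seed + r - 1, jitter = r > 1),
                    error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error"))
    stop("EM failed after ", n_restarts, " restarts: ", conditionMessage(fit))
  # per-axis delimiters: midpoint between the 2nd and 3rd sorted comp. means
  delim <- vapply(1:2, function(j) {
    m <- sort(vapply(fit$mean, `[`, numeric(1), j))
    (m[2] + m[3]) / 2
  }, numeric(1))
  assignment <- assign_quadrants(fit$mean, delim)
  structure(list(
    mean = fit$mean, cov = fit$cov, weight = fit$weight,
    loglik_trace = fit$loglik_trace,
    delimiters = c(speed_kmh = exp(delim[1]) - speed_floor_kmh,
                   turn_rad = delim[2]),
    delimiters_internal = delim,
    assignment = assignment,
    speed_floor_kmh = speed_floor_kmh
  ), class = "embc_model")
}

# Plain EM for a 4-component bivariate Gaussian mixture.
# Initialization: points split by per-axis median into the four quadrant
# archetype cells (a k-means++-flavoured seeding on archetypes), jittered on
# restarts. Asserts the monotone log-likelihood EM guarantee each iteration.
em_gmm4 <- function(X, max_iter, tol, seed, jitter = FALSE) {
  set.seed(seed)
  n <- nrow(X); K <- 4L
  med <- apply(X, 2, median)
  if (jitter) med <- med + rnorm(2, 0, apply(X, 2, sd) * 0.3)
  cell <- 1L + (X[, 1] > med[1]) * 2L + (X[, 2] > med[2])   # LL,LH,HL,HH order
  means <- lapply(1:K, function(k) {
    idx <- which(cell == k)
    if (length(idx) < 2) idx <- sample.int(n, max(2, n %/% 20))
    colMeans(X[idx, , drop = FALSE])
  })
  covs <- replicate(K, cov(X) / 4 + diag(1e-4, 2), simplify = FALSE)
  w <- rep(1 / K, K)
  ll_old <- -Inf; trace <- numeric()
  for (it in seq_len(max_iter)) {
    logd <- vapply(1:K, function(k)
      log(w[k]) + dmvnorm2_log(X, means[[k]], covs[[k]]), numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    if (ll < ll_old - 1e-8)
      stop("log-likelihood decreased (EM invariant violated)")
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 2)) stop("EM degeneracy: empty component")
    w <- nk / n
    for (k in 1:K) {
      mu <- colSums(resp[, k] * X) / nk[k]
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc * resp[, k], Xc) / nk[k] + diag(1e-8, 2)
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
        stop("EM degeneracy: singular covariance")
      means[[k]] <- mu; covs[[k]] <- S
    }
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
  }
  list(mean = means, cov = covs, weight = w, loglik_trace = trace)
}

# Log density of a bivariate normal at the rows of X.
dmvnorm2_log <- function(X, mu, S) {
  ch <- chol(S)
  Z <- forwardsolve(t(ch), t(X) - mu)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(Z^2)
}

# Map the 4 fitted components onto quadrants. Archetype for each quadrant is
# built from the component means grouped low/high per axis by the delimiter;
# the assignment is the minimum total squared distance bijection.
assign_quadrants <- function(means, delim) {
  M <- do.call(rbind, means)
  axis_lohi <- function(j) {
    lo <- mean(M[M[, j] <= delim[j], j]); hi <- mean(M[M[, j] > delim[j], j])
    c(lo, hi)
  }
  s <- axis_lohi(1); t <- axis_lohi(2)
  arch <- rbind(LL = c(s[1], t[1]), LH = c(s[1], t[2]),
                HL = c(s[2], t[1]), HH = c(s[2], t[2]))
  perms <- permutations4()
  cost <- vapply(seq_len(nrow(perms)), function(i)
    sum((M - arch[perms[i, ], ])^2), numeric(1))
  best <- perms[which.min(cost), ]
  setNames(rownames(arch)[best], paste0("comp", 1:4))
}

permutations4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4), ])
  dimnames(p) <- NULL
  p
}

#' Label steps with behavioural quadrants
#'
#' Each step is assigned the quadrant of its maximum-responsibility mixture
#' component; exact ties break towards the higher-weight component. Steps
#' with non-finite features get `NA` and are excluded downstream.
#'
#' @param features data.frame with `speed_kmh`, `turn_rad`.
#' @param model a fitted [fit_embc()] model.
#' @return factor of labels (levels LL, LH, HL, HH), one per input row.
#' @export
label_steps <- function(features, model) {
  stopifnot(inherits(model, "embc_model"))
  X <- cbind(log(features$speed_kmh + model$speed_floor_kmh), features$turn_rad)
  ok <- is.finite(X[, 1]) & is.finite(X[, 2])
  out <- factor(rep(NA_character_, nrow(X)), levels = STATE_LEVELS)
  if (any(ok)) {
    Xo <- X[ok, , drop = FALSE]
    logd <- vapply(1:4, function(k)
      log(model$weight[k]) + dmvnorm2_log(Xo, model$mean[[k]], model$cov[[k]]),
      numeric(nrow(Xo)))
    # deterministic tie-break: nudge by weight rank at machine scale
    tie <- matrix(rank(model$weight, ties.method = "first") * 1e-12,
                  nrow(Xo), 4, byrow = TRUE)
    comp <- max.col(logd + tie, ties.method = "first")
    out[ok] <- model$assignment[comp]
  }
  out
}

#' Per-fix labels for a segmented fix table
#'
#' Computes step features per trip, labels them with a (pooled) model and
#' propagates step labels to fixes: fix i takes the label of the step
#' leaving it; the trip's last fix inherits the final step's label, and
#' steps with undefined turn inherit the nearest following defined label.
#'
#' @param fixes segmented fix table (with trip_id).
#' @param model fitted [fit_embc()] model.
#' @return factor of per-fix labels aligned with `fixes`.
#' @export
label_fixes <- function(fixes, model) {
  out <- factor(rep(NA_character_, nrow(fixes)), levels = STATE_LEVELS)
  for (id in unique(fixes$trip_id)) {
    sel <- which(fixes$trip_id == id)
    if (length(sel) < 3) next
    st <- step_features(fixes[sel, , drop = FALSE])
    lab <- as.character(label_steps(st, model))
    # backfill undefined leading steps from the first defined label
    for (i in rev(seq_along(lab)[-length(lab)]))
      if (is.na(lab[i])) lab[i] <- lab[i + 1]
    out[sel] <- factor(c(lab, lab[length(lab)]), levels = STATE_LEVELS)
  }
  out
}

#' @export
print.embc_model <- function(x, ...) {
  cat("Four-mode behaviour model (EM Gaussian mixture on log-speed x turn)\n")
  cat(sprintf("  delimiters: speed %.2f km/h, turn %.2f rad\n",
              x$delimiters[["speed_kmh"]], x$delimiters[["turn_rad"]]))
  for (k in 1:4) {
    cat(sprintf("  comp %d -> %s  weight %.3f  mean (log-speed %.2f, turn %.2f)\n",
                k, x$assignment[k], x$weight[k], x$mean[[k]][1], x$mean[[k]][2]))
  }
  invisible(x)
}
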