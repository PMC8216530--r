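# Environmental predictor engineering: a lightweight regular-grid raster
# class, moving-window proportional-change gradients, regridding, per-fix
# extraction, and collinearity screening. Rasters are exchanged on disk as
# ESRI ASCII grids (plain text), one file per variable-month.

#' Construct a raster layer
#'
#' Values on a regular lon/lat grid of cell centers; rows are latitudes
#' (ascending), columns longitudes (ascending). `NA` marks missing cells.
#'
#' @param values numeric matrix, length(lat) x length(lon).
#' @param lon,lat ascending cell-center coordinate vectors (degrees).
#' @param var variable name (e.g. "SST").
#' @param month month index for dynamic layers, `NA` for static.
#' @return object of class `env_raster`.
#' @export
env_raster <- function(values, lon, lat, var = "layer", month = NA_integer_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(lat), ncol(values) == length(lon))
  if (length(lon) > 1 && any(diff(lon) <= 0)) stop("lon must be ascending")
  if (length(lat) > 1 && any(diff(lat) <= 0)) stop("lat must be ascending")
  structure(list(values = values, lon = as.numeric(lon), lat = as.numeric(lat),
                 var = var, month = month),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("env_raster '%s'%s: %d x %d cells, lon [%.3f, %.3f], lat [%.3f, %.3f], res %.3f deg\n",
              x$var, if (is.na(x$month)) "" else sprintf(" (month %d)", x$month),
              length(x$lat), length(x$lon), min(x$lon), max(x$lon),
              min(x$lat), max(x$lat), raster_res(x)))
  invisible(x)
}

raster_res <- function(r) {
  if (length(r$lon) > 1) diff(r$lon[1:2]) else if (length(r$lat) > 1) diff(r$lat[1:2]) else NA_real_
}

#' Moving-window proportional-change gradient
#'
#' For each cell, PC = (max - min) * 100 / max over the surrounding 3x3
#' window (windows truncated at edges so coastal cells retain gradients).
#' Cells whose window contains only missing values, or whose window maximum
#' is not positive (the formula is undefined there; relevant for variables
#' such as SSH that can be negative), are set missing. With `offset = TRUE`
#' the window is first shifted to be positive by subtracting the layer
#' minimum, a documented option for sign-crossing variables.
#'
#' @param raster an [env_raster].
#' @param offset shift the layer to positive values before applying the
#'   formula (default FALSE: compute as printed, mask where max <= 0).
#' @return an [env_raster] named `G<var>` with PC values in percent.
#' @export
gradient_pc <- function(raster, offset = FALSE) {
  v <- raster$values
  if (offset) {
    mn <- min(v, na.rm = TRUE)
    if (is.finite(mn) && mn <= 0) v <- v - mn + 1e-9
  }
  nr <- nrow(v); nc <- ncol(v)
  wmax <- matrix(-Inf, nr, nc); wmin <- matrix(Inf, nr, nc)
  nok <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    ti <- ri - di; tj <- rj - dj
    sub <- v[ri, rj, drop = FALSE]
    ok <- !is.na(sub)
    sub_max <- ifelse(ok, sub, -Inf); sub_min <- ifelse(ok, sub, Inf)
    wmax[ti, tj] <- pmax(wmax[ti, tj, drop = FALSE], sub_max)
    wmin[ti, tj] <- pmin(wmin[ti, tj, drop = FALSE], sub_min)
    nok[ti, tj] <- nok[ti, tj, drop = FALSE] + ok
  }
  pc <- (wmax - wmin) * 100 / wmax
  pc[nok == 0L | wmax <= 0] <- NA_real_
  env_raster(pc, raster$lon, raster$lat,
             var = paste0("G", raster$var), month = raster$month)
}

#' Regrid a raster
#'
#' Block-mean aggregation when coarsening (each source cell contributes to
#' its nearest target cell; missing cells are excluded from block means) and
#' bilinear interpolation when refining. A target grid identical to the
#' source is a no-op.
#'
#' @param raster an [env_raster].
#' @param target_res target cell size in degrees (default 0.08, the
#'   analysis grid).
#' @param target optional list with `lon` and `lat` center vectors,
#'   overriding `target_res`.
#' @return an [env_raster] on the target grid.
#' @export
regrid <- function(raster, target_res = 0.08, target = NULL) {
  src_res <- raster_res(raster)
  if (is.null(target)) {
    target <- list(
      lon = grid_centers(min(raster$lon) - src_res / 2, max(raster$lon) + src_res / 2, target_res),
      lat = grid_centers(min(raster$lat) - src_res / 2, max(raster$lat) + src_res / 2, target_res))
  }
  t_res <- if (length(target$lon) > 1) diff(target$lon[1:2]) else target_res
  if (isTRUE(all.equal(target$lon, raster$lon)) &&
      isTRUE(all.equal(target$lat, raster$lat)))
    return(raster)
  if (!length(target$lon) || !length(target$lat))
    stop("target grid has empty overlap with the source raster")
  if (t_res >= src_res) {
    # coarsen: average source cells mapped to their nearest target center
    ilon <- nearest_index(raster$lon, target$lon)
    ilat <- nearest_index(raster$lat, target$lat)
    acc <- matrix(0, length(target$lat), length(target$lon))
    cnt <- matrix(0L, length(target$lat), length(target$lon))
    v <- raster$values
    for (i in seq_along(raster$lat)) {
      if (is.na(ilat[i])) next
      for (j in seq_along(raster$lon)) {
        if (is.na(ilon[j]) || is.na(v[i, j])) next
        acc[ilat[i], ilon[j]] <- acc[ilat[i], ilon[j]] + v[i, j]
        cnt[ilat[i], ilon[j]] <- cnt[ilat[i], ilon[j]] + 1L
      }
    }
    out <- acc / cnt
    out[cnt == 0L] <- NA_real_
  } else {
    # refine: bilinear on the source cell centers
    G <- expand.grid(lon = target$lon, lat = target$lat)
    z <- pracma::interp2(raster$lon, raster$lat, raster$values,
                         pmin(pmax(G$lon, min(raster$lon)), max(raster$lon)),
                         pmin(pmax(G$lat, min(raster$lat)), max(raster$lat)),
                         method = "linear")
    out <- matrix(z, length(target$lat), length(target$lon), byrow = TRUE)
  }
  env_raster(out, target$lon, target$lat, var = raster$var, month = raster$month)
}

# Index of the nearest target center for each source coordinate; NA when the
# source coordinate falls outside the target grid by more than half a cell.
nearest_index <- function(src, tgt) {
  res <- if (length(tgt) > 1) diff(tgt[1:2]) else Inf
  i <- findInterval(src, c(tgt - res / 2, tgt[length(tgt)] + res / 2))
  i[i < 1 | i > length(tgt)] <- NA_integer_
  i
}

#' Extract raster values at fix positions
#'
#' Nearest-cell extraction of every static, dynamic and gradient layer of a
#' stack at each fix, using the fix's calendar month for dynamic layers.
#' Fixes outside a raster extent get `NA` with a warning.
#'
#' @param fixes data.frame with lon, lat and timestamp (POSIXct; used for
#'   the month of dynamic layers).
#' @param stack named list of [env_raster] layers (static name `VAR`,
#'   dynamic `VAR_mm`), e.g. from [simulate_environment()].
#' @return `fixes` with one appended column per variable (and per gradient
#'   when present in the stack).
#' @export
extract_at <- function(fixes, stack) {
  month <- as.integer(format(fixes$timestamp, "%m"))
  vars <- unique(vapply(stack, function(r) r$var, character(1)))
  out <- fixes
  warned <- FALSE
  for (v in vars) {
    layers <- stack[vapply(stack, function(r) identical(r$var, v), logical(1))]
    static <- length(layers) == 1L && is.na(layers[[1]]$month)
    col <- rep(NA_real_, nrow(fixes))
    for (ly in layers) {
      rows <- if (static) seq_len(nrow(fixes)) else which(month == ly$month)
      if (!length(rows)) next
      ii <- nearest_index(fixes$lat[rows], ly$lat)
      jj <- nearest_index(fixes$lon[rows], ly$lon)
      miss <- is.na(ii) | is.na(jj)
      if (any(miss) && !warned) {
        warning("some fixes fall outside the raster extent; values set NA")
        warned <- TRUE
      }
      ok <- !miss
      col[rows[ok]] <- ly$values[cbind(ii[ok], jj[ok])]
    }
    out[[v]] <- col
  }
  out
}

#' Iterative variance-inflation-factor screening
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing covariate j on all others;
#' variables are dropped one at a time (highest VIF first, ties broken by
#' name so the result does not depend on column order) until every VIF is
#' at or below the threshold. Perfectly collinear variables have infinite
#' VIF and are removed first.
#'
#' @param covariates data.frame of numeric covariates; incomplete rows are
#'   dropped.
#' @param threshold retention threshold (default 3).
#' @return list with `retained` (character), `dropped` (character) and
#'   `vif` (named numeric, final VIFs of the retained set).
#' @export
vif_screen <- function(covariates, threshold = 3) {
  covariates <- covariates[, sort(names(covariates)), drop = FALSE]
  covariates <- covariates[complete.cases(covariates), , drop = FALSE]
  if (nrow(covariates) < ncol(covariates) + 2)
    stop("need at least 2 more complete rows than variables")
  vifs <- function(df) {
    vapply(names(df), function(v) {
      # lm warns on an essentially perfect fit; that case is handled
      # explicitly as an infinite VIF
      r2 <- suppressWarnings(
        summary(lm(df[[v]] ~ ., data = df[setdiff(names(df), v)]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- covariates
  dropped <- character()
  while (ncol(keep) > 1) {
    v <- vifs(keep)
    if (all(v <= threshold)) break
    worst <- names(v)[which.max(v)]   # names sorted, so ties resolve by name
    dropped <- c(dropped, worst)
    keep <- keep[setdiff(names(keep), worst)]
  }
  final <- if (ncol(keep) > 1) vifs(keep) else setNames(1, names(keep))
  list(retained = names(keep), dropped = dropped, vif = final)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tooling; cell
#' registration is preserved via `xllcorner`/`yllcorner`.
#'
#' @param raster an [env_raster].
#' @param path output file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, digits = 8) {
  res <- raster_res(raster)
  v <- raster$values
  v[is.na(v)] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", min(raster$lon) - res / 2),
    sprintf("yllcorner %.10f", min(raster$lat) - res / 2),
    sprintf("cellsize %.10f", res),
    "NODATA_value -9999")
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param var,month metadata for the returned layer.
#' @return an [env_raster].
#' @export
read_ascii_grid <- function(path, var = "layer", month = NA_integer_) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, character(1), 1))
  val <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(val) <- key
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  v[v == val[["nodata_value"]]] <- NA_real_
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  res <- val[["cellsize"]]
  lon <- val[["xllcorner"]] + res * (seq_len(val[["ncols"]]) - 0.5)
  lat <- val[["yllcorner"]] + res * (seq_len(val[["nrows"]]) - 0.5)
  env_raster(v, lon, lat, var = var, month = month)
}
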