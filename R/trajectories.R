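# Trip segmentation and trip-level foraging metrics.

#' Split fix streams into central-place foraging trips
#'
#' A trip is a maximal run of fixes farther than `radius_km` from the colony,
#' padded with the adjacent at-colony fix on both sides when present. Trips
#' shorter than `min_duration_min` are discarded (logger jitter around the
#' colony otherwise forms spurious excursions).
#'
#' @param fixes data.frame with columns bird_id, timestamp (POSIXct), lon,
#'   lat; sorted by timestamp within bird.
#' @param colony numeric length-2 (lon, lat).
#' @param radius_km colony radius in km (> 0).
#' @param min_duration_min minimum trip duration in minutes.
#' @return data.frame of the retained at-sea fixes with a `trip_id` column
#'   (`<bird>_T<k>`); zero rows when no excursion exists.
#' @export
split_trips <- function(fixes, colony, radius_km = 1, min_duration_min = 30) {
  stopifnot(radius_km > 0)
  empty <- cbind(fixes[0, , drop = FALSE], trip_id = character())
  if (!nrow(fixes)) return(empty)
  out <- list()
  for (bird in unique(fixes$bird_id)) {
    fb <- fixes[fixes$bird_id == bird, , drop = FALSE]
    if (is.unsorted(fb$timestamp, strictly = TRUE))
      stop("fixes must be strictly time-ordered within bird: ", bird)
    at_sea <- gc_dist_km(fb$lon, fb$lat, colony[[1]], colony[[2]]) > radius_km
    r <- rle(at_sea)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- 0L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      # pad with the adjacent at-colony fix on both sides when present
      if (i0 > 1L) i0 <- i0 - 1L
      if (i1 < nrow(fb)) i1 <- i1 + 1L
      dur_min <- as.numeric(difftime(fb$timestamp[i1], fb$timestamp[i0], units = "mins"))
      if (dur_min < min_duration_min) next
      k <- k + 1L
      tr <- fb[i0:i1, , drop = FALSE]
      tr$trip_id <- sprintf("%s_T%02d", bird, k)
      out[[length(out) + 1L]] <- tr
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-step speed and turning angle of a trip
#'
#' Step i runs from fix i to fix i+1. Speed is the haversine distance over
#' the elapsed time; the turning angle is the absolute smallest difference
#' between the headings of successive steps, in \[0, pi\] radians (sign-
#' agnostic, matching the low/high-turn cluster semantics). The first step
#' has no previous heading and gets `NA` turn.
#'
#' @param trip data.frame with timestamp, lon, lat (one trip, time-ordered).
#' @return data.frame with one row per step: `speed_kmh`, `turn_rad`,
#'   `heading_deg`, `dt_h`.
#' @export
step_features <- function(trip) {
  n <- nrow(trip)
  if (n < 3) stop("a trip needs at least 3 fixes for step features")
  dt_h <- as.numeric(difftime(trip$timestamp[-1], trip$timestamp[-n], units = "hours"))
  if (any(dt_h <= 0)) stop("duplicate or non-increasing timestamps in trip")
  d <- gc_dist_km(trip$lon[-n], trip$lat[-n], trip$lon[-1], trip$lat[-1])
  hd <- gc_bearing(trip$lon[-n], trip$lat[-n], trip$lon[-1], trip$lat[-1])
  # a zero-length step has no defined heading; carry the previous one
  for (i in seq_along(hd)[-1]) if (d[i] == 0) hd[i] <- hd[i - 1]
  turn <- c(NA_real_, ang_diff_deg(hd[-length(hd)], hd[-1]) * pi / 180)
  data.frame(speed_kmh = d / dt_h, turn_rad = turn,
             heading_deg = hd, dt_h = dt_h)
}

#' Trip-level foraging metrics
#'
#' Duration, maximum colony distance, distal position and colony-to-distal
#' great-circle bearing, and the proportion of fixes in each behavioural
#' state. With uniform fix intervals the fix-count proportions equal time
#' shares.
#'
#' @param trip data.frame with timestamp, lon, lat.
#' @param labels factor/character of behavioural labels (LL/LH/HL/HH), one
#'   per fix; `NA` allowed and excluded from the proportions.
#' @param colony numeric length-2 (lon, lat).
#' @return one-row data.frame with duration_h, max_dist_colony_km,
#'   prop_rest, prop_forage, prop_travel, prop_relocate, distal_lon,
#'   distal_lat, distal_bearing_deg.
#' @export
trip_metrics <- function(trip, labels, colony) {
  n <- nrow(trip)
  if (length(labels) != n) stop("labels must align with fixes (", n, " fixes)")
  dur <- as.numeric(difftime(trip$timestamp[n], trip$timestamp[1], units = "hours"))
  d <- gc_dist_km(trip$lon, trip$lat, colony[[1]], colony[[2]])
  i_max <- which.max(d)
  lab <- factor(labels, levels = STATE_LEVELS)
  pr <- as.numeric(table(lab)) / sum(!is.na(lab))
  data.frame(
    duration_h = dur,
    max_dist_colony_km = d[i_max],
    prop_rest = pr[1], prop_forage = pr[2],
    prop_travel = pr[3], prop_relocate = pr[4],
    distal_lon = trip$lon[i_max], distal_lat = trip$lat[i_max],
    distal_bearing_deg = gc_bearing(colony[[1]], colony[[2]],
                                    trip$lon[i_max], trip$lat[i_max])
  )
}

#' Trip metrics table for a labelled fix set
#'
#' Convenience wrapper: applies [trip_metrics()] per trip of a segmented,
#' labelled fix table. This is the tidy export consumed by external
#' mixed-model fitting.
#'
#' @param fixes segmented fixes (with trip_id) as from [split_trips()].
#' @param labels per-fix behavioural labels aligned with `fixes`.
#' @param colony numeric length-2 (lon, lat).
#' @return data.frame keyed by (bird_id, trip_id), one row per trip.
#' @export
trip_metrics_table <- function(fixes, labels, colony) {
  ids <- unique(fixes$trip_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- fixes$trip_id == id
    m <- trip_metrics(fixes[sel, , drop = FALSE], labels[sel], colony)
    cbind(data.frame(bird_id = fixes$bird_id[sel][1], trip_id = id,
                     stringsAsFactors = FALSE), m)
  }))
  rownames(out) <- NULL
  out
}

#' Circular mean of bearings
#'
#' @param bearing_deg bearings in degrees.
#' @return mean direction in \[0, 360).
#' @export
circular_mean_deg <- function(bearing_deg) {
  th <- bearing_deg * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi + 360) %% 360
}
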