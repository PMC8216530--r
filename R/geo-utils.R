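# Great-circle helpers. All distances in km on a sphere of radius 6371 km,
# all coordinates decimal degrees WGS84, lon before lat.

EARTH_RADIUS_KM <- 6371

#' Haversine great-circle distance
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectors recycle.
#' @return distance in km.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(norm_lon(lon1), n), rep_len(lat1, n))
  p2 <- cbind(rep_len(norm_lon(lon2), n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

# normalize longitudes to (-180, 180]
norm_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Initial great-circle bearing
#'
#' @inheritParams gc_dist_km
#' @return bearing in degrees clockwise from north, in \[0, 360).
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  b <- geosphere::bearing(cbind(rep_len(norm_lon(lon1), n), rep_len(lat1, n)),
                          cbind(rep_len(norm_lon(lon2), n), rep_len(lat2, n)))
  (b + 360) %% 360
}

# Smallest absolute angular difference between two bearings (degrees),
# result in [0, 180].
ang_diff_deg <- function(b1, b2) {
  d <- (b2 - b1 + 180) %% 360 - 180
  abs(d)
}

# Advance a lon/lat point by dist_km along a bearing (degrees from north).
# Local flat-earth step, adequate for the 5-min steps used here (< 5 km).
advance_point <- function(lon, lat, bearing_deg, dist_km) {
  th <- bearing_deg * pi / 180
  dlat <- dist_km * cos(th) / (pi * EARTH_RADIUS_KM / 180)
  lat2 <- lat + dlat
  dlon <- dist_km * sin(th) / (pi * EARTH_RADIUS_KM / 180 * cos((lat + lat2) / 2 * pi / 180))
  c(lon + dlon, lat2)
}
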