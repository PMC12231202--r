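#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on the WGS84 mean-radius sphere, suitable at the tens
#' of kilometres scale of within-season goose movements where sub-metre
#' ellipsoidal accuracy is unnecessary.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees. Vectors are
#'   recycled in the usual way.
#' @return Distance in metres.
#' @export
gc_distance_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

#' Project longitude/latitude to a local metric plane
#'
#' Azimuthal equidistant projection centred on the point cloud (or a given
#' centre). Distances from the centre are exact great-circle distances;
#' distortion away from the centre is negligible at the scale of a wintering
#' site, which is what kernel density estimation and confinement geometry
#' need.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param center Optional length-2 numeric `c(lon, lat)`; defaults to the
#'   mean of the inputs.
#' @return A list with `x`, `y` (metres) and the `center` used.
#' @export
project_aeqd <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  R <- 6371008.8
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- R * k * cos(phi) * sin(lam - lam0)
  y <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  list(x = x, y = y, center = center)
}

#' Local civil date of a UTC timestamp
#'
#' Daily aggregation uses the study site's civil day (UTC+8 for Poyang
#' Lake); the offset is configurable for other deployments.
#'
#' @param time POSIXct timestamps (UTC).
#' @param tz_offset_h Hours ahead of UTC defining the civil day.
#' @return A `Date` vector.
#' @export
local_date <- function(time, tz_offset_h = 8) {
  as.Date(time + tz_offset_h * 3600, tz = "UTC")
}
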