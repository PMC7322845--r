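# Spherical geometry primitives shared by all modules.
# Single distance convention: Earth radius 6371 km, 111.19 km per degree.

EARTH_RADIUS_KM <- 6371
KM_PER_DEGREE <- 111.19

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. All arguments are
#' recycled to a common length.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees WGS84.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 1, 0)  # one degree of longitude at the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (!all(is.finite(c(lon1, lat1, lon2, lat2))))
    stop("haversine_km: non-finite coordinate", call. = FALSE)
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 360))
    stop("haversine_km: coordinate out of range", call. = FALSE)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial bearing from one point towards another
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Bearing in radians, clockwise from north, in (-pi, pi].
#' @keywords internal
bearing_rad <- function(lon1, lat1, lon2, lat2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  atan2(y, x)
}

# Wrap an angle (radians) into (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# Planar step in degrees for a displacement of `km` along bearing `theta`
# (radians clockwise from north) starting at latitude `lat`. Adequate for
# step sizes of tens of km away from the poles.
step_deg <- function(km, theta, lat) {
  dlat <- km * cos(theta) / KM_PER_DEGREE
  dlon <- km * sin(theta) / (KM_PER_DEGREE * cos(lat * pi / 180))
  c(dlon, dlat)
}

# Round half away from zero to `digits` decimals (reporting convention for
# front back-calculations; base round() ties to even).
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
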