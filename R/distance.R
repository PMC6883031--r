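#' Great-circle distance (haversine)
#'
#' Distance between points on a sphere of radius 6371.0 km, vectorized with
#' the usual recycling. All coordinates in degrees.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance in km.
#' @export
gc_distance <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

# km per degree of meridian arc on the 6371 km sphere
KM_PER_DEG <- 6371.0 * pi / 180
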