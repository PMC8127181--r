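#' Great-circle distance on the 6371 km sphere
#'
#' Haversine distance between lon/lat points, vectorised and recycled like
#' arithmetic. All trip metrics, dive georeferencing and landscape
#' distances in this package use this single definition; at foraging-trip
#' scales (tens of km) the spherical approximation is well within GPS
#' error, so no ellipsoidal refinement is used.
#'
#' @param lon1,lat1,lon2,lat2 numeric degrees (WGS84).
#' @return numeric distance in metres.
#' @examples
#' greatCircleDistance(0, 0, 1, 0) # ~111.19 km along the equator
#' @export
greatCircleDistance <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371000)
}

# local planar offsets (metres) -> lon/lat around an origin; used only by
# the synthetic generator where extents are << Earth radius
.offsetToLonLat <- function(xm, ym, origin) {
  mPerDegLat <- pi * 6371000 / 180
  lat <- origin[2] + ym / mPerDegLat
  lon <- origin[1] + xm / (mPerDegLat * cos(origin[2] * pi / 180))
  cbind(lon = lon, lat = lat)
}
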