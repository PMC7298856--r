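# Spherical geometry helpers. All geographic distances in the package go
# through haversine_km on a sphere of radius 6371.0088 km (IUGG mean Earth
# radius); degree offsets are never converted to km by a fixed factor.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (haversine) distance in kilometres
#'
#' Vectorized over the longer of the two point sets (the usual recycling
#' rules apply).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Pairwise haversine distance matrix
#'
#' @param lon,lat Coordinates of n points (decimal degrees).
#' @return n x n symmetric matrix of great-circle distances in km.
#' @export
haversine_matrix <- function(lon, lat) {
  n <- length(lon)
  out <- matrix(0, n, n)
  if (n < 2) return(out)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- haversine_km(lon[i], lat[i], lon[j], lat[j])
    out[i, j] <- d
    out[j, i] <- d
  }
  out
}

# distances from many cells to many points, returned as cells x points
haversine_cross <- function(lon_a, lat_a, lon_b, lat_b) {
  vapply(seq_along(lon_b),
         function(k) haversine_km(lon_a, lat_a, lon_b[k], lat_b[k]),
         numeric(length(lon_a)))
}
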