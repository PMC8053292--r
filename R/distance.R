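#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are geographic
#' coordinates in decimal degrees. Vectorized over both arguments with the
#' usual recycling rules.
#'
#' @param lat1,lon1 Latitude/longitude of the first point(s), degrees.
#' @param lat2,lon2 Latitude/longitude of the second point(s), degrees.
#' @return Numeric vector of distances in kilometers.
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.19 km along the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitudes must lie in [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("longitudes must lie in [-180, 180]")
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Planar Euclidean distance in kilometers
#'
#' Treats coordinates as kilometre-scaled planar positions. Intended for
#' synthetic grids where no geographic projection is implied.
#'
#' @inheritParams haversine_km
#' @return Numeric vector of distances.
#' @export
euclidean_km <- function(lat1, lon1, lat2, lon2) {
  sqrt((lat1 - lat2)^2 + (lon1 - lon2)^2)
}

#' Distance from each point to its nearest target
#'
#' @param lat,lon Coordinates of the query points (degrees).
#' @param target_lat,target_lon Coordinates of candidate targets (degrees).
#' @return Numeric vector: for each query point, the great-circle distance in
#'   km to the nearest target.
#' @export
distance_to_nearest_km <- function(lat, lon, target_lat, target_lon) {
  stopifnot(length(target_lat) >= 1, length(target_lat) == length(target_lon))
  out <- rep(Inf, length(lat))
  for (k in seq_along(target_lat)) {
    d <- haversine_km(lat, lon, target_lat[k], target_lon[k])
    out <- pmin(out, d)
  }
  out
}

# Gauss-Hermite nodes/weights for weight function exp(-z^2), via the
# Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}
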