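#' Local equirectangular projection
#'
#' Projects longitude/latitude (degrees) to planar metric coordinates about a
#' reference point, using an equirectangular approximation: adequate over a
#' study window of ~10 km, which is the scale of a city road network.
#'
#' @param lon,lat numeric vectors, degrees.
#' @param origin length-2 numeric `c(lon0, lat0)` reference point, degrees.
#' @return A two-column matrix `cbind(x, y)` in meters.
#' @export
project_lonlat <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2, is.finite(origin))
  rad <- pi / 180
  x <- .earth_radius_m * (lon - origin[1]) * rad * cos(origin[2] * rad)
  y <- .earth_radius_m * (lat - origin[2]) * rad
  cbind(x = x, y = y)
}

#' Inverse of [project_lonlat()]
#' @param x,y numeric vectors, meters.
#' @inheritParams project_lonlat
#' @return A two-column matrix `cbind(lon, lat)` in degrees.
#' @export
unproject_xy <- function(x, y, origin) {
  rad <- pi / 180
  lon <- origin[1] + x / (.earth_radius_m * rad * cos(origin[2] * rad))
  lat <- origin[2] + y / (.earth_radius_m * rad)
  cbind(lon = lon, lat = lat)
}

.earth_radius_m <- 6371008.8

#' Distance from points to a polyline (planar)
#'
#' Minimum Euclidean distance from each point to a polyline, both given in
#' projected metric coordinates.
#'
#' @param pts two-column matrix of point coordinates (m).
#' @param poly two-column matrix of polyline vertices (m), >= 2 rows.
#' @return numeric vector of distances (m).
#' @keywords internal
point_polyline_dist <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  stopifnot(nrow(poly) >= 2)
  d2 <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(poly) - 1L)) {
    a <- poly[j, ]
    b <- poly[j + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dj2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      dj2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, dj2)
  }
  sqrt(d2)
}

#' Polyline length in meters
#' @param poly two-column matrix of projected vertices (m).
#' @keywords internal
polyline_length <- function(poly) {
  dx <- diff(poly[, 1])
  dy <- diff(poly[, 2])
  sum(sqrt(dx^2 + dy^2))
}

#' Position at arc-length distance along a polyline
#' @param poly two-column matrix of projected vertices (m).
#' @param d arc-length offsets from the first vertex (m), clamped to the line.
#' @return two-column matrix of coordinates.
#' @keywords internal
polyline_point_at <- function(poly, d) {
  seglen <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  d <- pmin(pmax(d, 0), total)
  out <- matrix(NA_real_, length(d), 2)
  for (i in seq_along(d)) {
    j <- max(1L, findInterval(d[i], cum, rightmost.closed = TRUE))
    j <- min(j, length(seglen))
    t <- if (seglen[j] > 0) (d[i] - cum[j]) / seglen[j] else 0
    out[i, ] <- poly[j, ] + t * (poly[j + 1L, ] - poly[j, ])
  }
  out
}
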