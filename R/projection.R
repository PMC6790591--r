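# Coordinate projection. Only WGS84 geographic (EPSG:4326) and WGS84/UTM
# zones (EPSG 326xx north, 327xx south) are supported: no PROJ-backed package
# is available, so the transverse Mercator mapping is computed directly from
# the standard series expansions (WGS84 ellipsoid, k0 = 0.9996).

.WGS84 <- list(a = 6378137, f = 1 / 298.257223563)

#' Project coordinates to WGS84 longitude/latitude
#'
#' Supported input systems: EPSG:4326 (identity) and WGS84/UTM zones
#' (EPSG 32601-32660 north, 32701-32760 south). Any other EPSG code is an
#' error: general projection support would require a PROJ library.
#'
#' @param points two-column matrix or data.frame of (x, y) coordinates.
#' @param epsg_in integer EPSG code of the input system.
#' @return data.frame with columns `lon`, `lat` in degrees (EPSG:4326).
#' @export
project_coordinates <- function(points, epsg_in) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L)
  epsg_in <- as.integer(epsg_in)
  if (epsg_in == 4326L)
    return(data.frame(lon = pts[, 1L], lat = pts[, 2L]))
  if (epsg_in %in% 32601:32660 || epsg_in %in% 32701:32760) {
    south <- epsg_in > 32700L
    zone <- epsg_in - if (south) 32700L else 32600L
    ll <- .utm_inverse(pts[, 1L], pts[, 2L], zone, south)
    return(data.frame(lon = ll$lon, lat = ll$lat))
  }
  stop("unsupported EPSG code: ", epsg_in,
       " (supported: 4326 and WGS84/UTM 326xx/327xx)")
}

# Forward transverse Mercator (lon/lat degrees -> UTM metres); used by tests
# for the round-trip property and exported for completeness.
#' @rdname project_coordinates
#' @param lon,lat coordinates in degrees.
#' @param zone UTM zone number (1-60).
#' @param south logical; TRUE for the southern-hemisphere variant.
#' @export
utm_forward <- function(lon, lat, zone, south = FALSE) {
  a <- .WGS84$a; f <- .WGS84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  lam0 <- (-183 + 6 * zone) * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)
  M <- .meridian_arc(phi, a, e2)
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                   (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
                                   (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                                   (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) y <- y + 1e7
  data.frame(x = x, y = y)
}

.meridian_arc <- function(phi, a, e2) {
  a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
         (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
         (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
         (35 * e2^3 / 3072) * sin(6 * phi))
}

.utm_inverse <- function(x, y, zone, south = FALSE) {
  a <- .WGS84$a; f <- .WGS84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  x <- x - 500000
  if (south) y <- y - 1e7
  M <- y / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  C1 <- ep2 * cos(phi1)^2
  T1 <- tan(phi1)^2
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- x / (N1 * k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam0 <- (-183 + 6 * zone) * pi / 180
  lam <- lam0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
                   (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
                     D^5 / 120) / cos(phi1)
  list(lon = lam * 180 / pi, lat = phi * 180 / pi)
}
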