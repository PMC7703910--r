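# Transverse Mercator (UTM) on the WGS84 ellipsoid, 6th-order Krueger series.
# Sub-millimetre accuracy within a UTM zone; more than enough for 100-m grid
# cells and 15-m collar error.

.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

.tm_consts <- local({
  f <- .wgs84$f
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  list(
    n = n,
    e = sqrt(f * (2 - f)),
    A = .wgs84$a / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256),
    alpha = c(
      n / 2 - 2 * n2 / 3 + 5 * n3 / 16 + 41 * n4 / 180 - 127 * n5 / 288 +
        7891 * n6 / 37800,
      13 * n2 / 48 - 3 * n3 / 5 + 557 * n4 / 1440 + 281 * n5 / 630 -
        1983433 * n6 / 1935360,
      61 * n3 / 240 - 103 * n4 / 140 + 15061 * n5 / 26880 +
        167603 * n6 / 181440,
      49561 * n4 / 161280 - 179 * n5 / 168 + 6601661 * n6 / 7257600,
      34729 * n5 / 80640 - 3418889 * n6 / 1995840,
      212378941 * n6 / 319334400),
    beta = c(
      n / 2 - 2 * n2 / 3 + 37 * n3 / 96 - n4 / 360 - 81 * n5 / 512 +
        96199 * n6 / 604800,
      n2 / 48 + n3 / 15 - 437 * n4 / 1440 + 46 * n5 / 105 -
        1118711 * n6 / 3870720,
      17 * n3 / 480 - 37 * n4 / 840 - 209 * n5 / 4480 + 5569 * n6 / 90720,
      4397 * n4 / 161280 - 11 * n5 / 504 - 830251 * n6 / 7257600,
      4583 * n5 / 161280 - 108847 * n6 / 3991680,
      20648693 * n6 / 638668800)
  )
})

.utm_k0 <- 0.9996
.utm_false_easting <- 5e5
.utm_false_northing_south <- 1e7

#' UTM zone of a longitude
#'
#' @param lon longitude in degrees, may be a vector.
#' @return integer zone number(s) in 1..60.
#' @export
utm_zone <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

#' Project geographic coordinates to UTM
#'
#' Forward transverse-Mercator projection on the WGS84 ellipsoid with the
#' standard UTM scale factor and false origins.
#'
#' @param lon,lat coordinates in degrees (vectors of equal length).
#' @param zone UTM zone number (1-60).
#' @param hemisphere `"N"` or `"S"`; controls the false northing.
#' @return data.frame with columns `x`, `y` (meters).
#' @export
utm_forward <- function(lon, lat, zone, hemisphere = "N") {
  stopifnot(length(lon) == length(lat))
  bad <- which(!is.finite(lon) | !is.finite(lat) |
                 abs(lat) > 84 | abs(lon) > 180)
  if (length(bad))
    stop("coordinates outside projection validity at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  k <- .tm_consts
  lam0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lam0
  s <- sin(phi)
  t <- sinh(atanh(s) - (2 * sqrt(k$n) / (1 + k$n)) *
              atanh((2 * sqrt(k$n) / (1 + k$n)) * s))
  xip <- atan2(t, cos(lam))
  etap <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xip
  eta <- etap
  for (j in 1:6) {
    xi <- xi + k$alpha[j] * sin(2 * j * xip) * cosh(2 * j * etap)
    eta <- eta + k$alpha[j] * cos(2 * j * xip) * sinh(2 * j * etap)
  }
  x <- .utm_false_easting + .utm_k0 * k$A * eta
  y <- .utm_k0 * k$A * xi
  if (hemisphere == "S") y <- y + .utm_false_northing_south
  data.frame(x = x, y = y)
}

#' Inverse UTM projection
#'
#' @param x,y projected coordinates in meters.
#' @inheritParams utm_forward
#' @return data.frame with columns `lon`, `lat` (degrees).
#' @export
utm_inverse <- function(x, y, zone, hemisphere = "N") {
  k <- .tm_consts
  lam0 <- (zone * 6 - 183) * pi / 180
  if (hemisphere == "S") y <- y - .utm_false_northing_south
  xi <- y / (.utm_k0 * k$A)
  eta <- (x - .utm_false_easting) / (.utm_k0 * k$A)
  xip <- xi
  etap <- eta
  for (j in 1:6) {
    xip <- xip - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    etap <- etap - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  taup <- sin(xip) / sqrt(sinh(etap)^2 + cos(xip)^2)
  lam <- atan2(sinh(etap), cos(xip))
  # conformal -> geodetic latitude by fixed-point iteration
  chi <- atan(taup)
  e <- k$e
  phi <- chi
  for (i in 1:25) {
    phi_new <- 2 * atan(tan(pi / 4 + chi / 2) *
                          ((1 + e * sin(phi)) / (1 - e * sin(phi)))^(e / 2)) -
      pi / 2
    if (max(abs(phi_new - phi)) < 1e-14) { phi <- phi_new; break }
    phi <- phi_new
  }
  data.frame(lon = (lam + lam0) * 180 / pi, lat = phi * 180 / pi)
}
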