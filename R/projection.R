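# Ellipsoidal Lambert azimuthal equal-area projection (oblique aspect).
# Defaults reproduce the European standard equal-area CRS ETRS89-LAEA
# (EPSG:3035): GRS80 ellipsoid, projection centre 52N 10E, false easting
# 4321000 m, false northing 3210000 m.

.GRS80_A <- 6378137
.GRS80_E2 <- {
  f <- 1 / 298.257222101
  f * (2 - f)
}

#' Parameters of a Lambert azimuthal equal-area CRS
#'
#' Bundles the projection centre and false origin of an oblique ellipsoidal
#' Lambert azimuthal equal-area (LAEA) projection on the GRS80 ellipsoid.
#' The default is the standard European equal-area grid CRS, ETRS89-LAEA
#' (EPSG:3035).
#'
#' @param lon0,lat0 Projection centre in decimal degrees.
#' @param false_easting,false_northing False origin in metres.
#' @param name Label carried into output metadata.
#' @return A list of class `laea_crs`.
#' @export
laea_crs <- function(lon0 = 10, lat0 = 52,
                     false_easting = 4321000, false_northing = 3210000,
                     name = "EPSG:3035") {
  structure(
    list(lon0 = lon0, lat0 = lat0,
         false_easting = false_easting, false_northing = false_northing,
         name = name),
    class = "laea_crs"
  )
}

# authalic latitude machinery (Snyder 1987, eqs. 3-12, 3-11, 24-19/24-20)
.q_auth <- function(phi, e2) {
  e <- sqrt(e2)
  s <- sin(phi)
  (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
}

.beta_from_phi <- function(phi, e2) {
  qp <- .q_auth(pi / 2, e2)
  asin(pmin(1, pmax(-1, .q_auth(phi, e2) / qp)))
}

.phi_from_beta <- function(beta, e2) {
  beta +
    (e2 / 3 + 31 * e2^2 / 180 + 517 * e2^3 / 5040) * sin(2 * beta) +
    (23 * e2^2 / 360 + 251 * e2^3 / 3780) * sin(4 * beta) +
    (761 * e2^3 / 45360) * sin(6 * beta)
}

.laea_const <- function(crs) {
  e2 <- .GRS80_E2
  a <- .GRS80_A
  phi1 <- crs$lat0 * pi / 180
  qp <- .q_auth(pi / 2, e2)
  beta1 <- asin(.q_auth(phi1, e2) / qp)
  rq <- a * sqrt(qp / 2)
  m1 <- cos(phi1) / sqrt(1 - e2 * sin(phi1)^2)
  d <- a * m1 / (rq * cos(beta1))
  list(e2 = e2, a = a, lam0 = crs$lon0 * pi / 180,
       beta1 = beta1, rq = rq, d = d, qp = qp)
}

#' Project geographic coordinates to the equal-area plane
#'
#' Forward Lambert azimuthal equal-area projection. Vectorised over
#' coordinates.
#'
#' @param lon,lat WGS84/ETRS89 decimal degrees.
#' @param crs A [laea_crs()] object.
#' @return A data.frame with columns `x`, `y` in metres.
#' @export
laea_project <- function(lon, lat, crs = laea_crs()) {
  stopifnot(length(lon) == length(lat))
  k <- .laea_const(crs)
  lam <- lon * pi / 180
  beta <- .beta_from_phi(lat * pi / 180, k$e2)
  dl <- lam - k$lam0
  b <- k$rq * sqrt(2 / (1 + sin(k$beta1) * sin(beta) +
                          cos(k$beta1) * cos(beta) * cos(dl)))
  x <- b * k$d * cos(beta) * sin(dl)
  y <- (b / k$d) * (cos(k$beta1) * sin(beta) -
                      sin(k$beta1) * cos(beta) * cos(dl))
  data.frame(x = x + crs$false_easting, y = y + crs$false_northing)
}

#' Inverse-project planar coordinates to geographic
#'
#' @param x,y Projected coordinates in metres.
#' @param crs A [laea_crs()] object.
#' @return A data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
laea_unproject <- function(x, y, crs = laea_crs()) {
  stopifnot(length(x) == length(y))
  k <- .laea_const(crs)
  xr <- (x - crs$false_easting) / k$d
  yr <- (y - crs$false_northing) * k$d
  rho <- sqrt(xr^2 + yr^2)
  ce <- 2 * asin(pmin(1, rho / (2 * k$rq)))
  beta <- ifelse(
    rho == 0, k$beta1,
    asin(cos(ce) * sin(k$beta1) + yr * sin(ce) * cos(k$beta1) / rho)
  )
  lam <- k$lam0 + atan2(
    xr * sin(ce),
    rho * cos(k$beta1) * cos(ce) - yr * sin(k$beta1) * sin(ce)
  )
  data.frame(lon = lam * 180 / pi, lat = .phi_from_beta(beta, k$e2) * 180 / pi)
}
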