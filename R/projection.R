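# Spherical Albers equal-area conic projection (authalic sphere).
# Home-range areas must be computed on an equal-area surface; the Albers
# conic with standard parallels bracketing the data's latitude span keeps
# local area distortion negligible over a study window a few degrees wide.

AUTHALIC_R <- 6371007.181

#' Albers equal-area projection specification
#'
#' @param standard_parallels two latitudes (deg) bracketing the data.
#' @param central_meridian longitude of origin (deg).
#' @param latitude_of_origin latitude of origin (deg).
#' @return object of class `projection_spec`.
#' @export
projection_spec <- function(standard_parallels, central_meridian, latitude_of_origin) {
  stopifnot(length(standard_parallels) == 2)
  phi1 <- standard_parallels[1] * pi / 180
  phi2 <- standard_parallels[2] * pi / 180
  n <- (sin(phi1) + sin(phi2)) / 2
  if (abs(n) < 1e-12) stop("standard parallels must not be symmetric about the equator", call. = FALSE)
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  phi0 <- latitude_of_origin * pi / 180
  rho0 <- AUTHALIC_R * sqrt(C - 2 * n * sin(phi0)) / n
  structure(list(standard_parallels = standard_parallels,
                 central_meridian = central_meridian,
                 latitude_of_origin = latitude_of_origin,
                 n = n, C = C, rho0 = rho0),
            class = "projection_spec")
}

#' Projection for the nominal study window (40.2-40.5 N, 42.4-42.8 E)
#' @export
study_projection <- function() {
  projection_spec(standard_parallels = c(40.25, 40.45),
                  central_meridian = 42.6, latitude_of_origin = 40.2)
}

#' Build a projection whose parallels bracket a point set
#'
#' Standard parallels at 1/6 from each end of the latitude span (the usual
#' rule of thumb for conic projections).
#' @param lon,lat coordinates (deg WGS84).
#' @export
projection_for <- function(lon, lat) {
  span <- range(lat, na.rm = TRUE)
  d <- max(diff(span), 1e-3)
  projection_spec(standard_parallels = c(span[1] + d / 6, span[2] - d / 6),
                  central_meridian = mean(range(lon, na.rm = TRUE)),
                  latitude_of_origin = span[1])
}

#' Forward Albers projection
#' @param lon,lat degrees WGS84.
#' @param spec a [projection_spec()].
#' @return list with `x`, `y` in metres.
#' @export
albers_forward <- function(lon, lat, spec) {
  phi <- lat * pi / 180
  theta <- spec$n * (lon - spec$central_meridian) * pi / 180
  rho <- AUTHALIC_R * sqrt(spec$C - 2 * spec$n * sin(phi)) / spec$n
  list(x = rho * sin(theta), y = spec$rho0 - rho * cos(theta))
}

#' Inverse Albers projection
#' @param x,y metres.
#' @param spec a [projection_spec()].
#' @return list with `lon`, `lat` in degrees.
#' @export
albers_inverse <- function(x, y, spec) {
  rho <- sqrt(x^2 + (spec$rho0 - y)^2)
  theta <- atan2(x, spec$rho0 - y)
  if (spec$n < 0) {
    rho <- -rho
    theta <- atan2(-x, -(spec$rho0 - y))
  }
  phi <- asin((spec$C - (rho * spec$n / AUTHALIC_R)^2) / (2 * spec$n))
  list(lon = spec$central_meridian + theta / spec$n * 180 / pi,
       lat = phi * 180 / pi)
}

#' Project a cleaned trajectory to planar metres
#'
#' @param traj data.frame with `lon`, `lat` columns (deg WGS84).
#' @param spec a [projection_spec()]; default brackets the trajectory.
#' @return the trajectory with planar `x`, `y` columns (m) appended.
#' @export
project_trajectory <- function(traj, spec = NULL) {
  if (is.null(spec)) spec <- projection_for(traj$lon, traj$lat)
  xy <- albers_forward(traj$lon, traj$lat, spec)
  traj$x <- xy$x
  traj$y <- xy$y
  attr(traj, "projection") <- spec
  traj
}
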