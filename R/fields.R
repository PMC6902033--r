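#' Analytic velocity fields with closed-form behaviour
#'
#' Three flows used as integration oracles:
#'
#' * `uniform`: constant `(u0, v0)` everywhere. A particle released at
#'   latitude phi drifts `u0 * T / (R cos phi) * 180/pi` degrees of longitude
#'   over time `T` (and `v0 * T / R * 180/pi` degrees of latitude).
#' * `solid_rotation`: rotation about `center` in the longitude/latitude
#'   coordinate plane at angular rate `omega` (s^-1, positive
#'   anticlockwise). The stored eastward velocity carries a `cos(lat)`
#'   factor so that under the spherical advection equations the trajectory
#'   is an exact circle in degree space: coordinate-space radius
#'   `sqrt(dlon^2 + dlat^2)` is conserved and the closed form is available
#'   via [closed_form_trajectory()].
#' * `double_gyre`: the standard periodically perturbed two-cell
#'   recirculation on a rectangle, defined through its stream function on a
#'   local constant-metric (f-plane) projection, hence divergence-free
#'   there. Parameters `A` (m s^-1 scale), `eps` (perturbation amplitude),
#'   `period` (s).
#'
#' @param kind one of `"uniform"`, `"solid_rotation"`, `"double_gyre"`.
#' @param params named list of flow parameters (see Details above):
#'   uniform: `u0`, `v0`; solid_rotation: `center`, `omega`; double_gyre:
#'   `lon_range`, `lat_range`, `A`, `eps`, `period`.
#' @return an object of class `analytic_field` with element `fn(lon, lat, t)`
#'   returning `list(u, v)` in m s^-1.
#' @export
analytic_field <- function(kind = c("uniform", "solid_rotation",
                                    "double_gyre"),
                           params = list()) {
  kind <- match.arg(kind)
  fn <- switch(kind,
    uniform = {
      u0 <- params$u0 %||% 0.1
      v0 <- params$v0 %||% 0
      function(lon, lat, t) {
        list(u = rep(u0, length(lon)), v = rep(v0, length(lon)))
      }
    },
    solid_rotation = {
      ctr <- params$center %||% c(145, 30)
      omega <- params$omega %||% 5e-6
      k <- pi / 180 * EARTH_RADIUS_M
      function(lon, lat, t) {
        list(u = -omega * (lat - ctr[2]) * k * cos(lat / DEG_PER_RAD),
             v = omega * (lon - ctr[1]) * k)
      }
    },
    double_gyre = {
      lon_range <- params$lon_range %||% c(143, 147)
      lat_range <- params$lat_range %||% c(28, 32)
      A <- params$A %||% 0.1
      eps <- params$eps %||% 0.25
      period <- params$period %||% (20 * 86400)
      # constant-metric projection at the domain's central latitude
      latc <- mean(lat_range)
      mx <- pi / 180 * EARTH_RADIUS_M * cos(latc / DEG_PER_RAD)
      my <- pi / 180 * EARTH_RADIUS_M
      Lx <- (lon_range[2] - lon_range[1]) * mx
      Ly <- (lat_range[2] - lat_range[1]) * my
      function(lon, lat, t) {
        x <- (lon - lon_range[1]) * mx / Lx * 2  # in [0, 2]
        y <- (lat - lat_range[1]) * my / Ly      # in [0, 1]
        at <- eps * sin(2 * pi * t / period)
        bt <- 1 - 2 * at
        f <- at * x^2 + bt * x
        fx <- 2 * at * x + bt
        list(u = -pi * A * sin(pi * f) * cos(pi * y),
             v = pi * A * cos(pi * f) * sin(pi * y) * fx * 2 * Ly / Lx)
      }
    })
  structure(list(kind = kind, params = params, fn = fn),
            class = "analytic_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form trajectory of an analytic flow
#'
#' Exact particle position under the `uniform` and `solid_rotation` flows
#' (the double gyre has no closed form). Negative `t` queries the backward
#' trajectory.
#'
#' @param field an [analytic_field()] (or a [generate_field()] output, whose
#'   oracle record is used).
#' @param lon0,lat0 release position (degrees).
#' @param t elapsed time in seconds (vectorised; negative = backward).
#' @return data frame `t`, `lon`, `lat`.
#' @export
closed_form_trajectory <- function(field, lon0, lat0, t) {
  if (inherits(field, "velocity_field")) field <- attr(field, "oracle")
  stopifnot(inherits(field, "analytic_field"))
  if (field$kind == "uniform") {
    u0 <- field$params$u0 %||% 0.1
    v0 <- field$params$v0 %||% 0
    lat <- lat0 + v0 * t / EARTH_RADIUS_M * DEG_PER_RAD
    if (abs(v0) > 0) stop("uniform closed form requires v0 = 0 (cos(lat) varies)")
    lon <- lon0 + u0 * t / (EARTH_RADIUS_M * cos(lat0 / DEG_PER_RAD)) *
      DEG_PER_RAD
    return(data.frame(t = t, lon = lon, lat = lat))
  }
  if (field$kind == "solid_rotation") {
    ctr <- field$params$center %||% c(145, 30)
    omega <- field$params$omega %||% 5e-6
    dx <- lon0 - ctr[1]; dy <- lat0 - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    th0 <- atan2(dy, dx)
    return(data.frame(t = t,
                      lon = ctr[1] + r * cos(omega * t + th0),
                      lat = ctr[2] + r * sin(omega * t + th0)))
  }
  stop("no closed-form trajectory for kind '", field$kind, "'")
}

#' Sample an analytic flow onto a regular grid
#'
#' Builds a [velocity_field()] by evaluating an [analytic_field()] at the
#' grid nodes. The analytic definition is attached as attribute `"oracle"`,
#' so every generated field carries its own closed-form reference (see
#' [closed_form_trajectory()]).
#'
#' @param kind,params passed to [analytic_field()].
#' @param lon_range,lat_range domain extent in degrees.
#' @param spacing grid spacing in degrees (default 0.1, eddy-resolving
#'   reanalysis scale).
#' @param levels depth levels (m) to replicate the 2-D flow onto.
#' @param times snapshot instants (s).
#' @param land optional function `(lon, lat) -> logical` marking land cells
#'   (applied at all levels).
#' @param steady see [velocity_field()].
#' @return a [velocity_field()] with attribute `oracle` (the
#'   [analytic_field()]).
#' @export
generate_field <- function(kind = c("uniform", "solid_rotation",
                                    "double_gyre"),
                           params = list(),
                           lon_range = c(143, 147), lat_range = c(28, 32),
                           spacing = 0.1, levels = 0, times = 0,
                           land = NULL, steady = TRUE) {
  kind <- match.arg(kind)
  af <- analytic_field(kind, params)
  lons <- seq(lon_range[1], lon_range[2], by = spacing)
  lats <- seq(lat_range[1], lat_range[2], by = spacing)
  g <- expand.grid(lon = lons, lat = lats)
  nx <- length(lons); ny <- length(lats)
  nl <- length(levels); nt <- length(times)
  u <- array(NA_real_, c(nx, ny, nl, nt))
  v <- array(NA_real_, c(nx, ny, nl, nt))
  for (it in seq_len(nt)) {
    uv <- af$fn(g$lon, g$lat, times[it])
    for (il in seq_len(nl)) {
      u[, , il, it] <- uv$u
      v[, , il, it] <- uv$v
    }
  }
  mask <- array(TRUE, c(nx, ny, nl))
  if (!is.null(land)) {
    landgrid <- matrix(land(g$lon, g$lat), nx, ny)
    for (il in seq_len(nl)) mask[, , il] <- !landgrid
  }
  fld <- velocity_field(lons, lats, levels, times, u, v, mask, steady = steady)
  attr(fld, "oracle") <- af
  fld
}
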