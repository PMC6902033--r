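# Mean Earth radius (m); spherical Earth, no ellipsoid.
EARTH_RADIUS_M <- 6371000
DEG_PER_RAD <- 180 / pi

#' Seed a square particle grid
#'
#' Regular square grid centred on a station, extending `half_width` degrees in
#' each cardinal direction with node spacing `spacing` on both axes, giving
#' `(2 * half_width / spacing + 1)^2` particles.
#'
#' @param center numeric `c(lon, lat)` in degrees.
#' @param half_width extent (degrees) from the centre in each direction;
#'   must be an integer multiple of `spacing` (within 1e-9).
#' @param spacing node spacing in degrees (> 0).
#' @param level depth level (m) the particles live on.
#' @param t0 release instant (s), the start of a backward run.
#' @return an object of class `particle_set`: data frame of `lon`, `lat` with
#'   attributes `level` and `t0`.
#' @examples
#' nrow(seed_grid(c(145, 30), 0.25, 0.025))  # 441
#' @export
seed_grid <- function(center, half_width, spacing, level = 0, t0 = 0) {
  stopifnot(length(center) == 2, half_width >= 0, spacing > 0)
  k <- half_width / spacing
  if (abs(k - round(k)) > 1e-9) {
    stop("half_width must be an integer multiple of spacing")
  }
  off <- seq(-round(k), round(k)) * spacing
  g <- expand.grid(lon = center[1] + off, lat = center[2] + off)
  structure(g, level = level, t0 = t0,
            class = c("particle_set", "data.frame"))
}

# Velocity sampling dispatch: gridded fields are interpolated, analytic
# fields evaluated in closed form.
velocity_eval <- function(field, lon, lat, t, level) {
  UseMethod("velocity_eval")
}

#' @export
velocity_eval.analytic_field <- function(field, lon, lat, t, level) {
  uv <- field$fn(lon, lat, t)
  list(u = uv$u, v = uv$v, status = rep("ok", length(lon)))
}

#' @export
velocity_eval.velocity_field <- function(field, lon, lat, t, level) {
  il <- which(abs(field$levels - level) < 1e-6)
  if (length(il) != 1) stop("level ", level, " m is not stored in the field")
  n <- length(lon)
  status <- rep("ok", n)
  u <- v <- rep(NA_real_, n)

  inside <- lon >= field$lons[1] & lon <= field$lons[length(field$lons)] &
    lat >= field$lats[1] & lat <= field$lats[length(field$lats)]
  tmin <- field$times[1]; tmax <- field$times[length(field$times)]
  if (field$steady) {
    t <- min(max(t, tmin), tmax)
  } else if (t < tmin || t > tmax) {
    status[] <- "exited"
    return(list(u = u, v = v, status = status))
  }
  status[!inside] <- "exited"
  if (!any(inside)) return(list(u = u, v = v, status = status))

  nx <- length(field$lons); ny <- length(field$lats)
  if (nx < 2 || ny < 2) stop("interpolation needs at least a 2 x 2 grid")
  ix <- findInterval(lon[inside], field$lons, rightmost.closed = TRUE)
  iy <- findInterval(lat[inside], field$lats, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L); iy <- pmin(pmax(iy, 1L), ny - 1L)
  wx <- (lon[inside] - field$lons[ix]) / (field$lons[ix + 1] - field$lons[ix])
  wy <- (lat[inside] - field$lats[iy]) / (field$lats[iy + 1] - field$lats[iy])

  nt <- length(field$times)
  if (nt == 1) {
    it <- 1L; wt <- 0
  } else {
    it <- findInterval(t, field$times, rightmost.closed = TRUE)
    it <- min(max(it, 1L), nt - 1L)
    wt <- (t - field$times[it]) / (field$times[it + 1] - field$times[it])
  }

  corner <- function(arr, dx, dy, itt) {
    arr[cbind(ix + dx, iy + dy, il, itt)]
  }
  mask_at <- function(dx, dy) field$mask[cbind(ix + dx, iy + dy, il)]
  m00 <- mask_at(0L, 0L); m10 <- mask_at(1L, 0L)
  m01 <- mask_at(0L, 1L); m11 <- mask_at(1L, 1L)
  w00 <- (1 - wx) * (1 - wy) * m00
  w10 <- wx * (1 - wy) * m10
  w01 <- (1 - wx) * wy * m01
  w11 <- wx * wy * m11
  wsum <- w00 + w10 + w01 + w11
  landlocked <- wsum <= 0

  blend <- function(arr) {
    val <- function(itt) {
      a00 <- corner(arr, 0L, 0L, itt); a00[!m00] <- 0
      a10 <- corner(arr, 1L, 0L, itt); a10[!m10] <- 0
      a01 <- corner(arr, 0L, 1L, itt); a01[!m01] <- 0
      a11 <- corner(arr, 1L, 1L, itt); a11[!m11] <- 0
      (w00 * a00 + w10 * a10 + w01 * a01 + w11 * a11) / wsum
    }
    if (wt == 0) val(it) else (1 - wt) * val(it) + wt * val(it + 1L)
  }
  ui <- blend(field$u); vi <- blend(field$v)
  ui[landlocked] <- NA; vi[landlocked] <- NA
  u[inside] <- ui; v[inside] <- vi
  st <- rep("ok", sum(inside)); st[landlocked] <- "beached"
  status[inside] <- st
  list(u = u, v = v, status = status)
}

#' Interpolate velocity at arbitrary points
#'
#' Bilinear in longitude/latitude and linear in time at a stored depth level
#' (motion is per-level 2-D; there is no vertical interpolation). Weights of
#' land corners are dropped and the remaining sea weights renormalised; a
#' query whose four surrounding corners are all land reports `"beached"`, and
#' a query outside the grid hull (or outside the time range of a non-steady
#' field) reports `"exited"`, both with `NA` velocity.
#'
#' @param field a [velocity_field()] (or analytic field from
#'   [analytic_field()]).
#' @param lon,lat query positions (degrees), vectorised.
#' @param t query instant (s), scalar.
#' @param level a stored depth level (m); an unknown level is an error.
#' @return list of vectors `u`, `v` (m s^-1) and `status` (`"ok"`,
#'   `"beached"`, `"exited"`).
#' @export
interpolate_velocity <- function(field, lon, lat, t, level) {
  velocity_eval(field, lon, lat, t, level)
}

# RK4 advection shared by the backward/forward drivers. Integrates in
# elapsed time tau >= 0 with wall-clock t = t0 + sign * tau.
integrate_particles <- function(field, particles, duration, dt,
                                direction = c("backward", "forward"),
                                store_every = 1L) {
  direction <- match.arg(direction)
  sgn <- if (direction == "backward") -1 else 1
  stopifnot(inherits(particles, "particle_set"))
  if (dt <= 0) stop("dt must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (dt > duration) stop("dt must not exceed duration")
  level <- attr(particles, "level")
  t0 <- attr(particles, "t0")
  if (inherits(field, "velocity_field") && !field$steady) {
    tend <- t0 + sgn * duration
    if (min(t0, tend) < field$times[1] ||
        max(t0, tend) > field$times[length(field$times)]) {
      stop("run leaves the field's time range; use a steady field or extend it")
    }
  }

  n <- nrow(particles)
  lon <- particles$lon; lat <- particles$lat
  status <- rep("active", n)
  frozen_at <- rep(NA_integer_, n)

  # degree-space RHS: d(lon)/dtau, d(lat)/dtau
  rhs <- function(lon, lat, tau, active) {
    out <- matrix(NA_real_, length(lon), 2)
    ok <- rep(TRUE, length(lon)); why <- rep("ok", length(lon))
    idx <- which(active)
    if (!length(idx)) return(list(k = out, ok = ok, why = why))
    ve <- velocity_eval(field, lon[idx], lat[idx], t0 + sgn * tau, level)
    bad <- ve$status != "ok"
    ok[idx[bad]] <- FALSE
    why[idx[bad]] <- ve$status[bad]
    coslat <- cos(lat[idx] / DEG_PER_RAD)
    out[idx, 1] <- sgn * ve$u / (EARTH_RADIUS_M * coslat) * DEG_PER_RAD
    out[idx, 2] <- sgn * ve$v / EARTH_RADIUS_M * DEG_PER_RAD
    list(k = out, ok = ok, why = why)
  }

  n_steps <- ceiling(duration / dt - 1e-9)
  taus <- pmin(seq_len(n_steps) * dt, duration)
  stored <- unique(c(0L, seq_along(taus)[seq_along(taus) %% store_every == 0L],
                     n_steps))
  lon_hist <- matrix(NA_real_, length(stored), n)
  lat_hist <- matrix(NA_real_, length(stored), n)
  lon_hist[1, ] <- lon; lat_hist[1, ] <- lat
  store_row <- 1L

  tau_prev <- 0
  for (s in seq_len(n_steps)) {
    h <- taus[s] - tau_prev
    active <- status == "active"
    if (any(active)) {
      freeze <- function(res) {
        bad <- which(active & !res$ok)
        if (length(bad)) {
          status[bad] <<- res$why[bad]
          frozen_at[bad] <<- s
          active[bad] <<- FALSE
        }
      }
      k1 <- rhs(lon, lat, tau_prev, active); freeze(k1)
      k2 <- rhs(lon + h / 2 * k1$k[, 1], lat + h / 2 * k1$k[, 2],
                tau_prev + h / 2, active); freeze(k2)
      k3 <- rhs(lon + h / 2 * k2$k[, 1], lat + h / 2 * k2$k[, 2],
                tau_prev + h / 2, active); freeze(k3)
      k4 <- rhs(lon + h * k3$k[, 1], lat + h * k3$k[, 2],
                tau_prev + h, active); freeze(k4)
      idx <- which(active)
      if (length(idx)) {
        new_lon <- lon[idx] + h / 6 * (k1$k[idx, 1] + 2 * k2$k[idx, 1] +
                                         2 * k3$k[idx, 1] + k4$k[idx, 1])
        new_lat <- lat[idx] + h / 6 * (k1$k[idx, 2] + 2 * k2$k[idx, 2] +
                                         2 * k3$k[idx, 2] + k4$k[idx, 2])
        probe <- velocity_eval(field, new_lon, new_lat,
                               t0 + sgn * taus[s], level)
        land <- probe$status == "beached"
        out <- probe$status == "exited"
        move <- !(land | out)
        lon[idx[move]] <- new_lon[move]
        lat[idx[move]] <- new_lat[move]
        if (any(land)) {
          status[idx[land]] <- "beached"; frozen_at[idx[land]] <- s
        }
        if (any(out)) {
          status[idx[out]] <- "exited"; frozen_at[idx[out]] <- s
        }
        if (any(!is.finite(new_lon) | !is.finite(new_lat))) {
          bad <- idx[!is.finite(new_lon) | !is.finite(new_lat)]
          status[bad] <- "exited"; frozen_at[bad] <- s
        }
      }
    }
    if (s %in% stored) {
      store_row <- store_row + 1L
      lon_hist[store_row, ] <- lon
      lat_hist[store_row, ] <- lat
    }
    tau_prev <- taus[s]
  }

  structure(list(times = t0 + sgn * c(0, taus[stored[stored > 0]]),
                 lon = lon_hist, lat = lat_hist,
                 stored_steps = stored,
                 status = status, frozen_at = frozen_at,
                 level = level, t0 = t0, dt = dt, duration = duration,
                 direction = direction,
                 seed_lon = particles$lon, seed_lat = particles$lat),
            class = "trajectory_set")
}

#' Integrate particles backward in time
#'
#' Advances particle positions with 4th-order Runge-Kutta on the sphere:
#' d(lon)/dt = -u / (R cos(lat)) * 180/pi, d(lat)/dt = -v / R * 180/pi with
#' R = 6,371,000 m. Purely deterministic (no random-walk diffusion). A
#' particle whose position falls in a fully land-surrounded cell is frozen as
#' `"beached"` at its last sea position; one leaving the grid hull is frozen
#' as `"exited"`.
#'
#' @param field a [velocity_field()] or [analytic_field()].
#' @param particles a [seed_grid()] particle set (carries level and t0).
#' @param duration run length in seconds (> 0).
#' @param dt time step in seconds (0 < dt <= duration).
#' @param store_every store every k-th step (default 1 = every step).
#' @return a `trajectory_set`: stored `times` (strictly decreasing), `lon` and
#'   `lat` matrices (stored step x particle), per-particle `status`, and the
#'   run configuration. Convert with [as.data.frame()].
#' @export
integrate_backward <- function(field, particles, duration, dt,
                               store_every = 1L) {
  integrate_particles(field, particles, duration, dt, "backward", store_every)
}

#' Integrate particles forward in time
#'
#' Forward counterpart of [integrate_backward()] (same scheme, positive time
#' direction); used e.g. to verify backward runs by round-tripping.
#' @inheritParams integrate_backward
#' @return a `trajectory_set` with strictly increasing `times`.
#' @export
integrate_forward <- function(field, particles, duration, dt,
                              store_every = 1L) {
  integrate_particles(field, particles, duration, dt, "forward", store_every)
}

#' Final particle positions of a trajectory set
#' @param traj a `trajectory_set`.
#' @return data frame `lon`, `lat`, `status`.
#' @export
final_positions <- function(traj) {
  k <- nrow(traj$lon)
  data.frame(lon = traj$lon[k, ], lat = traj$lat[k, ], status = traj$status)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  n <- ncol(x$lon); m <- nrow(x$lon)
  status <- matrix("active", m, n)
  for (i in which(!is.na(x$frozen_at))) {
    status[x$stored_steps >= x$frozen_at[i], i] <- x$status[i]
  }
  data.frame(particle_id = rep(seq_len(n), each = m),
             time_s = rep(x$times, n),
             lon = as.vector(x$lon), lat = as.vector(x$lat),
             level_m = x$level,
             status = as.vector(status))
}

#' Write trajectories as CSV
#' @param traj a `trajectory_set` (or data frame already in long form).
#' @param path output path.
#' @export
write_trajectories <- function(traj, path) {
  df <- if (is.data.frame(traj)) traj else as.data.frame(traj)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a multi-month, multi-level backtracking experiment
#'
#' For every sampling instant and depth level, seeds a particle grid around
#' the station and integrates it backward for `duration` seconds. The archive
#' is keyed `"<month>@<level>m"`.
#'
#' @param field a [velocity_field()].
#' @param station `c(lon, lat)` of the station.
#' @param months named numeric vector of sampling instants (s); names label
#'   the runs (e.g. `"2011-02"`).
#' @param levels depth levels (m), each stored in the field.
#' @param duration,dt integration length and step (s); defaults 90 days at
#'   3 h.
#' @param half_width,spacing seeding geometry (degrees), see [seed_grid()].
#' @param store_every thin stored positions (default: store every step).
#' @return list of `trajectory_set`s with a `manifest` attribute recording
#'   the configuration.
#' @export
run_experiment <- function(field, station, months, levels,
                           duration = 90 * 86400, dt = 3 * 3600,
                           half_width = 0.25, spacing = 0.025,
                           store_every = 1L) {
  if (is.null(names(months))) names(months) <- as.character(months)
  missing_lev <- levels[!vapply(levels, function(l) {
    any(abs(field$levels - l) < 1e-6)
  }, logical(1))]
  if (length(missing_lev)) {
    stop("level(s) not stored in field: ", paste(missing_lev, collapse = ", "))
  }
  archive <- list()
  for (m in names(months)) {
    for (lev in levels) {
      p <- seed_grid(station, half_width, spacing, level = lev,
                     t0 = months[[m]])
      archive[[sprintf("%s@%gm", m, lev)]] <-
        integrate_backward(field, p, duration, dt, store_every)
    }
  }
  attr(archive, "manifest") <- list(
    station = station, months = months, levels = levels,
    duration_s = duration, dt_s = dt, half_width_deg = half_width,
    spacing_deg = spacing, scheme = "RK4",
    interpolation = "bilinear space, linear time",
    earth_radius_m = EARTH_RADIUS_M, random_walk = FALSE)
  archive
}
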