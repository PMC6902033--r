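#' Construct a gridded velocity field
#'
#' Container for horizontal ocean velocities on a regular longitude/latitude
#' grid with discrete depth levels and time snapshots, the shape of an
#' eddy-resolving reanalysis product (e.g. 1/10 degree, ~50 levels). Motion is
#' per-level 2-D: there is no vertical velocity.
#'
#' @param lons,lats strictly increasing, uniformly spaced coordinates
#'   (degrees E / N). Uniformity is enforced to 1e-9 degrees.
#' @param levels depth levels in metres.
#' @param times strictly increasing snapshot instants, seconds.
#' @param u,v eastward/northward velocity (m s^-1), arrays of dimension
#'   `c(length(lons), length(lats), length(levels), length(times))`. `NA`
#'   marks land.
#' @param mask logical array `lon x lat x level`, `TRUE` for sea. `NULL`
#'   infers sea where `u` and `v` are finite at the first snapshot.
#' @param steady logical; if `TRUE` the field is treated as frozen outside its
#'   time range (queries clamp to the nearest snapshot). If `FALSE`, leaving
#'   the time range during integration is an error.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(lons, lats, levels, times, u, v, mask = NULL,
                           steady = length(times) == 1L) {
  dims <- c(length(lons), length(lats), length(levels), length(times))
  check_axis <- function(x, name, uniform = TRUE) {
    if (length(x) < 1 || any(!is.finite(x))) stop(name, " must be finite")
    if (length(x) > 1) {
      d <- diff(x)
      if (any(d <= 0)) stop(name, " must be strictly increasing")
      if (uniform && diff(range(d)) > 1e-9) {
        stop(name, " spacing must be uniform within 1e-9")
      }
    }
  }
  check_axis(lons, "lons"); check_axis(lats, "lats")
  check_axis(times, "times", uniform = FALSE)
  if (!identical(dim(u), dims) || !identical(dim(v), dims)) {
    stop("u and v must have dimension lon x lat x level x time = ",
         paste(dims, collapse = " x "))
  }
  if (is.null(mask)) {
    mask <- is.finite(u[, , , 1, drop = FALSE]) &
      is.finite(v[, , , 1, drop = FALSE])
    dim(mask) <- dims[1:3]
  }
  if (!identical(dim(mask), dims[1:3])) {
    stop("mask must have dimension lon x lat x level")
  }
  sea <- as.vector(mask)
  for (it in seq_along(times)) {
    ut <- u[, , , it]; vt <- v[, , , it]
    if (any(!is.finite(ut[sea])) || any(!is.finite(vt[sea]))) {
      stop("u/v must be finite on sea cells (snapshot ", it, ")")
    }
  }
  structure(list(lons = lons, lats = lats, levels = levels, times = times,
                 u = u, v = v, mask = mask, steady = steady),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "velocity_field: %d x %d grid (%.4g deg), %d level(s), %d time(s), %s\n",
    length(x$lons), length(x$lats),
    if (length(x$lons) > 1) x$lons[2] - x$lons[1] else NA_real_,
    length(x$levels), length(x$times),
    if (x$steady) "steady" else "time-varying"))
  invisible(x)
}

#' Write a velocity field to NetCDF
#'
#' CF-style layout: dimensions `lon`, `lat`, `level`, `time`; variables `u`
#' and `v` in m s^-1 with land stored as the fill value.
#'
#' @param field a [velocity_field()].
#' @param path output NetCDF path.
#' @export
write_velocity_field <- function(field, path) {
  dl <- ncdf4::ncdim_def("lon", "degrees_east", field$lons)
  dp <- ncdf4::ncdim_def("lat", "degrees_north", field$lats)
  dz <- ncdf4::ncdim_def("level", "meters", field$levels)
  dt <- ncdf4::ncdim_def("time", "seconds", field$times, unlim = TRUE)
  fill <- 9.96921e36
  vu <- ncdf4::ncvar_def("u", "m s-1", list(dl, dp, dz, dt), fill,
                         prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s-1", list(dl, dp, dz, dt), fill,
                         prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv))
  on.exit(ncdf4::nc_close(nc))
  land <- !field$mask
  u <- field$u; v <- field$v
  for (it in seq_along(field$times)) {
    ut <- u[, , , it]; vt <- v[, , , it]
    ut[land] <- NA; vt[land] <- NA
    u[, , , it] <- ut; v[, , , it] <- vt
  }
  ncdf4::ncvar_put(nc, vu, u)
  ncdf4::ncvar_put(nc, vv, v)
  invisible(path)
}

#' Read a velocity field from NetCDF
#'
#' Expects longitude/latitude/level/time coordinates (common aliases such as
#' `longitude`, `latitude`, `depth`, `lev` are recognised) and `u`, `v`
#' variables in m s^-1. Land is inferred from fill values / NA when no
#' explicit mask variable is present.
#'
#' @param path NetCDF path.
#' @param steady see [velocity_field()].
#' @return a [velocity_field()].
#' @export
read_velocity_field <- function(path, steady = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  dimnames_nc <- names(nc$dim)
  find_dim <- function(aliases, what) {
    hit <- intersect(aliases, dimnames_nc)
    if (!length(hit)) stop("missing coordinate: ", what)
    nc$dim[[hit[1]]]$vals
  }
  lons <- find_dim(c("lon", "longitude", "x"), "lon")
  lats <- find_dim(c("lat", "latitude", "y"), "lat")
  levels <- find_dim(c("level", "depth", "lev", "z"), "level")
  times <- find_dim(c("time", "t"), "time")
  for (v in c("u", "v")) {
    if (!v %in% names(nc$var)) stop("missing variable: ", v)
  }
  dims <- c(length(lons), length(lats), length(levels), length(times))
  u <- ncdf4::ncvar_get(nc, "u", collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, "v", collapse_degen = FALSE)
  dim(u) <- dims; dim(v) <- dims
  mask <- NULL
  if ("mask" %in% names(nc$var)) {
    mask <- ncdf4::ncvar_get(nc, "mask", collapse_degen = FALSE) > 0
    dim(mask) <- dims[1:3]
  }
  if (any(diff(lons) <= 0)) stop("non-monotone coordinate: lon")
  if (any(diff(lats) <= 0)) stop("non-monotone coordinate: lat")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("non-monotone coordinate: time")
  }
  if (is.null(steady)) steady <- length(times) == 1L
  velocity_field(lons, lats, levels, times, u, v, mask, steady = steady)
}
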