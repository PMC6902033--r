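#' Depth-zone configuration
#'
#' Boundaries binning sampled depths (metres) into the oceanographic zones
#' used throughout the package. The surface layer is the upper part of the
#' epipelagic zone (the depth range mixed with the atmosphere on the sampling
#' date); in well-mixed winter months it can extend deeper, which is expressed
#' with a per-month override.
#'
#' Convention: `depth <= surface_max` is `"surface"`, `depth <= epipelagic_max`
#' is `"epipelagic"`, `depth < mesopelagic_max` is `"mesopelagic"`,
#' `depth < bathypelagic_max` is `"bathypelagic"`, deeper is `"abyssopelagic"`.
#' The shallow boundaries (50, 300 m) are inclusive; 1,000 m and 5,000 m belong
#' to the deeper zone, matching the standard definitions of the bathypelagic
#' (1,000-4,000 m) and the abyssal sampling range.
#'
#' @param surface_max maximum depth (m) of the surface layer. Default 50.
#' @param epipelagic_max maximum depth (m) of the epipelagic zone. Default 300.
#' @param mesopelagic_max exclusive upper depth (m) of the mesopelagic zone;
#'   depths at or beyond it are bathypelagic. Default 1000.
#' @param bathypelagic_max exclusive upper depth (m) of the bathypelagic zone;
#'   depths at or beyond it are abyssopelagic. Default 5000.
#' @param surface_max_by_month named numeric vector of per-month overrides of
#'   `surface_max` (e.g. `c("2011-02" = 100)` for a deeply mixed February).
#' @param month_order character vector giving the total order of month labels,
#'   earliest first. Month labels are opaque: no date parsing is attempted.
#'   `NULL` means "order of first appearance in the metadata".
#' @return an object of class `zone_config`.
#' @seealso [assign_zone()]
#' @export
zone_config <- function(surface_max = 50, epipelagic_max = 300,
                        mesopelagic_max = 1000, bathypelagic_max = 5000,
                        surface_max_by_month = c("2011-02" = 100),
                        month_order = NULL) {
  stopifnot(surface_max > 0, epipelagic_max > surface_max,
            mesopelagic_max > epipelagic_max,
            bathypelagic_max > mesopelagic_max)
  structure(list(surface_max = surface_max,
                 epipelagic_max = epipelagic_max,
                 mesopelagic_max = mesopelagic_max,
                 bathypelagic_max = bathypelagic_max,
                 surface_max_by_month = surface_max_by_month,
                 month_order = month_order),
            class = "zone_config")
}

#' Ordered zone labels, shallowest first
#' @export
zone_levels <- function() {
  c("surface", "epipelagic", "mesopelagic", "bathypelagic", "abyssopelagic")
}

#' Assign depth zones
#'
#' Maps sampled depths to zone labels under a [zone_config()]. Total over
#' nonnegative depths: every depth receives exactly one zone.
#'
#' @param depth_m numeric vector of depths in metres (>= 0).
#' @param month optional vector of month labels (recycled), used only for
#'   per-month surface-layer overrides.
#' @param config a [zone_config()].
#' @return character vector of zone labels.
#' @examples
#' assign_zone(c(5, 200, 500, 1000, 5000))
#' assign_zone(75, month = "2011-02")  # deep winter mixed layer -> surface
#' @export
assign_zone <- function(depth_m, month = NULL, config = zone_config()) {
  stopifnot(inherits(config, "zone_config"))
  if (any(!is.finite(depth_m)) || any(depth_m < 0)) {
    stop("depth_m must be finite and >= 0")
  }
  smax <- rep(config$surface_max, length(depth_m))
  if (!is.null(month) && length(config$surface_max_by_month)) {
    month <- rep_len(as.character(month), length(depth_m))
    hit <- match(month, names(config$surface_max_by_month))
    smax[!is.na(hit)] <- config$surface_max_by_month[hit[!is.na(hit)]]
  }
  ifelse(depth_m <= smax, "surface",
    ifelse(depth_m <= config$epipelagic_max, "epipelagic",
      ifelse(depth_m < config$mesopelagic_max, "mesopelagic",
        ifelse(depth_m < config$bathypelagic_max, "bathypelagic",
               "abyssopelagic"))))
}
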