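#' Instrument geometry
#'
#' Fixed geometry of an almucantar-scanning lidar: the constant view zenith
#' angle, the height of the instrument above the ground, and the maximum
#' range at which live foliage returns a valid measurement (night-time
#' detection limit of the rangefinder).
#'
#' @param zenith View zenith angle in degrees, in (0, 90). Default the hinge
#'   angle, 57.5.
#' @param instrument_height Height of the scan head above ground in metres
#'   (default 1.5, a typical pole mount).
#' @param max_detect_range Maximum range (m) at which a target still returns
#'   a valid range; beyond it the shot is recorded as a gap. Default 60.
#' @return An object of class `instrument_geometry`.
#' @export
instrument_geometry <- function(zenith = HINGE_ANGLE,
                                instrument_height = 1.5,
                                max_detect_range = 60) {
  if (!is.numeric(zenith) || length(zenith) != 1L || zenith <= 0 || zenith >= 90)
    stop("`zenith` must be a single angle in (0, 90) degrees", call. = FALSE)
  if (!is.numeric(instrument_height) || instrument_height < 0)
    stop("`instrument_height` must be >= 0", call. = FALSE)
  if (!is.numeric(max_detect_range) || max_detect_range <= 0)
    stop("`max_detect_range` must be > 0", call. = FALSE)
  structure(
    list(zenith = zenith,
         instrument_height = instrument_height,
         max_detect_range = max_detect_range),
    class = "instrument_geometry"
  )
}

#' @export
print.instrument_geometry <- function(x, ...) {
  cat(sprintf(
    "<instrument_geometry> zenith %.1f deg, mount %.2f m, detection limit %g m\n",
    x$zenith, x$instrument_height, x$max_detect_range
  ))
  invisible(x)
}

#' Convert slant range to height
#'
#' Height above the instrument datum of a target at slant range `d` seen at
#' the scan zenith angle, assuming flat ground: `h = cos(zenith) * d`.
#' At the 57.5 degree hinge angle the 60 m detection limit corresponds to a
#' profiling ceiling of about 32 m.
#'
#' @param d Slant range(s) in metres, >= 0.
#' @param geom An [instrument_geometry()].
#' @param datum `"instrument"` (default; z = 0 at the scan head) or
#'   `"ground"`, which adds the instrument mount height.
#' @return Heights in metres, same length as `d`.
#' @examples
#' height_from_range(10)   # ~5.37 m
#' height_from_range(60)   # ~32.2 m, the useful profiling ceiling
#' @export
height_from_range <- function(d, geom = instrument_geometry(),
                              datum = c("instrument", "ground")) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("ranges must be finite and >= 0", call. = FALSE)
  datum <- match.arg(datum)
  h <- cos(geom$zenith * pi / 180) * d
  if (datum == "ground") h <- h + geom$instrument_height
  h
}

#' Sampled plot footprint area
#'
#' Area of the circular plot sampled by a full-azimuth scan in a canopy of
#' uniform height `canopy_height`. Two rules are provided for the plot
#' radius: `"radius_2h"`, the rule of thumb that the beam exits the canopy
#' at a horizontal distance of twice the canopy height (radius `2H`), and
#' `"tangent"`, the exact horizontal distance at which a beam launched at
#' the scan zenith angle reaches the canopy top (radius `H tan(zenith)`,
#' about `1.57 H` at 57.5 degrees). The two disagree by design; both are
#' reported by this function so the discrepancy is visible.
#'
#' @param canopy_height Canopy height H in metres, > 0.
#' @param rule `"radius_2h"` (default) or `"tangent"`.
#' @param geom An [instrument_geometry()] (used by the tangent rule).
#' @return A tibble with columns `canopy_height`, `rule`, `radius_m`,
#'   `area_m2`, `area_ha`.
#' @examples
#' footprint_area(28)  # ~0.985 ha -> "1 hectare" to the nearest hectare
#' @export
footprint_area <- function(canopy_height, rule = c("radius_2h", "tangent"),
                           geom = instrument_geometry()) {
  if (!is.numeric(canopy_height) || any(canopy_height <= 0))
    stop("`canopy_height` must be > 0", call. = FALSE)
  rule <- match.arg(rule)
  radius <- switch(rule,
    radius_2h = 2 * canopy_height,
    tangent   = canopy_height * tan(geom$zenith * pi / 180)
  )
  area <- pi * radius^2
  tibble::tibble(
    canopy_height = canopy_height,
    rule = rule,
    radius_m = radius,
    area_m2 = area,
    area_ha = area / 1e4
  )
}

#' Angular scan density
#'
#' Shots per azimuth degree for a full 360-degree scan; e.g. a typical
#' 920-shot scan gives 2.6 shots per degree, and the instrument maximum of
#' 7360 gives about 20.4.
#'
#' @param n_shots Number of range measurements in a full-azimuth scan.
#' @return Shots per degree.
#' @export
scan_density <- function(n_shots) {
  if (!is.numeric(n_shots) || any(n_shots < 1))
    stop("`n_shots` must be >= 1", call. = FALSE)
  n_shots / 360
}
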