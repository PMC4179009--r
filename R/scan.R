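#' Construct a scan object
#'
#' A scan is one full-azimuth acquisition: an ordered table of shot records
#' (`index`, `azimuth` in degrees, `range` in metres) plus acquisition
#' metadata carried as attributes. A range of 0.000 m encodes a gap — the
#' beam passed through the canopy without a valid return (or the return was
#' invalid); gaps count towards the shot total but are never treated as
#' interceptions.
#'
#' @param records A data frame with columns `index`, `azimuth`, `range`.
#' @param instrument_id Instrument label, e.g. `"VN5"`.
#' @param timestamp Scan start time (`POSIXct`, or a string parseable by
#'   [as.POSIXct()]). Monitoring scans typically start at 22:00 local time.
#' @param zenith Scan zenith angle in degrees (default the hinge angle).
#' @param truncated Logical: was the scan terminated early by the rain
#'   cut-off (50 consecutive sub-300 mm returns)?
#' @return A tibble of class `iml_scan` with metadata attributes
#'   `instrument_id`, `timestamp`, `zenith`, `truncated`.
#' @export
iml_scan <- function(records, instrument_id = "UNKNOWN",
                     timestamp = as.POSIXct("2000-01-01 22:00:00", tz = "UTC"),
                     zenith = HINGE_ANGLE, truncated = FALSE) {
  records <- tibble::as_tibble(records)
  req <- c("index", "azimuth", "range")
  if (!all(req %in% names(records)))
    stop("scan records need columns index, azimuth, range", call. = FALSE)
  if (nrow(records) < 1L)
    stop("a scan must contain at least one shot record", call. = FALSE)
  if (any(records$range < 0) || any(!is.finite(records$range)))
    stop("ranges must be finite and >= 0 (0.000 encodes a gap)", call. = FALSE)
  if (any(records$azimuth < 0) || any(records$azimuth >= 360))
    stop("azimuths must lie in [0, 360) degrees", call. = FALSE)
  if (is.unsorted(records$index))
    stop("shot records must be ordered by index", call. = FALSE)
  if (is.character(timestamp)) timestamp <- as.POSIXct(timestamp, tz = "UTC")
  out <- records[req]
  attr(out, "instrument_id") <- as.character(instrument_id)
  attr(out, "timestamp") <- timestamp
  attr(out, "zenith") <- as.numeric(zenith)
  attr(out, "truncated") <- isTRUE(truncated)
  class(out) <- c("iml_scan", class(tibble::tibble()))
  out
}

#' Scan metadata
#'
#' @param scan An [iml_scan()].
#' @return A one-row tibble: `instrument_id`, `timestamp`, `zenith`,
#'   `truncated`, `n_shots`.
#' @export
scan_meta <- function(scan) {
  stopifnot(inherits(scan, "iml_scan"))
  tibble::tibble(
    instrument_id = attr(scan, "instrument_id"),
    timestamp = attr(scan, "timestamp"),
    zenith = attr(scan, "zenith"),
    truncated = attr(scan, "truncated"),
    n_shots = nrow(scan)
  )
}

#' @export
print.iml_scan <- function(x, ...) {
  m <- scan_meta(x)
  cat(sprintf(
    "<iml_scan> %s @ %s | zenith %.1f deg | %d shots (%d valid)%s\n",
    m$instrument_id, format(m$timestamp, "%Y-%m-%d %H:%M %Z"),
    m$zenith, m$n_shots, sum(x$range > 0),
    if (m$truncated) " | TRUNCATED (rain)" else ""
  ))
  NextMethod()
}
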