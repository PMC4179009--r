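#' Detect a rain-affected scan
#'
#' Rain on the scan prism produces consistently short returns (~270 mm).
#' A scan is rain-affected if it was truncated by the firmware cut-off, or
#' if it contains a run of at least `run_length` consecutive short returns
#' below `max_range`. By default a "short return" is a non-gap record in
#' (0, 0.300) m: the instrument reports droplets as ~0.27 m hits, not as
#' gaps, so gaps (0.000) break a run. Set `count_gaps = TRUE` to let gaps
#' continue a run instead.
#'
#' @param scan An [iml_scan()].
#' @param max_range Short-return threshold in metres (default 0.300).
#' @param run_length Consecutive short returns required (default 50, the
#'   firmware cut-off).
#' @param count_gaps Should gap records (0.000) count as short returns?
#' @return Logical.
#' @export
detect_rain <- function(scan, max_range = 0.300, run_length = 50L,
                        count_gaps = FALSE) {
  stopifnot(inherits(scan, "iml_scan"))
  if (isTRUE(attr(scan, "truncated"))) return(TRUE)
  short <- scan$range < max_range & (count_gaps | scan$range > 0)
  if (!any(short)) return(FALSE)
  r <- rle(short)
  any(r$values & r$lengths >= run_length)
}

#' Sum of valid range measurements in a scan
#'
#' Total of all non-gap ranges, the per-scan statistic whose distribution
#' separates clean scans from wind-degraded ones and anchors the
#' threshold-based quality filter.
#'
#' @param scan An [iml_scan()].
#' @return Sum in metres (0 for an all-gap scan).
#' @export
sum_valid_ranges <- function(scan) {
  stopifnot(inherits(scan, "iml_scan"))
  sum(scan$range[scan$range > 0])
}

#' Quality-control table for a set of scans
#'
#' Computes, per scan, the summed valid range, the rain flag, and the
#' exclusion decision against a per-instrument summed-range threshold.
#' A scan is excluded if it is rain-affected or if its summed range is
#' strictly less than the threshold (a sum exactly at the threshold is
#' retained). Exclusion is whole-scan: partial scans would overweight the
#' azimuths they retain and bias the profile.
#'
#' @param scans A list of [iml_scan()] objects.
#' @param threshold Summed-range threshold in metres (single value, or one
#'   per scan, or a named vector looked up by instrument id). Field-trial
#'   presets for instruments VN5/VN6/VN7 are available as
#'   [vegnet_thresholds].
#' @param ... Passed to [detect_rain()].
#' @return A tibble, one row per scan: `scan_id`, `instrument_id`,
#'   `timestamp`, `n_shots`, `sum_valid_ranges`, `rain_flag`, `threshold`,
#'   `excluded`, `reason` (`"rain"`, `"below_threshold"` or `"retained"`).
#' @export
qc_scans <- function(scans, threshold = 0, ...) {
  if (!is.list(scans) || length(scans) == 0L)
    stop("`scans` must be a non-empty list of iml_scan objects", call. = FALSE)
  meta <- purrr::map_dfr(scans, scan_meta)
  if (!is.null(names(threshold))) {
    thr <- unname(threshold[meta$instrument_id])
    if (anyNA(thr))
      stop("no threshold for instrument(s): ",
           paste(unique(meta$instrument_id[is.na(thr)]), collapse = ", "),
           call. = FALSE)
  } else {
    thr <- rep_len(threshold, length(scans))
  }
  if (any(thr < 0)) stop("thresholds must be >= 0", call. = FALSE)
  out <- dplyr::mutate(
    meta,
    scan_id = dplyr::row_number(),
    sum_valid_ranges = purrr::map_dbl(scans, sum_valid_ranges),
    rain_flag = purrr::map_lgl(scans, detect_rain, ...),
    threshold = thr,
    reason = dplyr::case_when(
      rain_flag ~ "rain",
      sum_valid_ranges < threshold ~ "below_threshold",
      TRUE ~ "retained"
    ),
    excluded = .data$reason != "retained"
  )
  dplyr::select(out, "scan_id", "instrument_id", "timestamp", "n_shots",
                "sum_valid_ranges", "rain_flag", "threshold", "excluded",
                "reason")
}

#' Field-trial summed-range thresholds (m)
#'
#' Per-instrument exclusion thresholds used in the original three-instrument
#' deployment: scans with a summed valid range strictly below the threshold
#' are excluded.
#'
#' @format Named numeric vector (metres) for instruments VN5, VN6, VN7.
#' @export
vegnet_thresholds <- c(VN5 = 8000, VN6 = 9000, VN7 = 8100)

#' Partition scans into retained and excluded sets
#'
#' @inheritParams qc_scans
#' @return A list with elements `retained` and `excluded` (lists of scans)
#'   and `qc` (the [qc_scans()] tibble). The two sets are disjoint and
#'   jointly exhaustive.
#' @export
apply_threshold <- function(scans, threshold, ...) {
  qc <- qc_scans(scans, threshold, ...)
  list(
    retained = scans[!qc$excluded],
    excluded = scans[qc$excluded],
    qc = qc
  )
}

#' Histogram of per-scan summed ranges
#'
#' Frequency table of [sum_valid_ranges()] across scans, the diagnostic
#' used to choose a summed-range threshold by eye: clean and wind-degraded
#' scan populations appear as separate modes.
#'
#' @param scans A list of scans, or a [qc_scans()] tibble.
#' @param bin_width Bin width in metres (> 0).
#' @return A tibble with `bin_start`, `bin_mid`, `bin_end`, `count`.
#' @export
summed_range_histogram <- function(scans, bin_width = 500) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0", call. = FALSE)
  sums <- if (is.data.frame(scans)) {
    scans$sum_valid_ranges
  } else {
    if (length(scans) == 0L) stop("no scans supplied", call. = FALSE)
    purrr::map_dbl(scans, sum_valid_ranges)
  }
  if (length(sums) == 0L) stop("no scans supplied", call. = FALSE)
  bin <- floor(sums / bin_width)
  tab <- dplyr::count(tibble::tibble(bin = bin), .data$bin, name = "count")
  dplyr::transmute(
    tab,
    bin_start = .data$bin * bin_width,
    bin_mid = (.data$bin + 0.5) * bin_width,
    bin_end = (.data$bin + 1) * bin_width,
    count = .data$count
  )
}

#' Monthly exclusion summary
#'
#' Per calendar month, the number of scans, the number excluded by quality
#' filtering, and the percentage excluded; plus the across-month average as
#' the `"mean_excluded_pct"` attribute. Months present in the data but with
#' zero scans cannot occur (months are derived from scan timestamps), and a
#' month's percentage is `NA` if it has no scans after an explicit
#' `month_range` is supplied.
#'
#' @param qc A [qc_scans()] tibble.
#' @param by_instrument Summarise per instrument as well as per month?
#' @param month_range Optional `Date` vector; all months spanned are
#'   reported, including empty ones (count 0, percentage `NA`).
#' @return A tibble with `month` (Date, first of month), counts and
#'   `excluded_pct`.
#' @export
exclusion_summary <- function(qc, by_instrument = FALSE, month_range = NULL) {
  stopifnot(is.data.frame(qc))
  d <- dplyr::mutate(qc, month = as.Date(format(.data$timestamp, "%Y-%m-01")))
  keys <- if (by_instrument) c("instrument_id", "month") else "month"
  out <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(keys))),
    n_scans = dplyr::n(),
    n_excluded = sum(.data$excluded),
    excluded_pct = 100 * sum(.data$excluded) / dplyr::n(),
    .groups = "drop"
  )
  if (!is.null(month_range)) {
    all_months <- seq(as.Date(format(min(month_range), "%Y-%m-01")),
                      as.Date(format(max(month_range), "%Y-%m-01")), by = "month")
    grid <- if (by_instrument) {
      tidyr::expand_grid(instrument_id = unique(d$instrument_id),
                         month = all_months)
    } else {
      tibble::tibble(month = all_months)
    }
    out <- dplyr::left_join(grid, out, by = keys)
    out$n_scans[is.na(out$n_scans)] <- 0L
    out$n_excluded[is.na(out$n_excluded)] <- 0L
  }
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
  attr(out, "mean_excluded_pct") <- mean(out$excluded_pct, na.rm = TRUE)
  out
}
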