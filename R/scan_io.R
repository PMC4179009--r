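#' Quantize a range measurement to instrument precision
#'
#' The rangefinder stores ranges at millimetre precision below 10 m and
#' centimetre precision at and above 10 m; the gap code 0.000 is preserved
#' exactly. Rounding is half-up (0.0005 -> 0.001), matching how the
#' firmware truncates, and quantization is idempotent.
#'
#' @param d Range(s) in metres, >= 0.
#' @return Quantized range(s) in metres.
#' @examples
#' quantize_range(5.12345)  # 5.123
#' quantize_range(23.456)   # 23.46
#' @export
quantize_range <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("ranges must be finite and >= 0", call. = FALSE)
  ifelse(d < 10, round_half_up(d, 3L), round_half_up(d, 2L))
}

# base round() is round-half-even; the instrument convention is half-up.
# The 1e-9 nudge keeps decimal literals like 10.005 (stored just below the
# true half in binary) on the half-up side.
round_half_up <- function(x, digits) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

fmt_range <- function(d) {
  ifelse(d < 10, sprintf("%.3f", d), sprintf("%.2f", d))
}

#' Write a scan to a text file
#'
#' Plain delimited text with a `#`-prefixed `key: value` header carrying
#' the scan metadata, then a CSV body of `index,azimuth,range`. Ranges are
#' written at instrument precision (mm below 10 m, cm at or above; gaps as
#' `0.000`), azimuths at 0.1 degree. A typical 920-shot scan is a few tens
#' of kilobytes. This layout is a stand-in for the instrument's unpublished
#' on-card format: human-inspectable and diff-able.
#'
#' @param scan An [iml_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_scan()]
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "iml_scan"))
  if (nrow(scan) > 7360L)
    stop("the scan file format holds at most 7360 records (instrument maximum)",
         call. = FALSE)
  m <- scan_meta(scan)
  header <- c(
    sprintf("# instrument_id: %s", m$instrument_id),
    sprintf("# timestamp: %s", format(m$timestamp, "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("# zenith: %.1f", m$zenith),
    sprintf("# truncated: %s", if (m$truncated) "true" else "false"),
    sprintf("# firmware: hingescan-sim %s", as.character(utils::packageVersion("hingescan"))),
    "index,azimuth,range"
  )
  body <- sprintf("%d,%.1f,%s", scan$index, scan$azimuth,
                  fmt_range(quantize_range(scan$range)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a scan file
#'
#' Parses the text format written by [write_scan()]. Tolerates trailing
#' whitespace and CRLF line endings; malformed header or body lines raise
#' an error naming the offending line.
#'
#' @param path Path to a scan file.
#' @return An [iml_scan()].
#' @export
read_scan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty scan file: ", path, call. = FALSE)

  hdr_idx <- grep("^#", lines)
  meta <- list()
  for (i in hdr_idx) {
    mm <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines[i]))[[1]]
    if (length(mm) != 3L)
      stop(sprintf("malformed header at line %d of %s", i, path), call. = FALSE)
    meta[[mm[2]]] <- mm[3]
  }
  for (key in c("instrument_id", "timestamp", "zenith", "truncated")) {
    if (is.null(meta[[key]]))
      stop("scan header missing field: ", key, call. = FALSE)
  }

  body <- setdiff(seq_along(lines), hdr_idx)
  body <- body[!grepl("^index", lines[body])]
  if (length(body) == 0L)
    stop("scan file has no shot records: ", path, call. = FALSE)
  parts <- strsplit(lines[body], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed record at line %d of %s", body[bad[1]], path),
         call. = FALSE)
  rec <- suppressWarnings(tibble::tibble(
    index = as.integer(vapply(parts, `[[`, "", 1L)),
    azimuth = as.numeric(vapply(parts, `[[`, "", 2L)),
    range = as.numeric(vapply(parts, `[[`, "", 3L))
  ))  # coercion failures surface as a parse error just below
  if (anyNA(rec))
    stop(sprintf("non-numeric record at line %d of %s",
                 body[which(rowSums(is.na(rec)) > 0)[1]], path), call. = FALSE)

  ts <- as.POSIXct(strptime(meta$timestamp, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
  if (is.na(ts))
    stop("unparseable timestamp in header: ", meta$timestamp, call. = FALSE)
  iml_scan(rec,
           instrument_id = meta$instrument_id,
           timestamp = ts,
           zenith = as.numeric(meta$zenith),
           truncated = tolower(meta$truncated) %in% c("true", "t", "1"))
}
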