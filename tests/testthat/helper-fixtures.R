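# quick scan from a vector of ranges (0 = gap)
make_scan <- function(ranges, instrument_id = "TEST",
                      timestamp = as.POSIXct("2013-03-05 22:00:00", tz = "UTC"),
                      zenith = 57.5, truncated = FALSE) {
  n <- length(ranges)
  iml_scan(
    tibble::tibble(index = seq_len(n),
                   azimuth = round((seq_len(n) - 1) * 360 / n, 1) %% 360,
                   range = ranges),
    instrument_id = instrument_id, timestamp = timestamp,
    zenith = zenith, truncated = truncated
  )
}

# independent brute-force gap-probability oracle: loops shot by shot
brute_force_pgap <- function(scan, grid, zenith = 57.5) {
  n <- nrow(scan)
  sapply(grid, function(h) {
    below <- 0L
    for (i in seq_len(n)) {
      d <- scan$range[i]
      if (d > 0 && cos(zenith * pi / 180) * d < h) below <- below + 1L
    }
    1 - below / n
  })
}

# homogeneous single-layer canopy with given total plant area
slab_canopy <- function(L_top, height = 15, x = 1) {
  canopy_model(height, L_top / height, ellipsoidal_lad(x))
}
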