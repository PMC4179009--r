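test_that("rain detection requires 50 consecutive short returns", {
  rain50 <- make_scan(c(runif(200, 2, 30), rep(0.270, 50)))
  expect_true(detect_rain(rain50))
  # 49 short returns then a long one: not rain
  rain49 <- make_scan(c(rep(0.270, 49), 12, runif(100, 2, 30)))
  expect_false(detect_rain(rain49))
  # gaps break a run under the default convention...
  broken <- make_scan(c(rep(0.270, 30), 0, rep(0.270, 30)))
  expect_false(detect_rain(broken))
  # ...but can be counted in if asked
  expect_true(detect_rain(broken, count_gaps = TRUE))
  # an all-gap scan is not rain: gaps are not "measurements < 300 mm"
  expect_false(detect_rain(make_scan(rep(0, 300))))
  # the firmware truncation flag alone marks rain
  flagged <- make_scan(runif(60, 2, 30), truncated = TRUE)
  expect_true(detect_rain(flagged))
})

test_that("rain detection has full recall on simulator-injected rain", {
  cm <- slab_canopy(1.4)
  for (seed in 1:20) {
    s <- simulate_scan(cm, n_shots = 920, seed = seed,
                       weather = weather_scenario(rain = TRUE))
    expect_true(detect_rain(s))
  }
})

test_that("sum of valid ranges excludes gaps", {
  expect_equal(sum_valid_ranges(make_scan(rep(0, 920))), 0)
  expect_equal(sum_valid_ranges(make_scan(c(10, 0, 20, 0, 30))), 60)
})

test_that("wind thinning roughly halves the summed range at p = 0.5", {
  cm <- slab_canopy(2)
  clean <- simulate_scan(cm, n_shots = 8000, seed = 31)
  windy <- simulate_scan(cm, n_shots = 8000, seed = 31,
                         weather = weather_scenario(wind_gap_prob = 0.5))
  ratio <- sum_valid_ranges(windy) / sum_valid_ranges(clean)
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("threshold partition is strict at the boundary and whole-scan", {
  # constructed sums: 7999 m excluded, 8000 m retained at threshold 8000
  s7999 <- make_scan(c(rep(20, 399), 19, rep(0, 100)))   # sums to 7999
  s8000 <- make_scan(c(rep(20, 400), rep(0, 100)))       # sums to 8000
  expect_equal(sum_valid_ranges(s7999), 7999)
  expect_equal(sum_valid_ranges(s8000), 8000)
  part <- apply_threshold(list(s7999, s8000), threshold = 8000)
  expect_equal(part$qc$reason, c("below_threshold", "retained"))
  expect_length(part$retained, 1)
  expect_length(part$excluded, 1)
  # zero threshold: only rain-flagged scans go
  rain <- make_scan(rep(0.270, 60), truncated = TRUE)
  part0 <- apply_threshold(list(s7999, rain), threshold = 0)
  expect_equal(part0$qc$reason, c("retained", "rain"))
})

test_that("per-instrument thresholds are looked up by id", {
  mk <- function(id, total) make_scan(rep(total / 500, 500), instrument_id = id)
  scans <- list(mk("VN5", 8500), mk("VN6", 8500), mk("VN7", 8500))
  qc <- qc_scans(scans, vegnet_thresholds)
  # 8500 m clears VN5 (8000) and VN7 (8100) but not VN6 (9000)
  expect_equal(qc$excluded, c(FALSE, TRUE, FALSE))
  expect_error(qc_scans(list(mk("VN9", 100)), vegnet_thresholds), "VN9")
})

test_that("filtering is deterministic, idempotent and a true partition", {
  cm <- slab_canopy(1.4)
  scans <- lapply(1:12, function(i) {
    simulate_scan(cm, n_shots = 400, seed = i,
                  weather = weather_scenario(
                    rain = i %% 4 == 0,
                    wind_gap_prob = if (i %% 3 == 0) 0.7 else 0))
  })
  thr <- 0.6 * expected_sum_valid_ranges(cm, n_shots = 400)
  p1 <- apply_threshold(scans, thr)
  p2 <- apply_threshold(scans, thr)
  expect_identical(p1$qc, p2$qc)
  expect_equal(length(p1$retained) + length(p1$excluded), length(scans))
  # re-filtering the retained set excludes nothing
  p3 <- apply_threshold(p1$retained, thr)
  expect_length(p3$excluded, 0)
  expect_identical(p1$qc$excluded, p1$qc$reason != "retained")
})

test_that("summed-range histogram separates clean and wind-degraded scans", {
  cm <- slab_canopy(2, height = 20)
  scans <- c(
    lapply(1:15, function(i) simulate_scan(cm, n_shots = 500, seed = i)),
    lapply(16:30, function(i) simulate_scan(
      cm, n_shots = 500, seed = i,
      weather = weather_scenario(wind_gap_prob = 0.6)))
  )
  hist <- summed_range_histogram(scans, bin_width = 500)
  expect_s3_class(hist, "tbl_df")
  expect_equal(sum(hist$count), 30)
  # bimodal: a wide gap separates the windy mode from the clean mode
  sums <- sapply(scans, sum_valid_ranges)
  expect_gt(min(sums[1:15]) - max(sums[16:30]), 1000)
  # single scan: one nonzero bin
  h1 <- summed_range_histogram(scans[1], bin_width = 500)
  expect_equal(nrow(h1), 1)
  expect_error(summed_range_histogram(scans, bin_width = 0), "> 0")
  expect_error(summed_range_histogram(list()), "no scans")
})

test_that("monthly exclusion summary reports percentages and the average", {
  mk <- function(day, excluded) {
    make_scan(if (excluded) rep(0.27, 60) else rep(15, 300),
              timestamp = as.POSIXct(sprintf("2013-%02d-%02d 22:00:00",
                                             (day - 1) %/% 28 + 1,
                                             (day - 1) %% 28 + 1), tz = "UTC"),
              truncated = excluded)
  }
  scans <- c(lapply(1:10, function(d) mk(d, d <= 4)),      # Jan: 4/10 excluded
             lapply(29:38, function(d) mk(d, d <= 30)))    # Feb: 2/10 excluded
  qc <- qc_scans(scans, threshold = 0)
  summ <- exclusion_summary(qc)
  expect_equal(summ$excluded_pct, c(40, 20))
  expect_equal(attr(summ, "mean_excluded_pct"), 30)
  # an empty covered month is reported with zero scans and NA percentage
  wide <- exclusion_summary(qc, month_range = as.Date(c("2013-01-01", "2013-03-31")))
  expect_equal(wide$n_scans, c(10L, 10L, 0L))
  expect_true(is.na(wide$excluded_pct[3]))
})

test_that("exclusion rate of a synthetic campaign matches its driving probability", {
  # nights rain-terminated i.i.d. with p = 0.48 -> mean monthly exclusion ~48%
  withr::with_seed(42, {
    dates <- seq(as.Date("2013-01-01"), by = "day", length.out = 180)
    rainy <- runif(180) < 0.48
    scans <- lapply(seq_along(dates), function(i) {
      make_scan(if (rainy[i]) rep(0.27, 60) else rep(15, 100),
                timestamp = as.POSIXct(paste(dates[i], "22:00:00"), tz = "UTC"),
                truncated = rainy[i])
    })
  })
  summ <- exclusion_summary(qc_scans(scans, threshold = 0))
  expect_lt(abs(attr(summ, "mean_excluded_pct") - 48),
            3 * 100 * sqrt(0.48 * 0.52 / 180))
})
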