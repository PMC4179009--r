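#' Simulate a multi-month monitoring campaign
#'
#' Generates nightly scans for several co-located instruments over a
#' seasonal canopy, with weather contamination, and returns both the scans
#' and the ground truth needed to validate the full
#' filter -> profile -> aggregate -> trend chain.
#'
#' The canopy follows the base `canopy` model with its PAVD profile scaled
#' day by day through a seasonal sinusoid:
#' `scale(t) = 1 + amplitude * sin(2 pi (t - t0) / 365.25)`, so total plant
#' area swings `amplitude` either side of the base value over a year. Each
#' night one scan per instrument is acquired at 22:00 local time. With
#' probability `rain_prob` the night is rainy (the scan is rain-terminated
#' mid-acquisition) and, independently, with probability `wind_prob` it is
#' windy (a fraction `wind_gap_prob` of true interceptions is lost, which
#' collapses the summed-range statistic and should be caught by the QC
#' threshold). Defaults give roughly the exclusion rates seen in long
#' unattended field deployments (around half of all nights).
#'
#' @param canopy Base [canopy_model()] shared by all instruments; per-
#'   instrument multipliers scale its density (co-located instruments see
#'   slightly different canopy).
#' @param months Campaign length in months (default 18).
#' @param start First scan date (default `"2012-08-01"`).
#' @param instruments Character vector of instrument ids.
#' @param instrument_scale Per-instrument multiplier on the PAVD profile,
#'   recycled.
#' @param amplitude Seasonal sinusoid amplitude as a fraction of the mean
#'   (default 0.10).
#' @param rain_prob,wind_prob Per-night contamination probabilities.
#' @param wind_gap_prob Fraction of interceptions lost on windy nights.
#' @param n_shots Shots per scan (default 920).
#' @param geom An [instrument_geometry()].
#' @param seed Integer master seed (required); all per-scan seeds derive
#'   from it.
#' @return A list:
#'   * `scans` — list of [iml_scan()] objects;
#'   * `truth` — tibble `instrument_id`, `date`, `rain`, `windy`,
#'     `true_pai_top` (the true cumulative plant area at the canopy top
#'     that night);
#'   * `params` — the campaign parameters, including the seed.
#' @export
simulate_campaign <- function(canopy = canopy_model(c(8, 18, 25),
                                                    c(0.06, 0.085, 0.035)),
                              months = 18, start = "2012-08-01",
                              instruments = c("VN5", "VN6", "VN7"),
                              instrument_scale = c(1.1, 1.0, 0.95),
                              amplitude = 0.10,
                              rain_prob = 0.2, wind_prob = 0.25,
                              wind_gap_prob = 0.6,
                              n_shots = 920,
                              geom = instrument_geometry(),
                              seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(canopy, "canopy_model"), months >= 1)
  start <- as.Date(start)
  end <- seq(start, by = "month", length.out = months + 1)[months + 1] - 1
  dates <- seq(start, end, by = "day")
  instrument_scale <- rep_len(instrument_scale, length(instruments))

  grid <- tidyr::expand_grid(instrument_id = instruments, date = dates)
  withr::with_seed(seed, {
    grid <- dplyr::mutate(
      grid,
      rain = stats::runif(dplyr::n()) < rain_prob,
      windy = stats::runif(dplyr::n()) < wind_prob,
      scan_seed = sample.int(.Machine$integer.max - 1L, dplyr::n())
    )
  })

  t0 <- as.numeric(start)
  scale_of <- function(date) 1 + amplitude * sin(2 * pi * (as.numeric(date) - t0) / 365.25)

  sim_one <- function(instrument_id, date, rain, windy, scan_seed) {
    s <- scale_of(date) * instrument_scale[match(instrument_id, instruments)]
    cm <- canopy_model(canopy$layer_tops, canopy$layer_pavd * s, canopy$lad)
    weather <- weather_scenario(
      rain = rain,
      wind_gap_prob = if (windy) wind_gap_prob else 0,
      wind_hit_prob = if (windy) 0.02 else 0
    )
    simulate_scan(cm, n_shots = n_shots, geom = geom, weather = weather,
                  seed = scan_seed, instrument_id = instrument_id,
                  timestamp = as.POSIXct(paste(date, "22:00:00"), tz = "UTC"))
  }
  scans <- purrr::pmap(grid[c("instrument_id", "date", "rain", "windy",
                              "scan_seed")], sim_one)

  truth <- dplyr::mutate(
    grid,
    true_pai_top = true_cumulative_pai(canopy, canopy$canopy_height) *
      scale_of(.data$date) *
      instrument_scale[match(.data$instrument_id, instruments)]
  )
  list(
    scans = scans,
    truth = dplyr::select(truth, "instrument_id", "date", "rain", "windy",
                          "true_pai_top"),
    params = list(seed = seed, months = months, start = start,
                  amplitude = amplitude, rain_prob = rain_prob,
                  wind_prob = wind_prob, wind_gap_prob = wind_gap_prob,
                  n_shots = n_shots, instruments = instruments,
                  instrument_scale = instrument_scale, canopy = canopy,
                  geom = geom)
  )
}

#' Default QC threshold for a simulated campaign
#'
#' Places the summed-range exclusion threshold at a fraction of the
#' deterministic expected clean-scan sum for the campaign's base canopy
#' (per instrument, accounting for the instrument's density multiplier).
#' With the default wind model (60% of interceptions lost on windy
#' nights), a windy scan sums to roughly 40% of a clean one, so the
#' default fraction 0.65 separates the two populations.
#'
#' @param campaign Result of [simulate_campaign()].
#' @param fraction Fraction of the expected clean sum (default 0.65).
#' @return Named numeric vector of thresholds (m), one per instrument.
#' @export
campaign_thresholds <- function(campaign, fraction = 0.65) {
  p <- campaign$params
  thr <- vapply(seq_along(p$instruments), function(i) {
    cm <- canopy_model(p$canopy$layer_tops,
                       p$canopy$layer_pavd * p$instrument_scale[i],
                       p$canopy$lad)
    fraction * expected_sum_valid_ranges(cm, p$n_shots, p$geom)
  }, numeric(1))
  stats::setNames(thr, p$instruments)
}
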