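#' Layered canopy model with known ground truth
#'
#' A horizontally homogeneous canopy described by a piecewise-constant
#' plant area volume density profile: layer `j` spans heights
#' (`layer_tops[j-1]`, `layer_tops[j]`\] above the instrument datum with
#' constant PAVD `layer_pavd[j]` (m2/m3). The cumulative plant area index
#' up to height z, L(z), is the integral of the PAVD profile and is
#' piecewise linear, zero at z = 0 and non-decreasing. This is the ground
#' truth that scan inversion is validated against.
#'
#' @param layer_tops Strictly increasing layer top heights in metres.
#' @param layer_pavd Plant area volume density per layer (m2/m3), >= 0,
#'   same length as `layer_tops`.
#' @param lad Leaf angle distribution, an [ellipsoidal_lad()].
#' @return An object of class `canopy_model` with elements `layer_tops`,
#'   `layer_pavd`, `lad`, `canopy_height` and the cumulative plant area at
#'   each layer top.
#' @examples
#' canopy_model(c(10, 15), c(0.05, 0.2))
#' @export
canopy_model <- function(layer_tops, layer_pavd, lad = ellipsoidal_lad(1)) {
  if (!is.numeric(layer_tops) || length(layer_tops) < 1L ||
      any(layer_tops <= 0) || is.unsorted(layer_tops, strictly = TRUE))
    stop("`layer_tops` must be strictly increasing heights > 0", call. = FALSE)
  if (!is.numeric(layer_pavd) || length(layer_pavd) != length(layer_tops) ||
      any(layer_pavd < 0))
    stop("`layer_pavd` must be >= 0, one value per layer", call. = FALSE)
  if (!inherits(lad, "ellipsoidal_lad"))
    lad <- ellipsoidal_lad(lad)
  edges <- c(0, layer_tops)
  cum <- cumsum(layer_pavd * diff(edges))
  structure(
    list(layer_tops = layer_tops, layer_pavd = layer_pavd, lad = lad,
         canopy_height = layer_tops[length(layer_tops)],
         cum_pai_at_tops = cum),
    class = "canopy_model"
  )
}

#' @export
print.canopy_model <- function(x, ...) {
  cat(sprintf(
    "<canopy_model> %d layer(s), height %.1f m, total plant area index %.3f (LAD x = %.3g)\n",
    length(x$layer_tops), x$canopy_height,
    x$cum_pai_at_tops[length(x$cum_pai_at_tops)], x$lad$x
  ))
  invisible(x)
}

#' True cumulative plant area index of a canopy model
#'
#' Integral of the model's PAVD profile from the instrument datum up to
#' height `z` — the quantity the lidar inversion estimates.
#'
#' @param canopy A [canopy_model()].
#' @param z Height(s) in metres, >= 0.
#' @return L(z), dimensionless; 0 at z = 0, constant above the canopy top.
#' @examples
#' cm <- canopy_model(15, 0.1)
#' true_cumulative_pai(cm, 15)  # 1.5
#' @export
true_cumulative_pai <- function(canopy, z) {
  stopifnot(inherits(canopy, "canopy_model"))
  if (!is.numeric(z) || any(!is.finite(z)) || any(z < 0))
    stop("heights must be finite and >= 0", call. = FALSE)
  edges <- c(0, canopy$layer_tops)
  cum <- c(0, canopy$cum_pai_at_tops)
  zc <- pmin(z, canopy$canopy_height)
  j <- findInterval(zc, edges, rightmost.closed = TRUE)
  j <- pmax(pmin(j, length(canopy$layer_pavd)), 1L)
  cum[j] + canopy$layer_pavd[j] * (zc - edges[j])
}

#' Weather scenario for scan simulation
#'
#' Per-shot weather perturbations. Wind moves canopy elements in and out of
#' the beam path: with probability `wind_gap_prob` a true interception is
#' lost (apparent gap), and with probability `wind_hit_prob` a true gap
#' gains a spurious interception at a range drawn from
#' `spurious_range_fun`. Rain puts droplets on the scan prism, producing
#' near-field returns around 0.27 m; a rain-affected scan is terminated by
#' the firmware after 50 consecutive sub-300 mm returns (see
#' [inject_rain()]). Wind is applied independently per shot; real gusts are
#' correlated in time, a deliberate simplification.
#'
#' @param rain Logical: does rain start during this scan?
#' @param wind_gap_prob Probability a true hit is lost to wind.
#' @param wind_hit_prob Probability a true gap becomes a spurious hit.
#' @param spurious_range_fun Function `n -> n ranges (m)` for spurious
#'   hits; default uniform on 0.5--10 m (near-range clutter).
#' @return An object of class `weather_scenario`.
#' @export
weather_scenario <- function(rain = FALSE, wind_gap_prob = 0,
                             wind_hit_prob = 0,
                             spurious_range_fun = function(n) stats::runif(n, 0.5, 10)) {
  for (p in c(wind_gap_prob, wind_hit_prob)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
      stop("wind probabilities must be single values in [0, 1]", call. = FALSE)
  }
  structure(
    list(rain = isTRUE(rain), wind_gap_prob = wind_gap_prob,
         wind_hit_prob = wind_hit_prob,
         spurious_range_fun = spurious_range_fun),
    class = "weather_scenario"
  )
}

#' Simulate one full-azimuth scan
#'
#' Monte Carlo simulation of an almucantar scan over a [canopy_model()].
#' Shots are fired at `n_shots` azimuths on a deterministic uniform grid
#' over \[0, 360) (matching stepper-motor stepping; optional uniform jitter
#' within each step). Along the slant path, the first interception height
#' z* is drawn by exact inverse-transform sampling from the Beer-Lambert
#' survival function S(z) = exp(-K L(z)), with K the extinction coefficient
#' of the canopy's leaf angle distribution at the scan zenith angle and
#' L(z) the model's piecewise-linear cumulative plant area. A shot that
#' survives to the canopy top is a gap; an interception whose slant range
#' `z*/cos(zenith)` exceeds the detection limit is also recorded as a gap
#' (no return from distant targets). Wind perturbations are applied
#' per shot, then ranges are quantized to instrument precision and gaps
#' encoded as 0.000. If `weather$rain` is `TRUE`, rain onset is drawn
#' uniformly over the scan and [inject_rain()] truncates it.
#'
#' All randomness comes from `seed` via a local RNG; the global RNG state
#' is never touched, and the same seed reproduces the scan byte-for-byte
#' after writing.
#'
#' @param canopy A [canopy_model()].
#' @param n_shots Shots per scan, 1 to 7360 (default 920, the typical
#'   configuration of 2.6 shots per degree).
#' @param geom An [instrument_geometry()].
#' @param weather A [weather_scenario()].
#' @param seed Integer seed (required).
#' @param quantize Quantize ranges to instrument precision (default TRUE).
#' @param jitter_azimuth Add uniform jitter within each azimuth step
#'   (default FALSE).
#' @param instrument_id,timestamp Metadata passed to [iml_scan()].
#' @return An [iml_scan()].
#' @examples
#' cm <- canopy_model(c(10, 15), c(0.05, 0.2))
#' s <- simulate_scan(cm, n_shots = 920, seed = 42)
#' @export
simulate_scan <- function(canopy, n_shots = 920,
                          geom = instrument_geometry(),
                          weather = weather_scenario(),
                          seed, quantize = TRUE, jitter_azimuth = FALSE,
                          instrument_id = "SIM",
                          timestamp = as.POSIXct("2000-01-01 22:00:00", tz = "UTC")) {
  stopifnot(inherits(canopy, "canopy_model"),
            inherits(geom, "instrument_geometry"),
            inherits(weather, "weather_scenario"))
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  if (n_shots < 1)
    stop("`n_shots` must be >= 1", call. = FALSE)
  n_shots <- as.integer(n_shots)

  withr::with_seed(seed, {
    az <- (seq_len(n_shots) - 1L) * 360 / n_shots
    if (jitter_azimuth) az <- az + stats::runif(n_shots, 0, 360 / n_shots)
    az <- round_half_up(az %% 360, 1L)  # 0.1 deg encoder precision
    az[az >= 360] <- 0

    K <- extinction_coefficient(geom$zenith, canopy$lad)
    L_top <- canopy$cum_pai_at_tops[length(canopy$cum_pai_at_tops)]

    # inverse-CDF draw of first-interception cumulative plant area A = -log(U)/K;
    # the shot is a gap if A exceeds L at the canopy top
    A <- -log(stats::runif(n_shots)) / K
    hit <- A < L_top
    z_star <- rep(NA_real_, n_shots)
    if (any(hit)) {
      cum <- c(0, canopy$cum_pai_at_tops)
      edges <- c(0, canopy$layer_tops)
      j <- findInterval(A[hit], cum, rightmost.closed = FALSE)
      # flat (pavd = 0) layers have zero measure in A; j indexes the layer
      # whose cumulative span contains A, where layer_pavd > 0
      j <- pmax(pmin(j, length(canopy$layer_pavd)), 1L)
      z_star[hit] <- edges[j] + (A[hit] - cum[j]) / canopy$layer_pavd[j]
    }
    d <- ifelse(hit, z_star / cos(geom$zenith * pi / 180), 0)
    # detection limit: interceptions beyond max range return nothing
    d[hit & d > geom$max_detect_range] <- 0

    # wind: per-shot i.i.d. loss of hits and gain of spurious near hits
    if (weather$wind_gap_prob > 0) {
      lost <- d > 0 & stats::runif(n_shots) < weather$wind_gap_prob
      d[lost] <- 0
    }
    if (weather$wind_hit_prob > 0) {
      gained <- d == 0 & stats::runif(n_shots) < weather$wind_hit_prob
      if (any(gained)) d[gained] <- weather$spurious_range_fun(sum(gained))
    }

    if (quantize) d <- quantize_range(d)
    scan <- iml_scan(
      tibble::tibble(index = seq_len(n_shots), azimuth = az, range = d),
      instrument_id = instrument_id, timestamp = timestamp,
      zenith = geom$zenith, truncated = FALSE
    )
    if (weather$rain) {
      onset <- sample.int(n_shots, 1L) - 1L
      scan <- inject_rain(scan, onset = onset, seed = NULL, quantize = quantize)
    }
    scan
  })
}

#' Inject a rain event into a scan
#'
#' Rain droplets on the scan prism scatter the beam and return near-field
#' ranges of about 270 mm (the distance from the rangefinder to the prism
#' face). From the onset shot onward, ranges are replaced by draws from
#' `rain_range_fun` (default uniform 0.260--0.290 m), and the scan is
#' truncated exactly 50 shots after onset, emulating the firmware's
#' power-saving cut-off after 50 consecutive sub-300 mm returns. The
#' scan's `truncated` flag is set.
#'
#' @param scan An [iml_scan()].
#' @param onset Number of clean shots before rain begins (0 = rain from the
#'   first shot). Drawn uniformly if `NULL` and `seed` is given.
#' @param seed Integer seed for the local RNG; if `NULL` the current RNG
#'   state is used (only do this inside an outer seeded context).
#' @param rain_range_fun Function `n -> n ranges (m)` for droplet returns.
#' @param quantize Quantize the injected ranges (default TRUE).
#' @return A truncated [iml_scan()] with `onset + 50` records.
#' @export
inject_rain <- function(scan, onset = NULL, seed = NULL,
                        rain_range_fun = function(n) stats::runif(n, 0.260, 0.290),
                        quantize = TRUE) {
  stopifnot(inherits(scan, "iml_scan"))
  run <- function() {
    n <- nrow(scan)
    if (is.null(onset)) onset <- sample.int(n, 1L) - 1L
    if (onset < 0 || onset >= n)
      stop("`onset` must be in [0, n_shots)", call. = FALSE)
    n_rain <- 50L
    rec <- scan[seq_len(min(n, onset + n_rain)), ]
    rainy <- seq_len(nrow(rec)) > onset
    r <- rain_range_fun(sum(rainy))
    if (quantize) r <- quantize_range(r)
    rec$range[rainy] <- r
    iml_scan(rec,
             instrument_id = attr(scan, "instrument_id"),
             timestamp = attr(scan, "timestamp"),
             zenith = attr(scan, "zenith"),
             truncated = TRUE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Expected sum of valid ranges for a clean scan
#'
#' Deterministic expectation of the per-scan summed range statistic used by
#' quality filtering, under the Beer-Lambert interception model with the
#' detection limit applied: `n_shots` times the expected slant range of a
#' shot, counting shots that end as gaps as zero. Useful for placing a
#' summed-range QC threshold for a synthetic campaign without simulating.
#'
#' @param canopy A [canopy_model()].
#' @param n_shots Shots per scan.
#' @param geom An [instrument_geometry()].
#' @param dz Integration step in metres (default 0.01).
#' @return Expected summed valid range in metres.
#' @export
expected_sum_valid_ranges <- function(canopy, n_shots = 920,
                                      geom = instrument_geometry(),
                                      dz = 0.01) {
  stopifnot(inherits(canopy, "canopy_model"))
  K <- extinction_coefficient(geom$zenith, canopy$lad)
  cz <- cos(geom$zenith * pi / 180)
  z_max <- min(canopy$canopy_height, geom$max_detect_range * cz)
  if (z_max <= 0) return(0)
  z <- seq(dz / 2, z_max, by = dz)
  u <- canopy$layer_pavd[pmin(
    findInterval(z, c(0, canopy$layer_tops), rightmost.closed = TRUE),
    length(canopy$layer_pavd)
  )]
  dens <- K * u * exp(-K * true_cumulative_pai(canopy, z))  # f(z) dz
  n_shots * sum((z / cz) * dens * dz)
}
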