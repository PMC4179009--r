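#' Height grid for vertical profiles
#'
#' Uniformly spaced bin-edge heights above the instrument datum. The
#' default, 0 to 35 m in 0.5 m bins, covers the ~32 m profiling ceiling of
#' a 60 m detection limit at the 57.5 degree hinge angle.
#'
#' @param max_height Top of the grid in metres.
#' @param bin_width Bin width in metres (> 0).
#' @return Numeric vector of heights starting at 0.
#' @export
height_grid <- function(max_height = 35, bin_width = 0.5) {
  if (bin_width <= 0 || max_height <= 0)
    stop("`max_height` and `bin_width` must be > 0", call. = FALSE)
  seq(0, max_height, by = bin_width)
}

#' Canopy gap probability profile from a scan
#'
#' For each height h on the grid, the probability that a beam reaches h
#' without interception, estimated as
#' `Pgap(h) = 1 - (# valid returns with z_i < h) / N`,
#' where `z_i = cos(zenith) * d_i` for valid (non-gap) returns and N is the
#' total number of shots. Gaps (range 0.000) count in N but never as
#' returns below h, so Pgap(0) = 1 and Pgap is non-increasing with height.
#' The count uses a strict `z_i < h`.
#'
#' Setting `literal = TRUE` instead counts every record's height (gaps
#' included, at z = 0) below h as a return — the naive reading of the
#' counting rule. It yields a non-physical profile (gap-heavy scans get
#' Pgap near 0 at all heights) and exists only for comparison.
#'
#' @param scan An [iml_scan()] (a retained, whole scan).
#' @param geom An [instrument_geometry()]; its zenith should match the
#'   scan's.
#' @param grid Height grid from [height_grid()].
#' @param literal Use the naive gap-inclusive count (debug only).
#' @return An `iml_profile` tibble with columns `height`, `pgap`, plus
#'   attributes `n_shots`, `instrument_id`, `timestamp`.
#' @export
gap_profile <- function(scan, geom = instrument_geometry(),
                        grid = height_grid(), literal = FALSE) {
  stopifnot(inherits(scan, "iml_scan"))
  if (nrow(scan) < 1L) stop("empty scan", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("height grid must be strictly increasing", call. = FALSE)
  n <- nrow(scan)
  valid <- scan$range > 0
  z <- height_from_range(scan$range[valid], geom)
  if (literal) z <- c(z, rep(0, sum(!valid)))
  # strict z_i < h via vectorized counting over the sorted heights
  below <- findInterval(grid, sort(z), left.open = TRUE)  # counts z <= h - eps: z < h needs care with ties
  # findInterval(..., left.open = TRUE) counts z_i < h exactly at ties
  pgap <- 1 - below / n
  out <- tibble::tibble(height = grid, pgap = pgap)
  attr(out, "n_shots") <- n
  attr(out, "instrument_id") <- attr(scan, "instrument_id")
  attr(out, "timestamp") <- attr(scan, "timestamp")
  class(out) <- c("iml_profile", class(tibble::tibble()))
  out
}

#' Cumulative plant area index from gap probability
#'
#' Inverts the Beer-Lambert attenuation at the hinge angle:
#' `PAI(z) = -coefficient * ln(Pgap(z))`, with the conventional
#' coefficient 1.1 (the hinge-angle value `1/K(57.5, x)`, which is near
#' 1.07--1.1 for any realistic leaf angle distribution — see
#' [hinge_inverse_coefficient()]). Because returns do not separate leaves
#' from stems and branches, the result is a plant area index, not a leaf
#' area index.
#'
#' A bin where every shot was intercepted (Pgap = 0) would give infinite
#' PAI; such values are clipped to `1/(2N)` before the log, and the profile
#' is marked with a `saturated` attribute.
#'
#' @param profile An `iml_profile` tibble with a `pgap` column (from
#'   [gap_profile()]).
#' @param coefficient Inversion coefficient (default 1.1).
#' @return The profile with a `pai` column added; attribute `saturated` is
#'   `TRUE` if any Pgap hit 0.
#' @export
pai_profile <- function(profile, coefficient = 1.1) {
  stopifnot(is.data.frame(profile), "pgap" %in% names(profile))
  if (any(profile$pgap < 0 | profile$pgap > 1))
    stop("pgap must lie in [0, 1]", call. = FALSE)
  n <- attr(profile, "n_shots")
  floor_p <- if (is.null(n)) .Machine$double.eps else 1 / (2 * n)
  saturated <- any(profile$pgap == 0)
  p <- pmax(profile$pgap, floor_p)
  out <- dplyr::mutate(profile, pai = -coefficient * log(p))
  attr(out, "saturated") <- saturated
  attr(out, "coefficient") <- coefficient
  out
}

#' Plant area volume density from cumulative PAI
#'
#' Vertical derivative of the cumulative PAI profile by forward finite
#' difference on the uniform height grid: the PAVD assigned to the bin
#' ending at height `h_k` is `(PAI(h_k) - PAI(h_{k-1})) / bin_width`
#' (m2/m3). The first row (height 0) has no bin below it and gets `NA`.
#' `bin_width * sum(pavd)` telescopes exactly to PAI at the grid top.
#' An optional centred moving average smooths the result (default off).
#'
#' @param profile An `iml_profile` with a `pai` column.
#' @param smooth_window Odd integer moving-average window in bins;
#'   `1` (default) means no smoothing.
#' @return The profile with a `pavd` column added.
#' @export
pavd_profile <- function(profile, smooth_window = 1L) {
  stopifnot(is.data.frame(profile), "pai" %in% names(profile))
  h <- profile$height
  dh <- diff(h)
  if (length(dh) < 1L) stop("profile needs at least two heights", call. = FALSE)
  if (max(abs(dh - dh[1])) > 1e-9 * dh[1])
    stop("pavd requires a uniform height grid", call. = FALSE)
  pavd <- c(NA_real_, diff(profile$pai) / dh[1])
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L)
      stop("`smooth_window` must be odd", call. = FALSE)
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(pavd[-1], k, sides = 2)
    pavd <- c(NA_real_, as.numeric(sm))
  }
  dplyr::mutate(profile, pavd = pavd)
}

#' Full vertical profile from a scan
#'
#' Convenience chain [gap_profile()] |> [pai_profile()] |>
#' [pavd_profile()]: heights, gap probability, cumulative plant area index
#' and plant area volume density on one grid.
#'
#' @inheritParams gap_profile
#' @inheritParams pai_profile
#' @inheritParams pavd_profile
#' @return An `iml_profile` tibble with columns `height`, `pgap`, `pai`,
#'   `pavd`.
#' @examples
#' cm <- canopy_model(c(10, 15), c(0.05, 0.2))
#' s <- simulate_scan(cm, seed = 1)
#' p <- compute_profile(s)
#' top_of_canopy_pai(p)
#' @export
compute_profile <- function(scan, geom = instrument_geometry(),
                            grid = height_grid(), coefficient = 1.1,
                            smooth_window = 1L) {
  gap_profile(scan, geom, grid) |>
    pai_profile(coefficient = coefficient) |>
    pavd_profile(smooth_window = smooth_window)
}

#' Top-of-canopy plant area index
#'
#' The cumulative PAI at the highest grid height — the profile's
#' asymptote, used for long-term trend monitoring.
#'
#' @param profile An `iml_profile` with a `pai` column.
#' @return A single PAI value.
#' @export
top_of_canopy_pai <- function(profile) {
  stopifnot(is.data.frame(profile), "pai" %in% names(profile))
  profile$pai[nrow(profile)]
}

#' @export
print.iml_profile <- function(x, ...) {
  cat(sprintf("<iml_profile> %s | N = %s shots%s\n",
              attr(x, "instrument_id") %||% "?",
              attr(x, "n_shots") %||% "?",
              if (isTRUE(attr(x, "saturated"))) " | SATURATED" else ""))
  NextMethod()
}

#' Plot a vertical profile
#'
#' Height against cumulative PAI (and PAVD if present), the standard way
#' these profiles are displayed: height on the y axis.
#'
#' @param object An `iml_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iml_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::any_of(c("height", "pai", "pavd"))),
    -"height", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$height)) +
    ggplot2::geom_path(na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "height above instrument (m)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
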