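#' Aggregate daily profiles to a monthly series
#'
#' Per instrument and calendar month, the arithmetic mean of the daily
#' profiles (PAI(z), PAVD(z) averaged height-by-height) and of the
#' top-of-canopy PAI. Averaging the per-scan profiles is the default;
#' `method = "pool"` instead pools all shots of a month into one gap
#' profile before inversion (requires the original scans).
#'
#' @param profiles A list of `iml_profile` objects (retained daily scans,
#'   profiled on a common grid).
#' @param scans For `method = "pool"`, the matching list of [iml_scan()]
#'   objects.
#' @param method `"average"` (default) or `"pool"`.
#' @param geom,grid,coefficient Passed to [compute_profile()] when pooling.
#' @return An object of class `monthly_series`: a list with
#'   * `monthly` — tibble `instrument_id`, `month` (Date, first of month),
#'     `n_scans`, `pai_top`;
#'   * `profiles` — tibble of monthly mean profiles
#'     (`instrument_id`, `month`, `height`, `pai`, `pavd`).
#' @export
monthly_aggregate <- function(profiles, scans = NULL,
                              method = c("average", "pool"),
                              geom = instrument_geometry(),
                              grid = height_grid(), coefficient = 1.1) {
  method <- match.arg(method)
  if (!is.list(profiles) || length(profiles) == 0L)
    stop("need at least one retained daily profile", call. = FALSE)

  key <- purrr::map_dfr(profiles, function(p) tibble::tibble(
    instrument_id = attr(p, "instrument_id") %||% "UNKNOWN",
    month = as.Date(format(attr(p, "timestamp"), "%Y-%m-01"))
  ))

  if (method == "average") {
    daily <- purrr::imap_dfr(profiles, function(p, i) {
      dplyr::mutate(tibble::as_tibble(p),
                    instrument_id = key$instrument_id[i],
                    month = key$month[i], scan = i)
    })
    prof <- dplyr::summarise(
      dplyr::group_by(daily, .data$instrument_id, .data$month, .data$height),
      pai = mean(.data$pai), pavd = mean(.data$pavd),
      .groups = "drop"
    )
    monthly <- dplyr::summarise(
      dplyr::group_by(
        dplyr::mutate(key, pai_top = purrr::map_dbl(profiles, top_of_canopy_pai)),
        .data$instrument_id, .data$month
      ),
      n_scans = dplyr::n(), pai_top = mean(.data$pai_top), .groups = "drop"
    )
  } else {
    if (is.null(scans) || length(scans) != length(profiles))
      stop("`method = \"pool\"` needs the matching list of scans", call. = FALSE)
    groups <- split(seq_along(scans), paste(key$instrument_id, key$month))
    prof <- purrr::map_dfr(groups, function(idx) {
      pooled <- dplyr::bind_rows(lapply(scans[idx], tibble::as_tibble))
      pooled$index <- seq_len(nrow(pooled))
      ps <- iml_scan(pooled,
                     instrument_id = key$instrument_id[idx[1]],
                     timestamp = as.POSIXct(key$month[idx[1]], tz = "UTC"),
                     zenith = attr(scans[[idx[1]]], "zenith"))
      p <- compute_profile(ps, geom, grid, coefficient)
      dplyr::mutate(tibble::as_tibble(p),
                    instrument_id = key$instrument_id[idx[1]],
                    month = key$month[idx[1]])
    })
    monthly <- dplyr::summarise(
      dplyr::group_by(prof, .data$instrument_id, .data$month),
      n_scans = NA_integer_,
      pai_top = .data$pai[which.max(.data$height)], .groups = "drop"
    )
    prof <- dplyr::select(prof, "instrument_id", "month", "height",
                          "pai", "pavd")
  }
  monthly <- dplyr::arrange(monthly, .data$instrument_id, .data$month)
  structure(
    list(monthly = monthly,
         profiles = dplyr::arrange(prof, .data$instrument_id, .data$month,
                                   .data$height)),
    class = "monthly_series"
  )
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series> %d instrument(s), %d instrument-months\n",
              length(unique(x$monthly$instrument_id)), nrow(x$monthly)))
  print(x$monthly, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a monthly series
#'
#' @param x A `monthly_series`.
#' @param ... Unused.
#' @return The per-month tibble (`instrument_id`, `month`, `n_scans`,
#'   `pai_top`).
#' @export
tidy.monthly_series <- function(x, ...) x$monthly

#' Summary statistics of a monthly series
#'
#' One row per instrument with the long-term mean, maximum, minimum, range
#' and relative range of monthly top-of-canopy PAI (see
#' [pai_summary_stats()]).
#'
#' @param x A `monthly_series`.
#' @param ... Unused.
#' @return A tibble with one row per instrument.
#' @export
glance.monthly_series <- function(x, ...) {
  dplyr::reframe(dplyr::group_by(x$monthly, .data$instrument_id),
                 pai_summary_stats(.data$pai_top))
}

#' Summary statistics of a PAI series
#'
#' Long-term mean, maximum, minimum, absolute range (max - min) and
#' relative range as a percentage of the mean, rounded to the nearest
#' integer — the standard summary table for multi-season monitoring.
#'
#' @param pai Numeric vector of (monthly) PAI values, non-empty.
#' @return A one-row tibble: `mean`, `max`, `min`, `range`,
#'   `range_percent`.
#' @examples
#' pai_summary_stats(c(1.21, 1.32, 1.43))
#' @export
pai_summary_stats <- function(pai) {
  if (!is.numeric(pai) || length(pai) == 0L || anyNA(pai))
    stop("`pai` must be a non-empty numeric vector without NA", call. = FALSE)
  rng <- max(pai) - min(pai)
  tibble::tibble(
    mean = mean(pai), max = max(pai), min = min(pai), range = rng,
    range_percent = round(100 * rng / mean(pai))
  )
}

#' Fit a smooth long-term trend to monthly PAI
#'
#' Cubic spline through the monthly top-of-canopy PAI values, with month
#' midpoints as abscissae, sampled daily. Interpolation (the default)
#' passes exactly through the monthly values; `spar` switches to a
#' smoothing spline. Runs of missing months longer than `max_gap_months`
#' split the trend into separately fitted pieces rather than bridging the
#' gap (set `max_gap_months = Inf` to bridge).
#'
#' @param series A `monthly_series`, or a tibble with columns
#'   `instrument_id`, `month`, `pai_top`.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) interpolates with
#'   [stats::splinefun()] (method `"fmm"`, exact for cubics).
#' @param max_gap_months Largest run of missing months to interpolate
#'   across (default 1).
#' @return A tibble: `instrument_id`, `date`, `pai_trend`, `piece`.
#' @export
fit_trend <- function(series, spar = NULL, max_gap_months = 1) {
  monthly <- if (inherits(series, "monthly_series")) series$monthly else
    tibble::as_tibble(series)
  stopifnot(all(c("instrument_id", "month", "pai_top") %in% names(monthly)))

  fit_one <- function(d) {
    d <- dplyr::arrange(d, .data$month)
    if (nrow(d) < 4L)
      stop("fewer than 4 monthly points: spline interpolation is unreliable",
           call. = FALSE)
    mid <- month_midpoint(d$month)
    # split into pieces at gaps longer than max_gap_months
    gap <- c(0, diff(month_index(d$month)))
    piece <- cumsum(gap > max_gap_months + 1)
    purrr::map_dfr(split(seq_len(nrow(d)), piece), function(idx) {
      if (length(idx) < 2L) {
        return(tibble::tibble(date = as.Date(round(mid[idx]),
                                             origin = "1970-01-01"),
                              pai_trend = d$pai_top[idx],
                              piece = piece[idx[1]]))
      }
      xs <- seq(ceiling(mid[idx[1]]), floor(mid[idx[length(idx)]]), by = 1)
      ys <- if (is.null(spar)) {
        stats::splinefun(mid[idx], d$pai_top[idx], method = "fmm")(xs)
      } else {
        stats::predict(stats::smooth.spline(mid[idx], d$pai_top[idx],
                                            spar = spar), xs)$y
      }
      tibble::tibble(date = as.Date(xs, origin = "1970-01-01"),
                     pai_trend = ys, piece = piece[idx[1]])
    })
  }

  out <- dplyr::group_modify(dplyr::group_by(monthly, .data$instrument_id),
                             ~fit_one(.x))
  dplyr::ungroup(out)
}

month_index <- function(month) {
  as.integer(format(month, "%Y")) * 12L + as.integer(format(month, "%m"))
}

month_midpoint <- function(month) {
  nxt <- seq_month <- as.Date(vapply(month, function(m) {
    as.character(seq(m, by = "month", length.out = 2)[2])
  }, ""))
  as.numeric(month) + as.numeric(nxt - month) / 2
}

#' Plot a monthly series with its fitted trend
#'
#' Monthly top-of-canopy PAI as points, spline trend as lines, coloured by
#' instrument.
#'
#' @param object A `monthly_series`.
#' @param trend Optional precomputed [fit_trend()] tibble; fitted on the
#'   fly when `NULL` and at least 4 months are present.
#' @param ... Passed to [fit_trend()].
#' @return A ggplot object.
#' @export
autoplot.monthly_series <- function(object, trend = NULL, ...) {
  monthly <- object$monthly
  p <- ggplot2::ggplot(
    monthly,
    ggplot2::aes(.data$month + 14, .data$pai_top,
                 colour = .data$instrument_id)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "top-of-canopy PAI", colour = "instrument")
  if (is.null(trend) && min(table(monthly$instrument_id)) >= 4)
    trend <- fit_trend(object, ...)
  if (!is.null(trend)) {
    p <- p + ggplot2::geom_line(
      data = trend,
      ggplot2::aes(.data$date, .data$pai_trend,
                   colour = .data$instrument_id,
                   group = interaction(.data$instrument_id, .data$piece))
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
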