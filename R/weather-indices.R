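# Station-weather indices: eight-day temperature integrands, threshold weeks,
# growing degree units, and climatograph water-balance classification.
#
# Daily weather tables are tibbles with one row per day and columns
# `doy`, `tmin`, `tmax`, `precip_mm`, and optionally `tmean`. When `tmean`
# is absent it defaults to (tmin + tmax) / 2.

.with_tmean <- function(weather) {
  stopifnot(is.data.frame(weather))
  if (!"tmean" %in% names(weather)) {
    if (!all(c("tmin", "tmax") %in% names(weather))) {
      abort("weather table needs either `tmean` or both `tmin` and `tmax`")
    }
    weather$tmean <- (weather$tmin + weather$tmax) / 2
  }
  weather
}

#' Eight-day temperature integrand
#'
#' Area under the curve of mean daily temperature across one eight-day
#' composite interval, by the trapezoidal rule with unit (1-day) spacing:
#' eight daily samples span seven unit panels, so a constant series of value
#' `c` integrates to `7 * c`. Up to two missing days are filled by linear
#' interpolation between the nearest present days (series endpoints are
#' extended flat); more than two missing days invalidate the interval.
#'
#' @param weather Daily weather tibble with `doy` and `tmean` (or
#'   `tmin`/`tmax`).
#' @param interval Eight-day interval index (1--46).
#' @return The integrand in degC-day, or `NA_real_` if the interval has more
#'   than two missing days.
#' @examples
#' w <- tibble::tibble(doy = 1:8, tmean = c(-4, -3, -2, -1, 0, 1, 2, 3))
#' eight_day_temperature_integrand(w, 1) # -3.5
#' @export
eight_day_temperature_integrand <- function(weather, interval) {
  stopifnot(length(interval) == 1, interval >= 1)
  weather <- .with_tmean(weather)
  days <- eight_day_start(interval) + 0:7
  y <- weather$tmean[match(days, weather$doy)]
  n_missing <- sum(is.na(y))
  if (n_missing > 2) {
    return(NA_real_)
  }
  if (n_missing > 0) {
    y <- .fill_linear(y)
  }
  trapezoid_area(y)
}

# Trapezoidal area of a numeric series at unit spacing.
trapezoid_area <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 2 || anyNA(y)) {
    return(NA_real_)
  }
  sum(y) - (y[1] + y[length(y)]) / 2
}

# Linear interpolation of interior NAs; flat extension at the ends.
.fill_linear <- function(y) {
  idx <- which(!is.na(y))
  if (length(idx) == 0) {
    return(y)
  }
  out <- stats::approx(idx, y[idx], xout = seq_along(y), rule = 2)$y
  out
}

#' First eight-day interval with a non-negative temperature integrand
#'
#' Scans intervals from the start of the year and returns the smallest index
#' whose eight-day temperature integrand is `>= 0` degC-day, the operational
#' marker for the transition out of winter conditions. Intervals invalidated
#' by missing data are skipped.
#'
#' @inheritParams eight_day_temperature_integrand
#' @param max_interval Last interval scanned (default 31, i.e. through
#'   August).
#' @return Integer interval index, or `NA_integer_` when no interval
#'   qualifies within the scanned span.
#' @export
first_nonnegative_interval <- function(weather, max_interval = 31L) {
  for (k in seq_len(max_interval)) {
    v <- eight_day_temperature_integrand(weather, k)
    if (!is.na(v) && v >= 0) {
      return(as.integer(k))
    }
  }
  NA_integer_
}

#' First week at or above a mean-temperature threshold
#'
#' Weeks are 7-day intervals beginning January 1. Returns the first week whose
#' mean of daily mean temperatures is `>=` the threshold (10 degC by default,
#' the conventional floor for photosynthetic activity).
#'
#' @inheritParams eight_day_temperature_integrand
#' @param threshold Mean-temperature threshold in degC.
#' @param max_week Last week scanned (default 35, through August).
#' @return Integer week index or `NA_integer_`.
#' @export
first_week_at_threshold <- function(weather, threshold = 10, max_week = 35L) {
  weather <- .with_tmean(weather)
  wk <- weekly_mean_temperature(weather, max_week = max_week)
  hit <- which(!is.na(wk$tmean_week) & wk$tmean_week >= threshold)
  if (length(hit) == 0) {
    return(NA_integer_)
  }
  wk$week[hit[1]]
}

#' Weekly mean temperature table
#'
#' @inheritParams first_week_at_threshold
#' @return A tibble with `week` and `tmean_week` (mean of available daily
#'   values in the week; `NA` for empty weeks).
#' @export
weekly_mean_temperature <- function(weather, max_week = 52L) {
  weather <- .with_tmean(weather)
  weather %>%
    mutate(week = week_of(.data$doy)) %>%
    filter(.data$week <= max_week) %>%
    group_by(.data$week) %>%
    summarise(
      tmean_week = if (all(is.na(.data$tmean))) NA_real_ else
        mean(.data$tmean, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Daily growing degree units (Method 2)
#'
#' Heat accumulation above a 10 degC baseline with both daily extremes clamped
#' into the `[base, cap]` range *before* averaging:
#' `gdu = (clamp(tmax) + clamp(tmin)) / 2 - base`. With the default base of
#' 10 degC and cap of 30 degC daily values lie in `[0, 20]` degC-day.
#'
#' @param tmin,tmax Daily minimum and maximum temperature, degC (vectorised).
#' @param base Baseline temperature, degC (default 10).
#' @param cap Upper temperature limit, degC (default 30).
#' @return Numeric vector of daily GDU.
#' @examples
#' daily_gdu(2, 8)    # 0: both extremes below baseline
#' daily_gdu(10, 20)  # 5
#' daily_gdu(25, 35)  # 17.5: tmax clamped at 30
#' @export
daily_gdu <- function(tmin, tmax, base = 10, cap = 30) {
  if (any(tmin > tmax, na.rm = TRUE)) {
    abort("daily_gdu(): tmin exceeds tmax")
  }
  cl <- function(x) pmin(pmax(x, base), cap)
  (cl(tmax) + cl(tmin)) / 2 - base
}

#' Weekly and cumulative growing degree units
#'
#' @inheritParams eight_day_temperature_integrand
#' @inheritParams daily_gdu
#' @return A tibble with one row per day: `doy`, `daily_gdu`,
#'   `cumulative_gdu`, `week`, plus a `weekly_gdu` column repeated within each
#'   week (sum of the week's daily values).
#' @export
gdu_series <- function(weather, base = 10, cap = 30) {
  stopifnot(all(c("doy", "tmin", "tmax") %in% names(weather)))
  out <- weather %>%
    arrange(.data$doy) %>%
    mutate(
      daily_gdu = daily_gdu(.data$tmin, .data$tmax, base = base, cap = cap),
      cumulative_gdu = cumsum(.data$daily_gdu),
      week = week_of(.data$doy)
    ) %>%
    group_by(.data$week) %>%
    mutate(weekly_gdu = sum(.data$daily_gdu)) %>%
    ungroup()
  out %>% select(
    "doy", "daily_gdu", "cumulative_gdu", "week", "weekly_gdu"
  )
}

#' Classify a four-week climatograph window as surplus or deficit
#'
#' Walter-diagram style water balance on a sliding four-week window ending at
#' `end_week`: the window is a deficit when its total precipitation (mm) falls
#' below `2 * max(mean temperature, 0)` -- the 2 mm-per-degC equivalency that
#' pairs 20 mm of precipitation with a 10 degC mean. Equality and sub-zero
#' mean temperatures (threshold floored at 0 mm) classify as surplus.
#'
#' @inheritParams eight_day_temperature_integrand
#' @param end_week Week index at which the four-week window ends (>= 4).
#' @return One-row tibble: `end_week`, `precip_total_mm`, `tmean_window`,
#'   `status` (`"surplus"` or `"deficit"`); zero rows if the window is not
#'   fully covered by the weather table.
#' @export
climatograph_classify <- function(weather, end_week) {
  stopifnot(length(end_week) == 1, end_week >= 4)
  weather <- .with_tmean(weather)
  days <- week_start(end_week - 3L):(week_start(end_week) + 6L)
  rows <- match(days, weather$doy)
  if (anyNA(rows)) {
    return(tibble(
      end_week = integer(), precip_total_mm = double(),
      tmean_window = double(), status = character()
    ))
  }
  precip <- sum(weather$precip_mm[rows])
  tmean <- mean(weather$tmean[rows])
  threshold <- 2 * max(tmean, 0)
  tibble(
    end_week = as.integer(end_week),
    precip_total_mm = precip,
    tmean_window = tmean,
    status = if (precip < threshold) "deficit" else "surplus"
  )
}

#' Climatograph status sequence across a season
#'
#' @inheritParams eight_day_temperature_integrand
#' @param weeks End-weeks to classify (default 4 through 34).
#' @return Tibble of [climatograph_classify()] rows, one per covered window.
#' @export
climatograph_series <- function(weather, weeks = 4:34) {
  purrr::map_dfr(weeks, function(w) climatograph_classify(weather, w))
}
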