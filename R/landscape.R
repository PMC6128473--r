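# Landscape remote sensing: snow-free onset from 8-day snow composites,
# the 8-day-to-weekly crosswalk, NDVI smoothing and green-up, ET onset,
# multi-interval accumulations, and the correlation battery against station
# weather.

#' Snow-free onset for one composite cell
#'
#' The onset of continuous snow-free conditions is the start date of the
#' first of two contiguous snow-free eight-day composites, where the first
#' composite of the pair starts on or after a late-winter cutoff (day 46 =
#' Feb 15 for field-scale analyses; day 59 = end of February for
#' remote-sensing analyses).
#'
#' @param flags Tibble with `interval` (composite index), `start_doy`, and
#'   `snow` (logical: snow present on >= 1 day of the window).
#' @param cutoff_doy Earliest allowed start day of the pair's first composite.
#' @return Integer onset day-of-year, or `NA_integer_` if no qualifying pair.
#' @export
snow_free_onset_cell <- function(flags, cutoff_doy = 46L) {
  stopifnot(all(c("interval", "start_doy", "snow") %in% names(flags)))
  flags <- flags %>% arrange(.data$interval)
  ok <- !flags$snow
  pair <- ok[-length(ok)] & ok[-1]
  eligible <- which(pair & flags$start_doy[-length(ok)] >= cutoff_doy)
  if (length(eligible) == 0) {
    return(NA_integer_)
  }
  as.integer(flags$start_doy[eligible[1]])
}

#' Block snow-off date from per-cell onsets
#'
#' Averages the per-cell snow-free onset days across the (up to 16) 500-m
#' cells of a 4-km2 block: arithmetic mean of day-of-year values rounded
#' half-up, plus the containing week index. Cells with no onset are dropped
#' with a warning.
#'
#' @param cell_onsets Integer vector of per-cell onset days (may contain NA).
#' @return One-row tibble: `mean_onset_doy`, `week`, `n_cells_used`,
#'   `n_cells_missing`; `NA`s if no cell has an onset.
#' @export
block_snow_off <- function(cell_onsets) {
  found <- cell_onsets[!is.na(cell_onsets)]
  n_missing <- sum(is.na(cell_onsets))
  if (length(found) == 0) {
    return(tibble(
      mean_onset_doy = NA_integer_, week = NA_integer_,
      n_cells_used = 0L, n_cells_missing = n_missing
    ))
  }
  if (n_missing > 0) {
    warn(sprintf("block_snow_off(): %d cell(s) without onset dropped",
                 n_missing))
  }
  doy <- as.integer(floor(mean(found) + 0.5)) # round half-up
  tibble(
    mean_onset_doy = doy, week = week_of(doy),
    n_cells_used = length(found), n_cells_missing = n_missing
  )
}

#' Crosswalk eight-day composites to the weekly calendar
#'
#' Each eight-day composite (start day `1 + 8(k-1)`) is assigned to the week
#' (start day `1 + 7(w-1)`) whose start is nearest its own, ties going to the
#' later week. The assignment is injective, so some weeks receive no
#' composite ("orphan" weeks); within weeks 1--34 these are weeks 5, 13, 21
#' and 29.
#'
#' @param n_days Days in the year (default 365 -> 46 composites).
#' @return List with `map` (tibble: `interval`, `start_doy`, `week`) and
#'   `orphan_weeks` (integer vector of unassigned weeks within 1--52).
#' @export
composite_week_crosswalk <- function(n_days = 365L) {
  comp <- eight_day_intervals(n_days)
  n_weeks <- ceiling(n_days / 7)
  wstart <- week_start(seq_len(n_weeks))
  assign_week <- function(s) {
    d <- abs(wstart - s)
    cand <- which(d == min(d))
    as.integer(max(cand)) # tie -> later week
  }
  comp$week <- vapply(comp$start_doy, assign_week, integer(1))
  if (anyDuplicated(comp$week)) {
    abort("composite_week_crosswalk(): non-injective assignment")
  }
  list(
    map = comp %>% select("interval", "start_doy", "week"),
    orphan_weeks = setdiff(seq_len(n_weeks), comp$week)
  )
}

#' Align an eight-day composite series to weeks
#'
#' @param series Tibble with `interval` and a value column.
#' @param value Name of the value column (string).
#' @param n_days Days in the year.
#' @param max_week Last week retained (default 52).
#' @return Tibble with `week` 1..`max_week` and the value column; orphan
#'   weeks carry `NA`.
#' @export
align_composites_to_weeks <- function(series, value, n_days = 365L,
                                      max_week = 52L) {
  cw <- composite_week_crosswalk(n_days)$map
  out <- tibble(week = seq_len(max_week)) %>%
    left_join(cw, by = "week") %>%
    left_join(series, by = "interval")
  out %>% select("week", dplyr::all_of(value))
}

#' Expected pooled weekly record counts
#'
#' Bookkeeping for pooled correlation analyses: the number of block-week
#' records contributed by `n_site_years` site-years over weeks
#' 1..`max_week`, after removing crosswalk-orphan weeks for eight-day
#' streams. A weekly stream (NDVI) covers all 34 weeks; an eight-day stream
#' (ET) covers 30.
#'
#' @param n_site_years Number of block-years pooled.
#' @param cadence `"7-day"` (no orphans) or `"8-day"` (orphan weeks removed).
#' @param max_week Last week of the analysis span (default 34, January
#'   through August).
#' @return Integer record count.
#' @export
pooled_weekly_n <- function(n_site_years, cadence = c("7-day", "8-day"),
                            max_week = 34L) {
  cadence <- match.arg(cadence)
  orphans <- composite_week_crosswalk()$orphan_weeks
  covered <- if (cadence == "8-day") {
    max_week - sum(orphans <= max_week)
  } else {
    max_week
  }
  as.integer(n_site_years * covered)
}

#' Smooth a weekly NDVI series
#'
#' Sliding three-point weighted least-squares smoother with a peak-preserving
#' upward bias: every window of three consecutive weeks gets a linear fit,
#' each week's smoothed value is a weighted mean of the predictions from the
#' (up to three) windows covering it, and windows whose prediction is at or
#' above the observed value are weighted `upweight` times (default 2) so the
#' smoother resists cloud-driven downward spikes. Endpoints keep their
#' single-window estimate; linear series pass through unchanged. Output is
#' clipped to `[-1, 1]`.
#'
#' @param ndvi Numeric weekly NDVI vector (length >= 5; interior NAs are
#'   first filled by linear interpolation).
#' @param upweight Weight multiplier for upward-predicting windows.
#' @return Numeric vector, same length.
#' @export
smooth_ndvi <- function(ndvi, upweight = 2) {
  y <- as.numeric(ndvi)
  if (all(is.na(y))) {
    abort("smooth_ndvi(): all-missing series")
  }
  if (length(y) < 5) {
    abort("smooth_ndvi(): need at least 5 weeks")
  }
  y <- .fill_linear(y)
  n <- length(y)
  pred_sum <- numeric(n)
  w_sum <- numeric(n)
  for (s in seq_len(n - 2)) {
    idx <- s:(s + 2)
    xs <- c(-1, 0, 1)
    ys <- y[idx]
    b <- (ys[3] - ys[1]) / 2
    a <- mean(ys)
    preds <- a + b * xs
    wts <- ifelse(preds >= ys, upweight, 1)
    pred_sum[idx] <- pred_sum[idx] + wts * preds
    w_sum[idx] <- w_sum[idx] + wts
  }
  out <- pred_sum / w_sum
  pmin(pmax(out, -1), 1)
}

#' Winter background NDVI level
#'
#' Median of smoothed NDVI over weeks 1--8, pooled across years, per block;
#' the area-level background is the mean of block backgrounds.
#'
#' @param ndvi_weekly Tibble with `block_id`, `year`, `week`, `ndvi`
#'   (smoothed or raw; smoothing is applied per block-year here if
#'   `smooth = TRUE`).
#' @param smooth Smooth each block-year series first (default `TRUE`).
#' @return List with `block` (tibble `block_id`, `background`) and `area`
#'   (scalar mean over blocks).
#' @export
winter_background <- function(ndvi_weekly, smooth = TRUE) {
  stopifnot(all(c("block_id", "year", "week", "ndvi") %in% names(ndvi_weekly)))
  prep <- ndvi_weekly %>%
    arrange(.data$block_id, .data$year, .data$week) %>%
    group_by(.data$block_id, .data$year) %>%
    mutate(ndvi_s = if (smooth) smooth_ndvi(.data$ndvi) else .data$ndvi) %>%
    ungroup()
  block <- prep %>%
    filter(.data$week <= 8) %>%
    group_by(.data$block_id) %>%
    summarise(background = median(.data$ndvi_s, na.rm = TRUE),
              .groups = "drop")
  list(block = block, area = mean(block$background))
}

#' Green-up week from a smoothed NDVI series
#'
#' First post-February week (week start day-of-year >= 60) in which NDVI
#' exceeds the threshold. The comparison is strict (`>`) by default;
#' `inclusive = TRUE` uses `>=`. Pre-March excursions above the threshold
#' (false green-up under intermittent snow) are ignored by construction.
#'
#' @param ndvi Numeric weekly NDVI vector indexed by week 1..length.
#' @param threshold Green-up threshold (default 0.60).
#' @param inclusive Use `>=` instead of strict `>`.
#' @return Integer week index or `NA_integer_`.
#' @export
green_up_week <- function(ndvi, threshold = 0.60, inclusive = FALSE) {
  weeks <- seq_along(ndvi)
  eligible <- week_start(weeks) >= .POST_FEBRUARY_DOY
  above <- if (inclusive) ndvi >= threshold else ndvi > threshold
  hit <- which(eligible & !is.na(above) & above)
  if (length(hit) == 0) {
    return(NA_integer_)
  }
  as.integer(hit[1])
}

#' Count of growing weeks above an NDVI threshold
#'
#' @inheritParams green_up_week
#' @param max_week Last week considered (default 34, through August).
#' @return Integer count of weeks with NDVI strictly above the threshold;
#'   missing weeks are excluded.
#' @export
growing_weeks_count <- function(ndvi, threshold = 0.60, max_week = 34L) {
  weeks <- seq_along(ndvi)
  keep <- weeks <= max_week & !is.na(ndvi)
  sum(ndvi[keep] > threshold)
}

#' Evapotranspiration onset week
#'
#' First week of the weekly-aligned ET series with total ET strictly greater
#' than 1 mm. Orphan weeks (no composite assigned) are `NA` and skipped.
#'
#' @param et_weekly Numeric weekly ET vector (mm; `NA` at orphan weeks).
#' @param threshold_mm Onset threshold (default 1 mm, strict).
#' @return Integer week index or `NA_integer_`.
#' @export
et_onset_week <- function(et_weekly, threshold_mm = 1) {
  hit <- which(!is.na(et_weekly) & et_weekly > threshold_mm)
  if (length(hit) == 0) {
    return(NA_integer_)
  }
  as.integer(hit[1])
}

#' Weekly, running four-week, and to-date accumulations
#'
#' The three time scales used in the weather-association battery: the weekly
#' value itself; the running four-week total (sum over weeks w-3..w,
#' incremented weekly, defined from week 4); and the to-date cumulative total
#' from week 1. Missing weeks are skipped-and-summed: they contribute nothing
#' but do not invalidate the window.
#'
#' @param weekly Numeric weekly value vector (weeks 1..length; `NA` =
#'   missing).
#' @return Tibble with `week`, `weekly`, `four_week`, `to_date`
#'   (`four_week` is `NA` before week 4).
#' @export
accumulate_weekly <- function(weekly) {
  n <- length(weekly)
  filled <- ifelse(is.na(weekly), 0, weekly)
  to_date <- cumsum(filled)
  four_week <- rep(NA_real_, n)
  if (n >= 4) {
    cs <- c(0, to_date)
    four_week[4:n] <- cs[(4:n) + 1] - cs[(4:n) - 3]
  }
  tibble(
    week = seq_len(n), weekly = as.numeric(weekly),
    four_week = four_week, to_date = to_date
  )
}

#' Correlate landscape responses with station weather drivers
#'
#' Pools block-week records across blocks and years and computes a Spearman
#' rank correlation per (response, driver, time-interval) cell, in the shape
#' of a seasonal weather-association table. In `"levels"` mode the weekly,
#' four-week and to-date accumulations are correlated directly; in
#' `"deltas"` mode week-over-week first differences of the weekly values are
#' used, which strips the shared seasonal trend (temporal autocorrelation)
#' that inflates levels-mode correlations.
#'
#' @param responses Tibble with `block_id`, `year`, `week`, `value`,
#'   `stream` (e.g. `"et"`, `"ndvi"`); weeks 1--`max_week`, `NA` at weeks
#'   with no record (orphans for eight-day streams).
#' @param drivers Tibble with `station_id`, `year`, `week`, `value`,
#'   `stream` (e.g. `"gdu"`, `"precip"`).
#' @param mapping Tibble with `block_id`, `station_id` linking each block to
#'   its weather station.
#' @param mode `"levels"` or `"deltas"`.
#' @param max_week Analysis span end (default 34).
#' @return Tibble with `response`, `driver`, `interval` (weekly / four_week /
#'   to_date; deltas mode reports `weekly_delta` only), `rho`, `n`.
#' @export
correlate_with_weather <- function(responses, drivers, mapping,
                                   mode = c("levels", "deltas"),
                                   max_week = 34L) {
  mode <- match.arg(mode)
  stopifnot(all(c("block_id", "year", "week", "value", "stream")
                %in% names(responses)))
  stopifnot(all(c("station_id", "year", "week", "value", "stream")
                %in% names(drivers)))
  resp_span <- range(responses$year)
  drv_span <- range(drivers$year)
  if (resp_span[1] < drv_span[1] || resp_span[2] > drv_span[2]) {
    abort(sprintf(
      "correlate_with_weather(): response years %d-%d not covered by driver years %d-%d",
      resp_span[1], resp_span[2], drv_span[1], drv_span[2]
    ))
  }
  responses <- responses %>% filter(.data$week <= max_week)
  drivers <- drivers %>% filter(.data$week <= max_week)

  acc3 <- function(df, val_col) {
    # per series: weekly/four_week/to_date (levels) or weekly delta
    df <- df %>% arrange(.data$week)
    full <- rep(NA_real_, max_week)
    full[df$week] <- df[[val_col]]
    if (mode == "levels") {
      accumulate_weekly(full) %>%
        tidyr::pivot_longer(c("weekly", "four_week", "to_date"),
                            names_to = "interval", values_to = "v")
    } else {
      obs <- which(!is.na(full))
      delta <- rep(NA_real_, max_week)
      if (length(obs) > 1) {
        delta[obs[-1]] <- diff(full[obs])
      }
      tibble(week = seq_len(max_week), interval = "weekly_delta", v = delta)
    }
  }

  resp_acc <- responses %>%
    group_by(.data$stream, .data$block_id, .data$year) %>%
    dplyr::group_modify(~ acc3(.x, "value")) %>%
    ungroup() %>%
    rename(response = "stream", rv = "v")
  drv_acc <- drivers %>%
    group_by(.data$stream, .data$station_id, .data$year) %>%
    dplyr::group_modify(~ acc3(.x, "value")) %>%
    ungroup() %>%
    rename(driver = "stream", dv = "v")

  joined <- resp_acc %>%
    left_join(mapping, by = "block_id") %>%
    dplyr::inner_join(
      drv_acc,
      by = c("station_id", "year", "week", "interval"),
      relationship = "many-to-many"
    ) %>%
    filter(!is.na(.data$rv), !is.na(.data$dv))

  joined %>%
    group_by(.data$response, .data$driver, .data$interval) %>%
    summarise(
      rho = cor(rank(.data$rv), rank(.data$dv)),
      n = dplyr::n(),
      .groups = "drop"
    )
}
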