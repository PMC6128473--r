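# Acoustic analyses on spectral-summary grids: band medians, the evening
# calling-activity integrand, signature matching, first call, presence, and
# phenophase summaries.
#
# A spectral-summary grid is a tibble with one row per (date, hour, bin):
# `site_id`, `date` (Date), `hour` (0--23), `bin_hz` (bin start, 0--10900 in
# 100-Hz steps), `min_db`, `mean_db`, `max_db`. dB values live in [-88, 0]:
# -88 dB is the recorder noise floor, 0 dB the clipping ceiling.

#' Recorder noise floor (dB)
#'
#' The approximate level below which recorder background noise dominates;
#' all spectral-summary values are floored here and the calling-activity
#' integrand is measured above it.
#' @export
DB_FLOOR <- -88

.BIN_HZ <- 100L
.N_BINS <- 110L

.grid_cols <- c("site_id", "date", "hour", "bin_hz",
                "min_db", "mean_db", "max_db")

.check_grid <- function(grid) {
  stopifnot(all(.grid_cols %in% names(grid)))
  invisible(grid)
}

# Bin start frequencies whose full [bin, bin+100) interval lies within
# the half-open band [lo, hi).
band_bin_starts <- function(band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (any(band %% .BIN_HZ != 0)) {
    abort("band limits must align to 100-Hz bins")
  }
  starts <- seq(0L, (.N_BINS - 1L) * .BIN_HZ, by = .BIN_HZ)
  starts[starts >= band[1] & (starts + .BIN_HZ) <= band[2]]
}

#' Hourly band median level
#'
#' Median of the mean-dB values across all 100-Hz bins fully contained in
#' the half-open band `[lo, hi)`, for one recording (date, hour). An absent
#' recording returns `NA_real_`, which is distinct from silence (-88 dB).
#'
#' @param grid Spectral-summary grid tibble.
#' @param date Date of the recording.
#' @param hour Hour of the recording (0--23).
#' @param band Numeric length-2 band in Hz, aligned to 100-Hz bins.
#' @return Median dB, or `NA_real_` if the (date, hour) entry is absent.
#' @export
band_hourly_median <- function(grid, date, hour, band = c(2900, 3200)) {
  .check_grid(grid)
  bins <- band_bin_starts(band)
  sub <- grid %>%
    filter(.data$date == as.Date(.env$date), .data$hour == .env$hour,
           .data$bin_hz %in% bins)
  if (nrow(sub) == 0) {
    return(NA_real_)
  }
  median(sub$mean_db)
}

#' Daily calling-activity integrand
#'
#' Area under the curve of hourly band median levels across a fixed set of
#' consecutive evening hours, offset so that silence maps to zero: the
#' trapezoidal integral (unit hour spacing) of `(band median + 88)`. With the
#' defaults -- the 2900--3200 Hz band and hours 21, 22, 23 -- a constant
#' level 40 dB above the floor integrates to 80 dB-hour.
#'
#' @inheritParams band_hourly_median
#' @param hours Ordered consecutive hours (default `21:23`).
#' @return Non-negative integrand in dB-hour, or `NA_real_` when fewer than
#'   two of the hours have recordings (invalid date).
#' @export
daily_activity_integrand <- function(grid, date, band = c(2900, 3200),
                                     hours = 21:23) {
  stopifnot(length(hours) >= 2, all(diff(hours) == 1))
  m <- vapply(hours, function(h) band_hourly_median(grid, date, h, band),
              numeric(1))
  if (anyNA(m)) {
    return(NA_real_)
  }
  max(trapezoid_area(m - DB_FLOOR), 0)
}

#' Daily calling-activity series with masking
#'
#' Computes the calling-activity integrand for every date in the grid and
#' flags dates masked by broadband noise (wind, rain): a date is masked when
#' the median of out-of-band mean-dB values across the evening hours exceeds
#' `mask_threshold_db`. Masked dates keep their integrand but are excluded
#' from peak ranking downstream.
#'
#' @inheritParams daily_activity_integrand
#' @param mask_threshold_db Broadband masking threshold (default -40 dB).
#' @return Tibble of class `wetscape_activity`: `site_id`, `date`,
#'   `integrand`, `valid`, `masked`.
#' @export
calling_activity <- function(grid, band = c(2900, 3200), hours = 21:23,
                             mask_threshold_db = -40) {
  .check_grid(grid)
  bins <- band_bin_starts(band)
  daily <- grid %>%
    filter(.data$hour %in% hours) %>%
    mutate(in_band = .data$bin_hz %in% bins) %>%
    group_by(.data$site_id, .data$date) %>%
    summarise(
      n_hours = dplyr::n_distinct(.data$hour),
      broadband = median(.data$mean_db[!.data$in_band]),
      .groups = "drop"
    )
  integrands <- vapply(
    seq_len(nrow(daily)),
    function(i) daily_activity_integrand(grid, daily$date[i], band, hours),
    numeric(1)
  )
  out <- daily %>%
    mutate(
      integrand = integrands,
      valid = .data$n_hours >= 2 & !is.na(integrands),
      masked = .data$broadband > mask_threshold_db
    ) %>%
    select("site_id", "date", "integrand", "valid", "masked") %>%
    arrange(.data$date)
  class(out) <- c("wetscape_activity", class(out))
  out
}

# Internal: reshape a grid's max-dB values into a [slot x bin] matrix with a
# slot key tibble (site_id, date, hour). Grids store bins densely, so a
# straight matrix fill after sorting is safe; a ragged grid falls back to a
# slower complete() path.
.grid_max_matrix <- function(grid) {
  g <- grid %>% arrange(.data$date, .data$hour, .data$bin_hz)
  slots <- g %>% distinct(.data$site_id, .data$date, .data$hour)
  if (nrow(g) != nrow(slots) * .N_BINS) {
    g <- g %>%
      tidyr::complete(
        tidyr::nesting(site_id = .data$site_id, date = .data$date,
                       hour = .data$hour),
        bin_hz = seq(0L, (.N_BINS - 1L) * .BIN_HZ, by = .BIN_HZ),
        fill = list(max_db = DB_FLOOR)
      ) %>%
      arrange(.data$date, .data$hour, .data$bin_hz)
    slots <- g %>% distinct(.data$site_id, .data$date, .data$hour)
  }
  m <- matrix(g$max_db, nrow = nrow(slots), ncol = .N_BINS, byrow = TRUE)
  list(max_db = m, slots = slots)
}

# Internal: per-slot detection for one signature on a prepared matrix.
# A slot detects when every signature peak's bin max-dB clears
# floor + margin + rel_db and is a strict local maximum within +/- 1 bin
# (a flat broadband spectrum has no local maxima, so rain-masked recordings
# cannot detect). Returns logical vector + mean exceedance score.
.match_on_matrix <- function(mm, signature, margin_db) {
  m <- mm$max_db
  ok <- rep(TRUE, nrow(m))
  exceed <- matrix(0, nrow(m), nrow(signature$peaks))
  for (j in seq_len(nrow(signature$peaks))) {
    bin <- signature$peaks$freq_hz[j] %/% .BIN_HZ + 1L
    thr <- DB_FLOOR + margin_db + signature$peaks$rel_db[j]
    v <- m[, bin]
    level_ok <- v >= thr
    local_max <- rep(TRUE, nrow(m))
    if (bin > 1L) local_max <- local_max & (v > m[, bin - 1L])
    if (bin < .N_BINS) local_max <- local_max & (v > m[, bin + 1L])
    ok <- ok & level_ok & local_max
    exceed[, j] <- v - thr
  }
  list(detected = ok, score = ifelse(ok, rowMeans(exceed), 0))
}

#' Match one call signature in one recording
#'
#' A recording matches when every peak of the signature clears a margin
#' above the noise floor (offset by the peak's relative intensity) *and*
#' sits on a strict local maximum of the spectrum within one bin. The score
#' is the mean exceedance over peaks.
#'
#' @inheritParams band_hourly_median
#' @param signature A [call_signature()].
#' @param margin_db Detection margin above the floor, dB (> 0). The default
#'   of 10 dB sits far above plausible excursions of the recorder's own
#'   noise floor, so an empty soundscape cannot produce chance detections
#'   even across hundreds of thousands of recordings; real calls sit tens
#'   of dB above the floor, so the margin costs no sensitivity.
#' @return One-row tibble: `species`, `date`, `hour`, `detected`, `score`.
#' @export
match_signature <- function(grid, date, hour, signature, margin_db = 10) {
  stopifnot(margin_db > 0)
  .check_grid(grid)
  sub <- grid %>%
    filter(.data$date == as.Date(.env$date), .data$hour == .env$hour)
  if (nrow(sub) == 0) {
    return(tibble(species = signature$species, date = as.Date(date),
                  hour = as.integer(hour), detected = FALSE, score = 0))
  }
  mm <- .grid_max_matrix(sub)
  res <- .match_on_matrix(mm, signature, margin_db)
  tibble(
    species = signature$species, date = as.Date(date),
    hour = as.integer(hour), detected = res$detected[1],
    score = res$score[1]
  )
}

#' Scan a grid for all signature detections
#'
#' Exhaustive template matching of every signature against every recording
#' in the grid.
#'
#' @inheritParams match_signature
#' @param signatures List of [call_signature()] objects.
#' @return Tibble of detections: `site_id`, `date`, `hour`, `species`,
#'   `score` (only detected recordings are returned).
#' @export
detect_calls <- function(grid, signatures = default_signatures(),
                         margin_db = 10) {
  stopifnot(margin_db > 0)
  .check_grid(grid)
  mm <- .grid_max_matrix(grid)
  purrr::map_dfr(signatures, function(sig) {
    res <- .match_on_matrix(mm, sig, margin_db)
    mm$slots %>%
      mutate(species = sig$species, score = res$score) %>%
      filter(res$detected)
  }) %>%
    arrange(.data$date, .data$hour, .data$species)
}

#' First amphibian call of the season
#'
#' Earliest detection of any species in any recording on or after the
#' deployment date, excluding days on which the station air temperature
#' never exceeded 0 degC (such days cannot host calling and any apparent
#' detection on them is ignored). The result is reported both as an exact
#' date and at eight-day-interval resolution; a detection on the deployment
#' date itself is flagged as "calling already underway", since the true
#' first call may predate monitoring.
#'
#' @inheritParams detect_calls
#' @param weather Daily weather tibble with `doy` and the exclusion
#'   temperature column.
#' @param deploy_date Date the recorder was deployed.
#' @param temp_exclusion_var Column of `weather` tested against 0 degC
#'   (default `"tmax"`).
#' @return One-row tibble: `first_call_date`, `first_call_doy`,
#'   `eight_day_interval`, `underway`, `species`, `found`. When no valid
#'   detection exists the row has `found = FALSE` and `NA` fields (an
#'   explicit no-call result, not an error).
#' @export
detect_first_call <- function(grid, signatures = default_signatures(),
                              weather = NULL, deploy_date = NULL,
                              margin_db = 10, temp_exclusion_var = "tmax") {
  det <- detect_calls(grid, signatures, margin_db)
  if (is.null(deploy_date)) {
    deploy_date <- min(grid$date)
  }
  deploy_date <- as.Date(deploy_date)
  det <- det %>% filter(.data$date >= deploy_date)
  if (!is.null(weather)) {
    stopifnot(temp_exclusion_var %in% names(weather))
    warm_doys <- weather$doy[weather[[temp_exclusion_var]] > 0]
    det <- det %>% filter(doy_of_date(.data$date) %in% warm_doys)
  }
  if (nrow(det) == 0) {
    return(tibble(
      first_call_date = as.Date(NA), first_call_doy = NA_integer_,
      eight_day_interval = NA_integer_, underway = NA,
      species = NA_character_, found = FALSE
    ))
  }
  first <- det %>% slice(1)
  doy <- doy_of_date(first$date)
  tibble(
    first_call_date = first$date,
    first_call_doy = doy,
    eight_day_interval = eight_day_interval_of(doy),
    underway = first$date == deploy_date,
    species = first$species,
    found = TRUE
  )
}

#' Seasonal presence/absence of a species
#'
#' A species is present in a site-year when at least one recording matches
#' its signature within the survey window (deployment through
#' `season_end_date`, default June 7, when calling is typically complete).
#' When no detection falls in the window but candidate detections occur
#' later in June, the scan extends through June 30 and those detections
#' count (the extension rule for unusually late calling).
#'
#' @inheritParams detect_first_call
#' @param signature A single [call_signature()].
#' @param season_end_date End of the standard survey window (Date; default
#'   June 7 of the grid's year).
#' @return One-row tibble: `species`, `present`, `n_detected_recordings`,
#'   `extended` (whether the June extension produced the presence call).
#' @export
detect_presence <- function(grid, signature, weather = NULL,
                            season_end_date = NULL, margin_db = 10,
                            temp_exclusion_var = "tmax") {
  if (nrow(grid) == 0) {
    warn("detect_presence(): empty grid; reporting absent")
    return(tibble(species = signature$species, present = FALSE,
                  n_detected_recordings = 0L, extended = FALSE))
  }
  year <- as.integer(format(min(grid$date), "%Y"))
  if (is.null(season_end_date)) {
    season_end_date <- as.Date(sprintf("%d-06-07", year))
  }
  season_end_date <- as.Date(season_end_date)
  extension_end <- as.Date(sprintf("%d-06-30", year))
  det <- detect_calls(grid, list(signature), margin_db)
  if (!is.null(weather)) {
    warm_doys <- weather$doy[weather[[temp_exclusion_var]] > 0]
    det <- det %>% filter(doy_of_date(.data$date) %in% warm_doys)
  }
  in_window <- det %>% filter(.data$date <= season_end_date)
  if (nrow(in_window) > 0) {
    return(tibble(species = signature$species, present = TRUE,
                  n_detected_recordings = nrow(in_window), extended = FALSE))
  }
  late <- det %>%
    filter(.data$date > season_end_date, .data$date <= extension_end)
  tibble(
    species = signature$species,
    present = nrow(late) > 0,
    n_detected_recordings = nrow(late),
    extended = nrow(late) > 0
  )
}

#' Phenophase and calling-peak summary
#'
#' Combines a calling-activity series with the species' detections into the
#' seasonal summary: first and last call dates, the top three peak-activity
#' dates among unmasked valid days (ties broken by the earlier date), the
#' median of those three dates, and the phenophase length in days
#' (`last - first + 1`).
#'
#' @param activity A [calling_activity()] tibble.
#' @param detections Detections for the species (from [detect_calls()]),
#'   with a `date` column.
#' @return One-row tibble: `species`, `first_call_date`, `last_call_date`,
#'   `phenophase_days`, `peak_dates` (list column of 3 dates),
#'   `median_peak_date`, `peak_defined`.
#' @export
summarize_phenophase <- function(activity, detections) {
  stopifnot(all(c("date", "integrand", "masked") %in% names(activity)))
  species <- if ("species" %in% names(detections) && nrow(detections) > 0) {
    detections$species[1]
  } else {
    NA_character_
  }
  if (nrow(detections) == 0) {
    return(tibble(
      species = species, first_call_date = as.Date(NA),
      last_call_date = as.Date(NA), phenophase_days = NA_integer_,
      peak_dates = list(as.Date(character())),
      median_peak_date = as.Date(NA), peak_defined = FALSE
    ))
  }
  first_call <- min(detections$date)
  last_call <- max(detections$date)
  qualifying <- activity %>%
    filter(.data$valid, !.data$masked, .data$integrand > 0,
           .data$date >= first_call, .data$date <= last_call) %>%
    arrange(dplyr::desc(.data$integrand), .data$date)
  peak_defined <- nrow(qualifying) >= 3
  if (peak_defined) {
    top3 <- sort(qualifying$date[1:3])
    median_peak <- top3[2]
  } else {
    warn("summarize_phenophase(): fewer than 3 qualifying dates; peak undefined")
    top3 <- as.Date(character())
    median_peak <- as.Date(NA)
  }
  tibble(
    species = species,
    first_call_date = first_call,
    last_call_date = last_call,
    phenophase_days = as.integer(last_call - first_call) + 1L,
    peak_dates = list(top3),
    median_peak_date = median_peak,
    peak_defined = peak_defined
  )
}

#' Median annual occupancy proportion per study area
#'
#' Per-year occupancy is `detected / monitored` sites; the area summary is
#' the median of those annual proportions across years (mean of the middle
#' two for an even year count). Years with no monitored sites are excluded
#' with a warning.
#'
#' @param counts Tibble with `area`, `year`, `detected`, `monitored`.
#' @return Tibble with `area`, `n_years`, `median_proportion`.
#' @export
summarize_occupancy <- function(counts) {
  stopifnot(all(c("area", "year", "detected", "monitored") %in% names(counts)))
  if (any(counts$detected > counts$monitored)) {
    abort("summarize_occupancy(): detected exceeds monitored")
  }
  if (any(counts$detected < 0)) {
    abort("summarize_occupancy(): negative detected count")
  }
  bad <- counts %>% filter(.data$monitored == 0)
  if (nrow(bad) > 0) {
    warn(sprintf("summarize_occupancy(): %d year(s) with 0 monitored sites excluded",
                 nrow(bad)))
    counts <- counts %>% filter(.data$monitored > 0)
  }
  counts %>%
    mutate(proportion = .data$detected / .data$monitored) %>%
    group_by(.data$area) %>%
    summarise(
      n_years = dplyr::n(),
      median_proportion = median(.data$proportion),
      .groups = "drop"
    )
}
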