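# Orchestration: bundle simulation, per-site-year event extraction, area
# summaries, and stream writers/readers.

#' Simulate the full multi-sensor bundle for one site-year
#'
#' Runs the five generators in order (weather, snow, depth, acoustics,
#' landscape) under sub-seeds derived from the master seed, so the bundle is
#' byte-identical for a fixed configuration.
#'
#' @param config A [sim_config()].
#' @param year Calendar year.
#' @param unit_id Site/block identifier (each unit is one wetland with its
#'   co-located 4-km2 landscape block).
#' @param signatures Signature list to plant (default [default_signatures()]).
#' @return A `wetscape_bundle` list: `unit_id`, `year`, `weather`, `snow`,
#'   `depth`, `acoustics`, `landscape`, `truth` (aggregated ground truth).
#' @export
simulate_site_year <- function(config, year, unit_id = "S1",
                               signatures = default_signatures()) {
  weather <- simulate_weather(config, year, unit_id)
  snow <- simulate_snow_composites(weather, config, unit_id)
  depth <- simulate_depth(weather, config, unit_id)
  melt_doys <- snow$truth$melt_doy
  melt_doy <- if (all(is.na(melt_doys))) NA_integer_ else
    as.integer(floor(mean(melt_doys, na.rm = TRUE) + 0.5))
  acoustics <- simulate_acoustics(weather, depth, signatures, config,
                                  melt_doy, unit_id)
  landscape <- simulate_landscape(weather, snow, config, unit_id)
  bundle <- list(
    unit_id = unit_id, year = as.integer(year),
    weather = weather, snow = snow, depth = depth,
    acoustics = acoustics, landscape = landscape,
    truth = list(
      melt_doy = melt_doy,
      cell_melt = snow$truth,
      calls = acoustics$truth,
      crucifer_peak_doys = acoustics$peaks,
      green_up_week = landscape$truth$green_up_week,
      depth_coupling_alpha = depth$truth$depth_coupling_alpha
    )
  )
  class(bundle) <- "wetscape_bundle"
  bundle
}

#' Extract the cyclo-seasonal event timing record for one site-year
#'
#' Runs every analysis stage against one bundle and assembles the event
#' table row: first non-negative eight-day temperature interval, snow-free
#' interval (field cutoff, Feb 15), first-call interval (with
#' already-underway flag), first 10 degC week, block snow-off week (remote
#' cutoff, end of February), green-up week, and ET onset week. A missing
#' stream leaves its events `NA` (explicit not-found) and is noted in the
#' manifest; other stages still run.
#'
#' @param bundle A `wetscape_bundle` (or a compatible list of streams).
#' @param signatures Signatures used for call detection.
#' @param margin_db Detection margin, dB.
#' @return List with `record` (one-row tibble of events) and `manifest`
#'   (tibble of stage statuses).
#' @export
run_site_year <- function(bundle, signatures = default_signatures(),
                          margin_db = 10) {
  unit_id <- bundle$unit_id
  year <- bundle$year
  manifest <- list()
  note <- function(stage, status) {
    manifest[[stage]] <<- tibble(stage = stage, status = status)
  }

  temp0 <- NA_integer_
  temp10 <- NA_integer_
  if (!is.null(bundle$weather)) {
    temp0 <- first_nonnegative_interval(bundle$weather)
    temp10 <- first_week_at_threshold(bundle$weather, 10)
    note("weather", "ok")
  } else {
    note("weather", "missing")
  }

  snowfree_interval <- NA_integer_
  snowoff_week <- NA_integer_
  if (!is.null(bundle$snow)) {
    onsets <- bundle$snow$flags %>%
      group_by(.data$cell) %>%
      dplyr::group_split() %>%
      purrr::map_int(function(f) snow_free_onset_cell(f, cutoff_doy = 46L))
    field_off <- suppressWarnings(block_snow_off(onsets))
    snowfree_interval <- if (is.na(field_off$mean_onset_doy)) NA_integer_
      else eight_day_interval_of(field_off$mean_onset_doy)
    onsets_remote <- bundle$snow$flags %>%
      group_by(.data$cell) %>%
      dplyr::group_split() %>%
      purrr::map_int(function(f) snow_free_onset_cell(f, cutoff_doy = 59L))
    snowoff_week <- suppressWarnings(block_snow_off(onsets_remote))$week
    note("snow", "ok")
  } else {
    note("snow", "missing")
  }

  first_call_interval <- NA_integer_
  first_call_underway <- NA
  if (!is.null(bundle$acoustics)) {
    fc <- detect_first_call(
      bundle$acoustics$grid, signatures, bundle$weather,
      deploy_date = min(bundle$acoustics$grid$date), margin_db = margin_db
    )
    first_call_interval <- fc$eight_day_interval
    first_call_underway <- fc$underway
    note("acoustics", "ok")
  } else {
    note("acoustics", "missing")
  }

  greenup_week <- NA_integer_
  etonset_week <- NA_integer_
  if (!is.null(bundle$landscape)) {
    smoothed <- smooth_ndvi(bundle$landscape$ndvi$ndvi)
    greenup_week <- green_up_week(smoothed)
    et_weekly <- align_composites_to_weeks(bundle$landscape$et, "et_mm")
    etonset_week <- et_onset_week(et_weekly$et_mm)
    note("landscape", "ok")
  } else {
    note("landscape", "missing")
  }

  list(
    record = tibble(
      unit_id = unit_id, year = year,
      temp0_interval = temp0,
      snowfree_interval = snowfree_interval,
      first_call_interval = first_call_interval,
      first_call_underway = first_call_underway,
      temp10_week = temp10,
      snowoff_week = snowoff_week,
      greenup_week = greenup_week,
      et_onset_week = etonset_week
    ),
    manifest = bind_rows(manifest)
  )
}

#' Five-number distribution summary of event timings per area
#'
#' Summarises each event column of an event-timing table as minimum,
#' quartiles, median and maximum per area (and year when present), using
#' linear interpolation between order statistics (quantile type 7). Missing
#' (not-found) events are excluded and counted.
#'
#' @param records Event tibble from [run_site_year()] rows, with an `area`
#'   column added by the caller.
#' @param events Event columns to summarise (default: all interval/week
#'   columns present).
#' @return Tibble with `area`, `event`, `n`, `n_missing`, `min`, `q25`,
#'   `median`, `q75`, `max`.
#' @export
assemble_area_summary <- function(records, events = NULL) {
  stopifnot("area" %in% names(records), nrow(records) >= 1)
  if (is.null(events)) {
    events <- intersect(
      c("temp0_interval", "snowfree_interval", "first_call_interval",
        "temp10_week", "snowoff_week", "greenup_week", "et_onset_week"),
      names(records)
    )
  }
  records %>%
    tidyr::pivot_longer(dplyr::all_of(events), names_to = "event",
                        values_to = "value") %>%
    group_by(.data$area, .data$event) %>%
    summarise(
      n = sum(!is.na(.data$value)),
      n_missing = sum(is.na(.data$value)),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE,
                     type = 7),
      median = median(.data$value, na.rm = TRUE),
      q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE,
                     type = 7),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    mutate(across(c("min", "max"), ~ ifelse(is.infinite(.x), NA, .x)))
}

#' Write a simulated bundle as delimited text streams
#'
#' One comma-separated file per stream plus a YAML ground-truth sidecar,
#' with ISO-8601 dates. Returns a manifest with an MD5 content digest per
#' file, so an unchanged re-run can be recognised as a no-op.
#'
#' @param bundle A `wetscape_bundle`.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest: `file`, `md5`.
#' @export
write_site_year <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%d", bundle$unit_id, bundle$year)
  path <- function(stream) file.path(dir, sprintf("%s_%s.csv", stem, stream))
  utils::write.csv(bundle$weather, path("weather"), row.names = FALSE)
  utils::write.csv(bundle$snow$flags, path("snow"), row.names = FALSE)
  utils::write.csv(bundle$depth$hourly, path("depth"), row.names = FALSE)
  utils::write.csv(bundle$acoustics$grid, path("acoustics"),
                   row.names = FALSE)
  utils::write.csv(bundle$landscape$ndvi, path("ndvi"), row.names = FALSE)
  utils::write.csv(bundle$landscape$et, path("et"), row.names = FALSE)
  truth_path <- file.path(dir, sprintf("%s_truth.yaml", stem))
  truth <- bundle$truth
  truth$cell_melt <- as.list(setNames(truth$cell_melt$melt_doy,
                                      paste0("cell_", truth$cell_melt$cell)))
  truth$calls <- purrr::transpose(as.list(truth$calls))
  yaml::write_yaml(truth, truth_path)
  files <- c(vapply(c("weather", "snow", "depth", "acoustics", "ndvi", "et"),
                    path, character(1)), truth_path)
  tibble(file = basename(files),
         md5 = unname(tools::md5sum(files)))
}

#' Serialize a simulation/run configuration for provenance
#'
#' Writes every tunable (thresholds, seeds, windows) of a [sim_config()] to
#' a YAML run log so a result can always be traced to the exact settings
#' that produced it.
#'
#' @param config A [sim_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read back site-year streams written by [write_site_year()]
#'
#' @param dir Directory containing the stream files.
#' @param unit_id,year Bundle identity.
#' @return List with `weather`, `snow_flags`, `depth_hourly`, `grid`,
#'   `ndvi`, `et`, `truth`.
#' @export
read_site_year <- function(dir, unit_id, year) {
  stem <- sprintf("%s_%d", unit_id, year)
  path <- function(stream) file.path(dir, sprintf("%s_%s.csv", stem, stream))
  rd <- function(p) as_tibble(utils::read.csv(p))
  out <- list(
    weather = rd(path("weather")),
    snow_flags = rd(path("snow")),
    depth_hourly = rd(path("depth")),
    grid = rd(path("acoustics")),
    ndvi = rd(path("ndvi")),
    et = rd(path("et")),
    truth = yaml::read_yaml(file.path(dir, sprintf("%s_truth.yaml", stem)))
  )
  out$weather$date <- as.Date(out$weather$date)
  out$depth_hourly$date <- as.Date(out$depth_hourly$date)
  out$grid$date <- as.Date(out$grid$date)
  out
}
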