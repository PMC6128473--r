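# Synthetic 8-day snow composites: per-cell thaw-threshold melt with planted
# melt-date truth.

# Maximum-extent compositing: an interval is snow if any of its days is.
.composite_snow_flags <- function(snow_day, intervals) {
  purrr::map2_lgl(
    intervals$start_doy, intervals$end_doy,
    function(s, e) any(snow_day[s:e])
  )
}

#' Simulate per-cell eight-day snow composites for one block
#'
#' Each of the block's cells starts the year snow-covered and melts
#' permanently on the first day its accumulated thaw (sum of positive mean
#' daily temperatures) exceeds a cell-specific threshold, jittered around
#' `melt_threshold` so that the block-mean onset is nondegenerate. A
#' composite interval is flagged `snow` when snow is present on at least one
#' of its days -- the maximum-extent convention of eight-day snow products.
#'
#' @param weather Daily weather tibble from [simulate_weather()].
#' @param config A [sim_config()].
#' @param block_id Block identifier (also seeds the cell jitter).
#' @return List: `flags` (tibble `block_id`, `cell`, `interval`,
#'   `start_doy`, `snow`), `truth` (tibble `block_id`, `cell`, `melt_doy`;
#'   `NA` for cells that never melt).
#' @export
simulate_snow_composites <- function(weather, config, block_id = "B1") {
  stopifnot(inherits(config, "wetscape_sim_config"))
  stopifnot(all(c("doy", "tmean", "year") %in% names(weather)))
  year <- weather$year[1]
  n_days <- nrow(weather)
  thaw <- cumsum(pmax(weather$tmean, 0))
  with_stream_seed(config, "snow", year, block_id, {
    thresholds <- pmax(
      rnorm(config$block_cells, mean = config$melt_threshold,
            sd = config$melt_jitter_sd),
      1
    )
    intervals <- eight_day_intervals(n_days)
    per_cell <- purrr::map(seq_len(config$block_cells), function(cell) {
      snow_day <- thaw <= thresholds[cell]
      melt <- which(!snow_day)
      melt_doy <- if (length(melt) == 0) NA_integer_ else
        as.integer(melt[1])
      flags <- intervals %>%
        mutate(
          block_id = block_id, cell = as.integer(cell),
          snow = .composite_snow_flags(snow_day, intervals)
        )
      list(flags = flags, melt_doy = melt_doy)
    })
    list(
      flags = purrr::map_dfr(per_cell, "flags") %>%
        select("block_id", "cell", "interval", "start_doy", "snow"),
      truth = tibble(
        block_id = block_id,
        cell = seq_len(config$block_cells),
        melt_doy = purrr::map_int(per_cell, "melt_doy")
      )
    )
  })
}
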