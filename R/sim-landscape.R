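# Synthetic landscape composites: weekly NDVI with logistic green-up and
# 8-day ET totals driven by growing degree units and moisture.

#' Simulate weekly NDVI and eight-day ET for one block-year
#'
#' NDVI sits at the winter background level and rises logistically to a
#' summer plateau, with the logistic midpoint `ndvi_lag_weeks` after the
#' block's snow-off week; weekly observations add Gaussian noise (clipped to
#' `[-1, 1]`). The planted green-up truth is the first post-February week
#' (week start on/after day 60) in which the *noise-free* logistic exceeds
#' 0.60. Daily ET is `et_coeff * GDU * moisture`, where moisture ramps with
#' 30-day antecedent precipitation, summed into eight-day composite totals
#' -- zero whenever GDU is zero, so winter composites are zero.
#'
#' @param weather Daily weather tibble from [simulate_weather()].
#' @param snow Result of [simulate_snow_composites()] for the block.
#' @param config A [sim_config()] (`ndvi_plateau` must exceed 0.60).
#' @param block_id Block identifier.
#' @return List: `ndvi` (tibble `block_id`, `year`, `week`, `ndvi`), `et`
#'   (tibble `block_id`, `year`, `interval`, `start_doy`, `et_mm`), `truth`
#'   (list: `green_up_week`, `melt_week`, `ndvi_clean` vector).
#' @export
simulate_landscape <- function(weather, snow, config, block_id = "B1") {
  stopifnot(inherits(config, "wetscape_sim_config"))
  if (config$ndvi_plateau <= 0.60) {
    abort("simulate_landscape(): ndvi_plateau must exceed 0.60")
  }
  year <- weather$year[1]
  melt_doys <- snow$truth$melt_doy
  if (all(is.na(melt_doys))) {
    abort("simulate_landscape(): no melt truth available for block")
  }
  melt_week <- week_of(as.integer(floor(mean(melt_doys, na.rm = TRUE) + 0.5)))
  weeks <- 1:52
  mid <- melt_week + config$ndvi_lag_weeks
  clean <- config$ndvi_background +
    (config$ndvi_plateau - config$ndvi_background) *
      plogis(config$ndvi_rate * (weeks - mid))
  green_truth <- green_up_week(clean, threshold = 0.60)

  gdu <- daily_gdu(weather$tmin, weather$tmax)
  precip30 <- as.numeric(stats::filter(weather$precip_mm, rep(1, 30),
                                       sides = 1))
  precip30[is.na(precip30)] <- cumsum(weather$precip_mm)[is.na(precip30)]
  moisture <- 0.4 + 0.6 * pmin(precip30 / 60, 1)
  et_daily <- config$et_coeff * gdu * moisture
  intervals <- eight_day_intervals(nrow(weather))
  et <- intervals %>%
    mutate(
      block_id = block_id, year = as.integer(year),
      et_mm = purrr::map2_dbl(.data$start_doy, .data$end_doy,
                              function(s, e) sum(et_daily[s:e]))
    ) %>%
    select("block_id", "year", "interval", "start_doy", "et_mm")

  with_stream_seed(config, "landscape", year, block_id, {
    noise <- if (config$ndvi_noise_sd > 0) {
      rnorm(length(weeks), sd = config$ndvi_noise_sd)
    } else {
      rep(0, length(weeks))
    }
    ndvi <- tibble(
      block_id = block_id, year = as.integer(year), week = weeks,
      ndvi = pmin(pmax(clean + noise, -1), 1)
    )
    list(
      ndvi = ndvi, et = et,
      truth = list(green_up_week = green_truth, melt_week = melt_week,
                   ndvi_clean = clean)
    )
  })
}
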