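# Synthetic daily station weather: sinusoidal annual temperature cycle with
# AR(1) noise, Bernoulli-gamma precipitation.

#' Simulate one year of daily station weather
#'
#' Mean daily temperature is a cosine of the day of year (peak at
#' `latitude_phase`) plus stationary AR(1) noise with marginal SD
#' `temp_noise_sd`; `tmax`/`tmin` sit a fixed half-range above/below, so
#' `tmin <= tmean <= tmax` always holds. Daily precipitation is a Bernoulli
#' wet-day draw times a gamma amount.
#'
#' @param config A [sim_config()].
#' @param year Calendar year (within the configured span).
#' @param unit Unit identifier used to decorrelate stations (string or
#'   integer; default 0 -- one shared station).
#' @return Tibble with 365 rows: `year`, `doy`, `date`, `tmin`, `tmean`,
#'   `tmax`, `precip_mm`.
#' @export
simulate_weather <- function(config, year, unit = 0L) {
  stopifnot(inherits(config, "wetscape_sim_config"))
  if (!is.numeric(year) || length(year) != 1 || year != round(year) ||
      year < config$start_year ||
      year > config$start_year + config$n_years - 1) {
    abort(sprintf(
      "simulate_weather(): year must be a single integer in %d..%d",
      config$start_year, config$start_year + config$n_years - 1
    ))
  }
  n <- 365L
  doy <- seq_len(n)
  with_stream_seed(config, "weather", year, unit, {
    seasonal <- config$temp_annual_mean +
      config$temp_mean_amplitude *
        cos(2 * pi * (doy - config$latitude_phase) / 365)
    noise <- if (config$temp_noise_sd > 0) {
      innov <- rnorm(n, sd = config$temp_noise_sd *
                       sqrt(1 - config$temp_ar1^2))
      as.numeric(stats::filter(innov, config$temp_ar1,
                               method = "recursive"))
    } else {
      rep(0, n)
    }
    tmean <- seasonal + noise
    wet <- rbinom(n, 1L, config$precip_occurrence_prob)
    amount <- rgamma(n, shape = config$precip_gamma_shape,
                     scale = config$precip_gamma_scale)
    tibble(
      year = as.integer(year),
      doy = doy,
      date = as.Date(sprintf("%d-01-01", year)) + doy - 1L,
      tmin = tmean - config$diurnal_half_range,
      tmean = tmean,
      tmax = tmean + config$diurnal_half_range,
      precip_mm = wet * amount
    )
  })
}
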