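# Simulation configuration and seeded sub-stream management for the
# synthetic multi-sensor generator.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic generator with defaults chosen to
#' emulate a seasonally snow-covered north-central US study area: a sinusoidal
#' annual temperature cycle peaking in late July with AR(1) day-to-day noise,
#' Bernoulli-gamma daily precipitation, bucket-balance wetland depth coupled
#' to rainfall, planted anuran calling seasons, and logistic NDVI green-up
#' with degree-day-driven evapotranspiration.
#'
#' @param seed Integer master seed; every stream draws from a sub-seed
#'   derived from it, so a fixed seed yields byte-identical outputs.
#' @param n_years Number of simulated years.
#' @param start_year First calendar year.
#' @param latitude_phase Day-of-year of the temperature peak.
#' @param temp_annual_mean Annual mean temperature, degC.
#' @param temp_mean_amplitude Sinusoid amplitude, degC (>= 0).
#' @param temp_noise_sd Marginal SD of the AR(1) temperature noise, degC.
#' @param temp_ar1 AR(1) coefficient of the temperature noise.
#' @param diurnal_half_range Half the tmax - tmin spread, degC.
#' @param precip_occurrence_prob Probability of a wet day.
#' @param precip_gamma_shape,precip_gamma_scale Gamma parameters of wet-day
#'   amounts, mm.
#' @param depth_start_m Initial wetland depth, m.
#' @param depth_coupling_alpha Depth gain per mm of rain, m/mm (>= 0).
#' @param depth_drawdown Daily depth loss, m/day.
#' @param depth_noise_sd Daily sensor/process noise on depth, m.
#' @param call_snr_db Planted call level above the -88 dB floor (> 0).
#' @param call_peak_boost_db Extra level on the three planted peak days.
#' @param call_day_jitter_db SD of day-to-day calling-intensity jitter.
#' @param acoustic_noise_sd SD of the half-normal background noise, dB.
#' @param rain_mask_prob Daily probability of a broadband masking event
#'   (wind/rain); default 0 (masking is exercised explicitly in tests).
#' @param species_absence_prob Per species-site-year probability that the
#'   species is absent (no calls planted).
#' @param acoustic_start_doy,acoustic_end_doy Recorder deployment span.
#' @param melt_threshold Accumulated thaw degree-days (base 0 degC) at which
#'   a snow cell melts.
#' @param melt_jitter_sd Per-cell SD of the melt threshold.
#' @param block_cells Snow cells per 4-km2 block (default 16).
#' @param ndvi_background Winter background NDVI.
#' @param ndvi_plateau Summer NDVI plateau (must exceed 0.60 or the green-up
#'   truth is undefined).
#' @param ndvi_rate Logistic rise rate per week.
#' @param ndvi_lag_weeks Weeks from block snow-off to the logistic midpoint.
#' @param ndvi_noise_sd SD of weekly NDVI noise.
#' @param et_coeff ET per growing degree unit, mm/GDU.
#' @param species_set Character vector naming which default signatures to
#'   simulate.
#' @return A `wetscape_sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_years = 5L,
                       start_year = 2008L,
                       latitude_phase = 200,
                       temp_annual_mean = 6,
                       temp_mean_amplitude = 18,
                       temp_noise_sd = 3,
                       temp_ar1 = 0.6,
                       diurnal_half_range = 4,
                       precip_occurrence_prob = 0.3,
                       precip_gamma_shape = 0.7,
                       precip_gamma_scale = 10,
                       depth_start_m = 0.5,
                       depth_coupling_alpha = 0.002,
                       depth_drawdown = 0.008,
                       depth_noise_sd = 0.003,
                       call_snr_db = 30,
                       call_peak_boost_db = 8,
                       call_day_jitter_db = 0.8,
                       acoustic_noise_sd = 1,
                       rain_mask_prob = 0,
                       species_absence_prob = 0.1,
                       acoustic_start_doy = 60L,
                       acoustic_end_doy = 175L,
                       melt_threshold = 30,
                       melt_jitter_sd = 6,
                       block_cells = 16L,
                       ndvi_background = 0.45,
                       ndvi_plateau = 0.85,
                       ndvi_rate = 0.35,
                       ndvi_lag_weeks = 4,
                       ndvi_noise_sd = 0.02,
                       et_coeff = 0.2,
                       species_set = names(default_signatures())) {
  cfg <- as.list(environment())
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    cfg$n_years >= 1,
    cfg$temp_mean_amplitude >= 0,
    cfg$temp_noise_sd >= 0,
    cfg$precip_occurrence_prob >= 0, cfg$precip_occurrence_prob <= 1,
    cfg$rain_mask_prob >= 0, cfg$rain_mask_prob <= 1,
    cfg$species_absence_prob >= 0, cfg$species_absence_prob <= 1,
    cfg$depth_coupling_alpha >= 0,
    cfg$block_cells >= 1
  )
  if (cfg$call_snr_db <= 0) {
    abort("sim_config(): call_snr_db must be > 0")
  }
  if (cfg$ndvi_plateau <= 0.60) {
    abort("sim_config(): ndvi_plateau must exceed 0.60 (green-up truth undefined)")
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "wetscape_sim_config"
  cfg
}

# Fixed per-stream offsets; sub-stream seeds are a deterministic function of
# (master seed, stream, year, unit), kept inside 32-bit integer range.
.STREAM_OFFSETS <- c(
  weather = 1L, snow = 2L, depth = 3L, acoustics = 4L, landscape = 5L,
  study = 6L
)

stream_seed <- function(config, stream, year = 0L, unit = 0L) {
  off <- .STREAM_OFFSETS[[stream]]
  if (is.character(unit)) {
    cp <- utf8ToInt(unit)
    unit <- sum(cp * seq_along(cp)) %% 100000
  }
  s <- (as.double(config$seed) * 2654435.0 + off * 97003.0 +
          as.double(year) * 131.0 + as.double(unit) * 7907.0)
  as.integer(s %% 2147483647)
}

# Run code under a stream-specific seed, restoring the caller's RNG state.
with_stream_seed <- function(config, stream, year, unit, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(config, stream, year, unit))
  force(code)
}
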