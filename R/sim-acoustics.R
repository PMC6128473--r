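# Synthetic spectral-summary grids with planted calling truth.

#' Simulate a site-year spectral-summary grid
#'
#' Builds the full recorder grid (24 five-minute recordings per day, 110
#' 100-Hz bins, dB in `[-88, 0]`) over the deployment span with half-normal
#' background noise above the -88 dB floor, then plants species calls:
#' calling windows open on the first day after block snowmelt on which the
#' mean temperature is at or above 0 degC *and* the first non-negative
#' eight-day temperature integrand has occurred (sustained, not one-day,
#' warmth), each species with its own lag and duration; calls are planted
#' only on window days with `tmean >= 0`. Every planted call raises each
#' signature peak bin to `floor + intensity + rel_db` with a -5 dB rolloff
#' on the two adjacent bins (the spectral width that makes the primary-band
#' median respond). Spring-peeper intensity follows a triangular seasonal
#' profile; the three planted peak days are boosted by `call_peak_boost_db`.
#' Optional broadband masking events (off by default) overwrite whole
#' recordings with loud flat noise.
#'
#' @param weather Daily weather tibble from [simulate_weather()].
#' @param depth Result of [simulate_depth()] (its daily series gates
#'   planting: a species is dropped if the site is dry at its window start).
#' @param signatures Named list of [call_signature()]s to plant.
#' @param config A [sim_config()] (`call_snr_db` must be > 0).
#' @param melt_doy Block-level snowmelt day-of-year (mean over cells).
#' @param site_id Site identifier.
#' @return List: `grid` (spectral-summary tibble), `truth` (tibble
#'   `species`, `present`, `first_call_doy`, `last_call_doy`,
#'   `n_calling_days`) and `peaks` (integer vector of the three planted
#'   spring-peeper peak days, sorted; `NULL` when that species is absent).
#' @export
simulate_acoustics <- function(weather, depth, signatures, config,
                               melt_doy, site_id = "S1") {
  stopifnot(inherits(config, "wetscape_sim_config"))
  if (config$call_snr_db <= 0) {
    abort("simulate_acoustics(): call_snr_db must be > 0")
  }
  year <- weather$year[1]
  days <- config$acoustic_start_doy:config$acoustic_end_doy
  n_days <- length(days)
  n_slots <- n_days * 24L
  bin_starts <- seq(0L, (.N_BINS - 1L) * .BIN_HZ, by = .BIN_HZ)

  temp0 <- first_nonnegative_interval(weather)
  elig_floor <- max(
    if (is.na(melt_doy)) Inf else melt_doy,
    if (is.na(temp0)) Inf else eight_day_start(temp0)
  )
  warm <- weather$doy[weather$tmean >= 0]
  eligible_days <- warm[warm >= elig_floor & warm >= min(days)]

  with_stream_seed(config, "acoustics", year, site_id, {
    # background noise
    mean_db <- DB_FLOOR + abs(rnorm(n_slots * .N_BINS,
                                    sd = config$acoustic_noise_sd))
    max_db <- mean_db + 1 + abs(rnorm(n_slots * .N_BINS, sd = 0.5))

    species_lag <- c(
      pseudacris_crucifer = 0L, pseudacris_maculata = 1L,
      lithobates_sylvaticus = 0L, hyla_versicolor = 35L
    )
    species_duration <- c(
      pseudacris_crucifer = 45L, pseudacris_maculata = 30L,
      lithobates_sylvaticus = 15L, hyla_versicolor = 30L
    )

    flat_index <- function(doy, hour, bin_col) {
      day_i <- match(doy, days)
      ((day_i - 1L) * 24L + hour) * .N_BINS + bin_col
    }
    plant_level <- function(idx, level) {
      level <- pmin(level, 0)
      mean_db[idx] <<- pmax(mean_db[idx], level - 2)
      max_db[idx] <<- pmax(max_db[idx], level)
    }

    truth <- list()
    peaks_truth <- NULL
    for (sp in config$species_set) {
      sig <- signatures[[sp]]
      if (is.null(sig)) {
        abort(sprintf("simulate_acoustics(): no signature for '%s'", sp))
      }
      absent <- runif(1) < config$species_absence_prob
      lag <- species_lag[[sp]] %||% 0L
      duration <- species_duration[[sp]] %||% 30L
      jitter <- sample(0:2, 1)
      cand <- eligible_days[eligible_days >= elig_floor + lag + jitter]
      cand <- cand[cand <= max(days) - 2L]
      if (!absent && length(cand) > 0) {
        first_doy <- cand[1]
        window <- cand[cand <= first_doy + duration]
        dry_at_start <- depth$daily$depth_m[match(first_doy,
                                                  depth$daily$doy)] <= 0
        if (isTRUE(dry_at_start)) {
          absent <- TRUE
        }
      } else {
        absent <- TRUE
      }
      if (absent || length(cand) == 0) {
        truth[[sp]] <- tibble(
          species = sp, present = FALSE, first_call_doy = NA_integer_,
          last_call_doy = NA_integer_, n_calling_days = 0L
        )
        next
      }
      n_w <- length(window)
      # triangular seasonal intensity: call_snr_db at mid-window, -6 dB edges
      tri <- if (n_w > 1) {
        -6 * abs(2 * (seq_len(n_w) - 1) / (n_w - 1) - 1)
      } else {
        0
      }
      intensity <- config$call_snr_db + tri +
        rnorm(n_w, sd = config$call_day_jitter_db)
      if (sp == "pseudacris_crucifer" && n_w >= 5) {
        mid <- window[window > window[1] + n_w %/% 4 &
                        window < window[n_w] - n_w %/% 4]
        if (length(mid) >= 3) {
          pk <- sort(sample(mid, 3))
          intensity[match(pk, window)] <-
            config$call_snr_db + config$call_peak_boost_db
          peaks_truth <- pk
        }
      }
      for (h in sig$typical_hours) {
        for (j in seq_len(nrow(sig$peaks))) {
          bin_col <- sig$peaks$freq_hz[j] %/% .BIN_HZ + 1L
          lv <- DB_FLOOR + intensity + sig$peaks$rel_db[j]
          plant_level(flat_index(window, h, bin_col), lv)
          if (bin_col > 1L) {
            plant_level(flat_index(window, h, bin_col - 1L), lv - 5)
          }
          if (bin_col < .N_BINS) {
            plant_level(flat_index(window, h, bin_col + 1L), lv - 5)
          }
        }
      }
      truth[[sp]] <- tibble(
        species = sp, present = TRUE,
        first_call_doy = as.integer(window[1]),
        last_call_doy = as.integer(window[n_w]),
        n_calling_days = n_w
      )
    }

    # broadband masking events (wind/rain): whole days of loud flat noise
    if (config$rain_mask_prob > 0) {
      masked_days <- days[runif(n_days) < config$rain_mask_prob]
      for (d in masked_days) {
        for (h in 0:23) {
          idx <- flat_index(rep(d, .N_BINS), h, seq_len(.N_BINS))
          lvl <- -30 + rnorm(.N_BINS, sd = 0.3)
          mean_db[idx] <- pmax(mean_db[idx], lvl)
          max_db[idx] <- pmax(max_db[idx], lvl + 1)
        }
      }
    }

    mean_db <- pmin(mean_db, 0)
    max_db <- pmin(max_db, 0)
    grid <- tibble(
      site_id = site_id,
      date = rep(as.Date(sprintf("%d-01-01", year)) + days - 1L,
                 each = 24L * .N_BINS),
      hour = rep(rep(0:23, each = .N_BINS), times = n_days),
      bin_hz = rep(bin_starts, times = n_slots),
      min_db = DB_FLOOR,
      mean_db = mean_db,
      max_db = max_db
    )
    list(grid = grid, truth = bind_rows(truth), peaks = peaks_truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
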