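# Synthetic wetland depth: daily bucket balance coupled to precipitation,
# expanded to the 24-readings-per-day logger schedule.

#' Simulate a wetland depth series for one site-year
#'
#' Daily bucket balance
#' `depth[d] = max(depth[d-1] + alpha * precip[d] - drawdown + noise, 0)`,
#' i.e. rainfall recharges the wetland at `depth_coupling_alpha` m per mm,
#' a constant drawdown drains it, and a small daily sensor/process noise term
#' perturbs it (set `depth_noise_sd = 0` for the exact deterministic
#' balance). The 24 hourly readings of a day all equal the day's balance, so
#' daily medians recover it exactly; the hydroperiod ends when depth reaches
#' 0 (clamped, never negative).
#'
#' @param weather Daily weather tibble from [simulate_weather()].
#' @param config A [sim_config()].
#' @param site_id Site identifier.
#' @param include_hourly Build the 24-readings-per-day logger expansion
#'   (default `TRUE`; disable in large ensemble studies that only consume
#'   daily values, which are identical either way).
#' @return List: `hourly` (tibble `site_id`, `date`, `hour`, `depth_m`;
#'   `NULL` when `include_hourly = FALSE`), `daily` (tibble `site_id`,
#'   `date`, `doy`, `depth_m`), `truth` (list with `depth_coupling_alpha`).
#' @export
simulate_depth <- function(weather, config, site_id = "S1",
                           include_hourly = TRUE) {
  stopifnot(inherits(config, "wetscape_sim_config"))
  stopifnot(all(c("doy", "date", "precip_mm", "year") %in% names(weather)))
  year <- weather$year[1]
  n <- nrow(weather)
  with_stream_seed(config, "depth", year, site_id, {
    noise <- if (config$depth_noise_sd > 0) {
      rnorm(n, sd = config$depth_noise_sd)
    } else {
      rep(0, n)
    }
    depth <- numeric(n)
    prev <- config$depth_start_m
    for (d in seq_len(n)) {
      prev <- max(
        prev + config$depth_coupling_alpha * weather$precip_mm[d] -
          config$depth_drawdown + noise[d],
        0
      )
      depth[d] <- prev
    }
    daily <- tibble(
      site_id = site_id, date = weather$date, doy = weather$doy,
      depth_m = depth
    )
    hourly <- if (include_hourly) {
      tibble(
        site_id = site_id,
        date = rep(weather$date, each = 24L),
        hour = rep(0:23, times = n),
        depth_m = rep(depth, each = 24L)
      )
    } else {
      NULL
    }
    list(
      hourly = hourly, daily = daily,
      truth = list(depth_coupling_alpha = config$depth_coupling_alpha)
    )
  })
}
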