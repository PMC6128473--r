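cfg0 <- sim_config(seed = 7)

test_that("weather collapses to a pure sinusoid in the noise-free limit", {
  cfg <- sim_config(seed = 1, temp_noise_sd = 0, precip_occurrence_prob = 0)
  w <- simulate_weather(cfg, 2008)
  expected <- cfg$temp_annual_mean +
    cfg$temp_mean_amplitude * cos(2 * pi * (1:365 - cfg$latitude_phase) / 365)
  expect_equal(w$tmean, expected)
  expect_true(all(w$precip_mm == 0))
  expect_true(all(w$tmin <= w$tmean & w$tmean <= w$tmax))
})

test_that("identical seeds give byte-identical streams", {
  b1 <- simulate_site_year(cfg0, 2009, "S3")
  b2 <- simulate_site_year(cfg0, 2009, "S3")
  expect_identical(b1$weather, b2$weather)
  expect_identical(b1$acoustics$grid, b2$acoustics$grid)
  expect_identical(b1$truth, b2$truth)
  # different units decorrelate
  b3 <- simulate_site_year(cfg0, 2009, "S4")
  expect_false(identical(b1$weather$tmean, b3$weather$tmean))
})

test_that("weather rejects years outside the configured span", {
  expect_error(simulate_weather(cfg0, 1999), "year must be")
  expect_error(simulate_weather(cfg0, 2008.5), "year must be")
})

test_that("wet-day frequency and amounts match the configured law", {
  cfg <- sim_config(seed = 3, precip_occurrence_prob = 0.3, n_years = 1000,
                    start_year = 1)
  wet <- vapply(1:1000, function(y) {
    sum(simulate_weather(cfg, y)$precip_mm > 0)
  }, numeric(1))
  # binomial expectation 365 * 0.3 = 109.5, SE of the mean over replicates
  se <- sqrt(365 * 0.3 * 0.7 / 1000)
  expect_lt(abs(mean(wet) - 109.5), 3 * se)
})

test_that("snow composites follow maximum-extent window arithmetic", {
  # snow on days 1..9 only: composites 1 (1-8) and 2 (9-16) snow, 3 free
  snow_day <- c(rep(TRUE, 9), rep(FALSE, 56))
  flags <- wetscape:::.composite_snow_flags(snow_day, eight_day_intervals(65))
  expect_equal(flags[1:3], c(TRUE, TRUE, FALSE))

  # always-freezing year: every composite flagged snow
  cfg <- sim_config(seed = 5)
  w <- make_weather(rep(-10, 365))
  w$year <- 2008
  s <- simulate_snow_composites(w, cfg)
  expect_true(all(s$flags$snow))
  expect_true(all(is.na(s$truth$melt_doy)))

  # identical thresholds -> identical flags across the 16 cells
  cfg_flat <- sim_config(seed = 5, melt_jitter_sd = 0)
  w2 <- simulate_weather(cfg0, 2008)
  s2 <- simulate_snow_composites(w2, cfg_flat)
  per_cell <- split(s2$flags$snow, s2$flags$cell)
  expect_true(all(vapply(per_cell, identical, logical(1), per_cell[[1]])))
  expect_equal(length(unique(s2$truth$melt_doy)), 1L)
})

test_that("depth balance drains, recharges, and never goes negative", {
  cfg <- sim_config(seed = 2, depth_coupling_alpha = 0, depth_noise_sd = 0,
                    depth_drawdown = 0.01, depth_start_m = 0.5)
  w <- make_weather(rep(5, 120), precip_mm = 5)
  w$year <- 2008
  d <- simulate_depth(w, cfg)
  expect_true(all(diff(d$daily$depth_m) <= 0))
  expect_equal(min(d$daily$depth_m), 0)
  expect_true(all(d$hourly$depth_m >= 0))

  # one 50 mm event under alpha = 0.001: net next-day gain 0.04 m
  cfg2 <- sim_config(seed = 2, depth_coupling_alpha = 0.001,
                     depth_noise_sd = 0, depth_drawdown = 0.01)
  pr <- rep(0, 30)
  pr[10] <- 50
  w2 <- make_weather(rep(5, 30), precip_mm = pr)
  w2$year <- 2008
  d2 <- daily_median_depth(simulate_depth(w2, cfg2)$hourly)
  expect_equal(d2$median_depth_m[10] - d2$median_depth_m[9], 0.04)
  expect_true(all(d2$valid))
})

test_that("planted calls respect melt, warmth, and the recorder floor", {
  b <- simulate_site_year(cfg0, 2010, "S1")
  tr <- b$truth$calls
  present <- dplyr::filter(tr, present)
  expect_gt(nrow(present), 0)
  # no planted window opens before block melt or on sub-zero days
  expect_true(all(present$first_call_doy >= b$truth$melt_doy))
  warm_doys <- b$weather$doy[b$weather$tmean >= 0]
  expect_true(all(present$first_call_doy %in% warm_doys))
  expect_true(all(present$last_call_doy %in% warm_doys))
  expect_true(all(present$first_call_doy <= present$last_call_doy))
  # peaks inside the spring-peeper window
  cru <- dplyr::filter(tr, species == "pseudacris_crucifer")
  if (cru$present && !is.null(b$truth$crucifer_peak_doys)) {
    expect_true(all(b$truth$crucifer_peak_doys >= cru$first_call_doy))
    expect_true(all(b$truth$crucifer_peak_doys <= cru$last_call_doy))
  }
  # grid bounded by the dB floor and ceiling
  expect_true(all(b$acoustics$grid$mean_db >= -88))
  expect_true(all(b$acoustics$grid$max_db <= 0))
})

test_that("a no-call site keeps every bin near the noise floor", {
  cfg <- sim_config(seed = 9, species_absence_prob = 1)
  b <- simulate_site_year(cfg, 2008, "S1")
  expect_true(all(!b$truth$calls$present))
  # half-normal noise with sd 1 dB stays within ~6 dB of the floor
  expect_lt(max(b$acoustics$grid$mean_db), -88 + 8)
  fc <- detect_first_call(b$acoustics$grid, default_signatures(), b$weather)
  expect_false(fc$found)
})

test_that("planted spring-peeper calls raise the primary band as built", {
  cfg <- sim_config(seed = 4, species_absence_prob = 0)
  b <- simulate_site_year(cfg, 2008, "S1")
  cru <- dplyr::filter(b$truth$calls, species == "pseudacris_crucifer")
  d <- as.Date("2008-01-01") + cru$first_call_doy - 1
  m <- band_hourly_median(b$acoustics$grid, d, 22, c(2900, 3200))
  # band median sits near floor + snr - rolloff - mean/max offset
  expect_gt(m, -88 + cfg$call_snr_db - 6 - 9)
  # and a pre-season day stays at the floor
  m0 <- band_hourly_median(b$acoustics$grid, min(b$acoustics$grid$date), 22,
                           c(2900, 3200))
  expect_lt(m0, -80)
})

test_that("noise-free landscape recovers the analytic green-up truth", {
  cfg <- sim_config(seed = 6, ndvi_noise_sd = 0)
  w <- simulate_weather(cfg, 2008)
  s <- simulate_snow_composites(w, cfg)
  l <- simulate_landscape(w, s, cfg)

  # closed-form crossing of the logistic: first week past the inverse
  bg <- cfg$ndvi_background
  pl <- cfg$ndvi_plateau
  mid <- l$truth$melt_week + cfg$ndvi_lag_weeks
  w_star <- mid + log((0.60 - bg) / (pl - 0.60)) / cfg$ndvi_rate
  analytic <- max(as.integer(ceiling(w_star + 1e-9)), 10L)
  expect_equal(l$truth$green_up_week, analytic)

  # detector on the (noise-free) emitted series equals the planted truth
  expect_equal(green_up_week(smooth_ndvi(l$ndvi$ndvi)),
               l$truth$green_up_week)

  # ET composites are zero while GDU is zero
  gdu_by_interval <- tapply(
    daily_gdu(w$tmin, w$tmax),
    eight_day_interval_of(w$doy), sum
  )
  zero_ivals <- as.integer(names(gdu_by_interval)[gdu_by_interval == 0])
  expect_true(all(l$et$et_mm[l$et$interval %in% zero_ivals] == 0))

  expect_error(sim_config(ndvi_plateau = 0.55), "plateau")
})

test_that("signature files and run configs round-trip through YAML", {
  sigs <- default_signatures()
  p <- tempfile(fileext = ".yaml")
  write_signatures(sigs, p)
  back <- read_signatures(p)
  expect_equal(names(back), names(sigs))
  expect_equal(back$pseudacris_crucifer$peaks, sigs$pseudacris_crucifer$peaks)
  expect_equal(back$pseudacris_crucifer$primary_band, c(2900, 3200))
  expect_equal(back$hyla_versicolor$typical_hours,
               sigs$hyla_versicolor$typical_hours)

  pc <- tempfile(fileext = ".yaml")
  write_run_config(cfg0, pc)
  cfg_back <- yaml::read_yaml(pc)
  expect_equal(cfg_back$seed, cfg0$seed)
  expect_equal(cfg_back$call_snr_db, cfg0$call_snr_db)
  unlink(c(p, pc))
})

test_that("truth sidecar and streams survive a write/read round trip", {
  dir <- tempfile("bundle")
  b <- simulate_site_year(cfg0, 2008, "S2")
  man1 <- write_site_year(b, dir)
  expect_true(all(file.exists(file.path(dir, man1$file))))
  man2 <- write_site_year(b, dir)
  expect_identical(man1, man2) # unchanged inputs -> identical digests

  back <- read_site_year(dir, "S2", 2008)
  expect_equal(nrow(back$grid), nrow(b$acoustics$grid))
  expect_equal(back$truth$green_up_week, b$truth$green_up_week)
  expect_equal(back$weather$tmean, b$weather$tmean)
  unlink(dir, recursive = TRUE)
})
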