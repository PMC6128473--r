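slots1 <- tibble::tibble(date = as.Date("2008-04-20"), hour = 21:23)

test_that("band medians use half-open 100-Hz bin containment", {
  g <- make_grid(slots1)
  expect_equal(band_hourly_median(g, "2008-04-20", 21, c(2900, 3200)), -88)

  g2 <- set_bins(g, "2008-04-20", 21, 2900, mean_db = -40)
  g2 <- set_bins(g2, "2008-04-20", 21, 3000, mean_db = -50)
  g2 <- set_bins(g2, "2008-04-20", 21, 3100, mean_db = -60)
  expect_equal(band_hourly_median(g2, "2008-04-20", 21, c(2900, 3200)), -50)

  # the bin starting at 3200 is outside [2900, 3200)
  g3 <- set_bins(g2, "2008-04-20", 21, 3200, mean_db = 0)
  expect_equal(band_hourly_median(g3, "2008-04-20", 21, c(2900, 3200)), -50)

  # absent recording is distinct from silence
  expect_true(is.na(band_hourly_median(g, "2008-04-21", 21, c(2900, 3200))))
})

test_that("daily integrand offsets the floor and integrates trapezoidally", {
  g <- make_grid(slots1)
  expect_equal(daily_activity_integrand(g, "2008-04-20"), 0)

  g2 <- g
  for (h in 21:23) {
    g2 <- set_bins(g2, "2008-04-20", h, c(2900, 3000, 3100), mean_db = -48)
  }
  expect_equal(daily_activity_integrand(g2, "2008-04-20"), 80)
  expect_equal(daily_activity_integrand(g2, "2008-04-20"),
               brute_trapezoid(rep(-48 + 88, 3)))

  # raising all in-band bins strictly increases it; raising a single bin
  # never decreases the band median; out-of-band changes leave it unchanged
  g3 <- set_bins(g2, "2008-04-20", 22, c(2900, 3000, 3100), mean_db = -20)
  expect_gt(daily_activity_integrand(g3, "2008-04-20"),
            daily_activity_integrand(g2, "2008-04-20"))
  g3b <- set_bins(g2, "2008-04-20", 22, 3000, mean_db = -20)
  expect_gte(daily_activity_integrand(g3b, "2008-04-20"),
             daily_activity_integrand(g2, "2008-04-20"))
  g4 <- set_bins(g2, "2008-04-20", 22, 5000, mean_db = -10)
  expect_equal(daily_activity_integrand(g4, "2008-04-20"),
               daily_activity_integrand(g2, "2008-04-20"))

  # a missing hour invalidates the date
  g5 <- dplyr::filter(g2, hour != 22)
  expect_true(is.na(daily_activity_integrand(g5, "2008-04-20")))
})

plant_signature <- function(grid, date, hour, sig, snr) {
  for (j in seq_len(nrow(sig$peaks))) {
    ctr <- sig$peaks$freq_hz[j]
    lvl <- -88 + snr + sig$peaks$rel_db[j]
    grid <- set_bins(grid, date, hour, ctr, mean_db = lvl - 2, max_db = lvl)
    grid <- set_bins(grid, date, hour, c(ctr - 100, ctr + 100),
                     mean_db = lvl - 7, max_db = lvl - 5)
  }
  grid
}

test_that("signature matching needs level margins and local maxima", {
  sig <- default_signatures()$pseudacris_crucifer
  g <- make_grid(slots1)
  r <- match_signature(g, "2008-04-20", 21, sig)
  expect_false(r$detected)
  expect_equal(r$score, 0)

  g2 <- plant_signature(g, "2008-04-20", 21, sig, snr = 20)
  r2 <- match_signature(g2, "2008-04-20", 21, sig, margin_db = 6)
  expect_true(r2$detected)
  expect_gt(r2$score, 0)

  # flat broadband masking spectrum has no local maxima
  g3 <- g
  g3$mean_db <- -30
  g3$max_db <- -30
  expect_false(match_signature(g3, "2008-04-20", 21, sig)$detected)
})

test_that("calling activity flags broadband-masked dates", {
  slots <- tidyr::crossing(date = as.Date("2008-04-20") + 0:1, hour = 21:23)
  g <- make_grid(slots)
  for (h in 21:23) {
    g <- set_bins(g, "2008-04-20", h, c(2900, 3000, 3100), mean_db = -48)
  }
  g$mean_db[g$date == as.Date("2008-04-21")] <- -30 # rain day
  act <- calling_activity(g)
  expect_false(act$masked[act$date == as.Date("2008-04-20")])
  expect_true(act$masked[act$date == as.Date("2008-04-21")])
  expect_equal(act$integrand[act$date == as.Date("2008-04-20")], 80)
})

test_that("first call scans all species and honours the sub-zero exclusion", {
  sigs <- default_signatures()
  slots <- tidyr::crossing(date = as.Date("2008-03-25") + 0:5, hour = 20:22)
  g <- make_grid(slots)
  g <- plant_signature(g, "2008-03-26", 21, sigs$lithobates_sylvaticus, 25)
  g <- plant_signature(g, "2008-03-28", 21, sigs$pseudacris_crucifer, 25)

  w <- make_weather(rep(5, 120))
  fc <- detect_first_call(g, sigs, w, deploy_date = "2008-03-25")
  expect_equal(fc$first_call_date, as.Date("2008-03-26"))
  expect_equal(fc$species, "lithobates_sylvaticus")
  expect_equal(fc$eight_day_interval, eight_day_interval_of(86))
  expect_false(fc$underway)

  # the wood-frog day never exceeded 0 degC at the station: skip to the next
  w2 <- w
  w2$tmax[86] <- -1
  fc2 <- detect_first_call(g, sigs, w2, deploy_date = "2008-03-25")
  expect_equal(fc2$first_call_date, as.Date("2008-03-28"))

  # silence -> explicit no-call result
  fc3 <- detect_first_call(make_grid(slots), sigs, w, "2008-03-25")
  expect_false(fc3$found)
  expect_true(is.na(fc3$eight_day_interval))

  # detection on the deployment date itself flags calling underway
  fc4 <- detect_first_call(g, sigs, w, deploy_date = "2008-03-26")
  expect_true(fc4$underway)
})

test_that("noise-free planted first call lands in interval ceil(doy/8)", {
  # planted day 85 -> interval 11 (days 81-88)
  sigs <- default_signatures()
  d85 <- as.Date("2008-01-01") + 84
  slots <- tidyr::crossing(date = d85 + (-3:3), hour = 21:22)
  g <- make_grid(slots)
  g <- plant_signature(g, d85, 21, sigs$pseudacris_crucifer, 30)
  fc <- detect_first_call(g, sigs, make_weather(rep(5, 120)), d85 - 3)
  expect_equal(fc$first_call_doy, 85L)
  expect_equal(fc$eight_day_interval, 11L)
})

test_that("presence uses the June-7 window with the late-June extension", {
  sig <- default_signatures()$pseudacris_crucifer
  april <- tidyr::crossing(date = as.Date("2008-04-10") + 0:2, hour = 21L)
  june <- tidyr::crossing(date = as.Date("2008-06-18") + 0:3, hour = 21L)
  g_april <- plant_signature(make_grid(april), "2008-04-11", 21, sig, 25)
  r <- detect_presence(g_april, sig)
  expect_true(r$present)
  expect_false(r$extended)

  g_june <- plant_signature(make_grid(dplyr::bind_rows(april, june)),
                            "2008-06-20", 21, sig, 25)
  r2 <- detect_presence(g_june, sig)
  expect_true(r2$present)
  expect_true(r2$extended)

  r3 <- detect_presence(make_grid(april), sig)
  expect_false(r3$present)

  expect_warning(r4 <- detect_presence(make_grid(april)[0, ], sig), "empty")
  expect_false(r4$present)
})

test_that("phenophase summary ranks unmasked peaks with early tie-breaks", {
  dates <- as.Date("2008-04-01") + 0:9
  act <- tibble::tibble(
    site_id = "T1", date = dates, integrand = 1:10,
    valid = TRUE, masked = FALSE
  )
  det <- tibble::tibble(species = "pseudacris_crucifer", date = dates)
  s <- summarize_phenophase(act, det)
  expect_equal(s$median_peak_date, dates[9])
  expect_equal(s$phenophase_days, 10L)
  expect_equal(sort(s$peak_dates[[1]]), dates[8:10])

  # all equal -> three earliest dates, median the 2nd
  act2 <- dplyr::mutate(act, integrand = 5)
  s2 <- summarize_phenophase(act2, det)
  expect_equal(s2$peak_dates[[1]], dates[1:3])
  expect_equal(s2$median_peak_date, dates[2])

  # masked dates are excluded from ranking
  act3 <- act
  act3$masked[10] <- TRUE
  s3 <- summarize_phenophase(act3, det)
  expect_equal(s3$median_peak_date, dates[8])

  expect_warning(
    s4 <- summarize_phenophase(act[1:2, ], det[1:2, ]),
    "fewer than 3"
  )
  expect_false(s4$peak_defined)
})

test_that("occupancy medians reproduce per-year proportions", {
  counts <- tibble::tibble(
    area = "X", year = 2008, detected = 3, monitored = 4
  )
  expect_equal(summarize_occupancy(counts)$median_proportion, 0.75)

  counts2 <- tibble::tibble(
    area = "Y", year = 2008:2009, detected = c(1, 0), monitored = c(2, 0)
  )
  expect_warning(r <- summarize_occupancy(counts2), "0 monitored")
  expect_equal(r$median_proportion, 0.5)

  expect_error(
    summarize_occupancy(tibble::tibble(area = "Z", year = 2008,
                                       detected = 5, monitored = 4)),
    "exceeds"
  )
})
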