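flags_tbl <- function(snow, start = NULL) {
  k <- seq_along(snow)
  tibble::tibble(
    interval = k,
    start_doy = if (is.null(start)) 1L + 8L * (k - 1L) else start,
    snow = snow
  )
}

test_that("snow-free onset finds the first contiguous snow-free pair", {
  # S S ... S F F with the first F starting day 65
  f <- flags_tbl(c(rep(TRUE, 8), FALSE, FALSE, FALSE))
  expect_equal(snow_free_onset_cell(f), 65L)

  # all snow-free: onset at the first composite starting on/after the cutoff
  f <- flags_tbl(rep(FALSE, 12))
  expect_equal(snow_free_onset_cell(f, cutoff_doy = 46L), 49L)
  expect_equal(snow_free_onset_cell(f, cutoff_doy = 59L), 65L)

  # F S F F after cutoff: onset at the first F of the contiguous pair
  f <- flags_tbl(c(rep(TRUE, 6), FALSE, TRUE, FALSE, FALSE))
  expect_equal(snow_free_onset_cell(f), 65L)

  expect_true(is.na(snow_free_onset_cell(flags_tbl(rep(TRUE, 12)))))
})

test_that("block snow-off averages cell onsets with half-up rounding", {
  r <- block_snow_off(rep(80L, 16))
  expect_equal(r$mean_onset_doy, 80L)
  expect_equal(r$week, 12L)

  r <- block_snow_off(c(rep(73L, 8), rep(81L, 8)))
  expect_equal(r$mean_onset_doy, 77L)
  expect_equal(r$week, 11L)

  expect_warning(r <- block_snow_off(c(rep(80L, 15), NA)), "dropped")
  expect_equal(r$n_cells_used, 15L)
  expect_true(is.na(block_snow_off(rep(NA_integer_, 16))$week))
})

test_that("composite-week crosswalk is injective with the printed orphans", {
  cw <- composite_week_crosswalk()
  expect_equal(nrow(cw$map), 46)
  expect_equal(cw$map$week[cw$map$interval == 1], 1L)
  expect_equal(cw$map$week[cw$map$interval == 5], 6L)
  expect_equal(anyDuplicated(cw$map$week), 0)
  expect_equal(intersect(cw$orphan_weeks, 1:34), c(5L, 13L, 21L, 29L))
})

test_that("pooled weekly bookkeeping matches site-years times covered weeks", {
  expect_equal(pooled_weekly_n(180, "8-day"), 5400L)
  expect_equal(pooled_weekly_n(180, "7-day"), 6120L)
  expect_equal(pooled_weekly_n(1, "8-day"), 30L)
})

test_that("NDVI smoothing is exact on lines and lifts downward spikes", {
  x <- seq(0.2, 0.8, length.out = 12)
  expect_equal(smooth_ndvi(x), x, tolerance = 1e-12)
  expect_equal(smooth_ndvi(rep(0.5, 10)), rep(0.5, 10))

  spike <- rep(0.7, 11)
  spike[6] <- 0.3
  sm <- smooth_ndvi(spike)
  expect_gt(sm[6], 0.3)

  expect_error(smooth_ndvi(rep(NA_real_, 8)), "all-missing")
  expect_error(smooth_ndvi(c(0.1, 0.2, 0.3)), "at least 5")
  expect_true(all(smooth_ndvi(c(0.9, 0.99, 1, 1, 0.98, 0.9)) <= 1))
})

test_that("winter background pools weeks 1-8 and averages blocks", {
  wk <- tidyr::crossing(block_id = c("B1", "B2"), year = 2008:2009,
                        week = 1:20)
  wk$ndvi <- 0.45
  bg <- winter_background(wk)
  expect_equal(bg$area, 0.45)
  expect_equal(bg$block$background, c(0.45, 0.45))
})

test_that("green-up week is strict, post-February, and spike-proof", {
  ndvi <- rep(0.4, 30)
  ndvi[16:30] <- 0.75
  expect_equal(green_up_week(ndvi), 16L)

  expect_true(is.na(green_up_week(rep(0.60, 30))))
  expect_equal(green_up_week(rep(0.60, 30), inclusive = TRUE), 10L)

  # pre-March excursion above threshold is ignored (false green-up)
  ndvi2 <- ndvi
  ndvi2[4:5] <- 0.9
  expect_equal(green_up_week(ndvi2), 16L)
})

test_that("growing-weeks count is strict and skips missing weeks", {
  ndvi <- rep(0.5, 40)
  expect_equal(growing_weeks_count(ndvi), 0L)

  ndvi[16:40] <- 0.8
  expect_equal(growing_weeks_count(ndvi), 19L) # weeks 16..34

  ndvi[20] <- NA
  expect_equal(growing_weeks_count(ndvi), 18L)
})

test_that("ET onset uses the weekly-aligned series with orphan handling", {
  # composite landing at week 14 because week 13 is an orphan
  et <- tibble::tibble(interval = 1:46, et_mm = 0)
  et$et_mm[et$interval == 12] <- 1.2
  aligned <- align_composites_to_weeks(et, "et_mm")
  cw <- composite_week_crosswalk()
  expect_true(13 %in% cw$orphan_weeks)
  expect_equal(cw$map$week[cw$map$interval == 12], 14L)
  expect_equal(et_onset_week(aligned$et_mm), 14L)

  expect_true(is.na(et_onset_week(rep(1, 30))))
  expect_equal(et_onset_week(c(0, 1.5, 2)), 2L)
})

test_that("accumulations skip-and-sum missing weeks and conserve totals", {
  a <- accumulate_weekly(rep(1, 10))
  expect_true(all(is.na(a$four_week[1:3])))
  expect_equal(a$four_week[4:10], rep(4, 7))

  x <- rep(1, 10)
  x[5] <- NA
  a <- accumulate_weekly(x)
  expect_equal(a$four_week[6], 3) # weeks 3,4,6
  expect_equal(a$to_date[10], sum(x, na.rm = TRUE))
})

test_that("correlation battery recovers construction and spans", {
  resp <- tidyr::crossing(block_id = "B1", year = 2008:2009, week = 1:34)
  resp$value <- resp$week + 10 * (resp$year - 2008)
  resp$stream <- "et"
  drv <- dplyr::rename(resp, station_id = block_id)
  drv$stream <- "gdu"
  mapping <- tibble::tibble(block_id = "B1", station_id = "B1")

  tab <- correlate_with_weather(resp, drv, mapping, mode = "levels")
  expect_true(all(abs(tab$rho - 1) < 1e-12))
  expect_setequal(tab$interval, c("weekly", "four_week", "to_date"))
  expect_equal(tab$n[tab$interval == "weekly"], 68)

  bad <- dplyr::filter(drv, year == 2008)
  expect_error(correlate_with_weather(resp, bad, mapping), "not covered")
})

test_that("white-noise responses decorrelate in delta mode", {
  mapping <- tibble::tibble(block_id = "B1", station_id = "B1")
  set.seed(31)
  drv <- tidyr::crossing(station_id = "B1", year = 2008:2010, week = 1:34)
  drv$stream <- "gdu"
  drv$value <- cumsum(runif(nrow(drv), 0, 5))
  rhos <- vapply(1:200, function(i) {
    resp <- tidyr::crossing(block_id = "B1", year = 2008:2010, week = 1:34)
    resp$stream <- "et"
    resp$value <- rnorm(nrow(resp))
    tab <- correlate_with_weather(resp, drv, mapping, mode = "deltas")
    tab$rho
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.1)
  expect_lt(abs(mean(rhos)), 0.05)
})
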