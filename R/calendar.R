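# Calendar arithmetic shared across modules. All analyses run on a 365-day
# civil year: 8-day satellite composite intervals and 7-day weeks both start
# on January 1 (day-of-year 1), so interval k spans days 1 + 8(k-1) .. 8k and
# week w spans days 1 + 7(w-1) .. 7w. 46 composites and 52 weeks cover a year
# (the final period is truncated at day 365).

#' Eight-day composite interval containing a day of year
#'
#' Composite intervals begin on January 1 and run in unbroken 8-day steps, so
#' a 365-day year holds 46 of them. This is the time base used for satellite
#' snow composites, evapotranspiration totals, and eight-day temperature
#' integrands.
#'
#' @param doy Integer day(s) of year (1--365).
#' @return Integer interval index (1--46), vectorised.
#' @examples
#' eight_day_interval_of(85) # days 81--88 fall in interval 11
#' @export
eight_day_interval_of <- function(doy) {
  stopifnot(all(doy >= 1), all(doy <= 366))
  (as.integer(doy) - 1L) %/% 8L + 1L
}

#' Week index containing a day of year
#'
#' Weeks are 7-day intervals beginning on January 1.
#'
#' @param doy Integer day(s) of year.
#' @return Integer week index (1--53), vectorised.
#' @export
week_of <- function(doy) {
  stopifnot(all(doy >= 1), all(doy <= 366))
  (as.integer(doy) - 1L) %/% 7L + 1L
}

#' Start day-of-year of an eight-day interval
#' @param k Interval index (1--46).
#' @return Integer day of year.
#' @export
eight_day_start <- function(k) {
  stopifnot(all(k >= 1))
  1L + 8L * (as.integer(k) - 1L)
}

#' Start day-of-year of a week
#' @param w Week index (1--52).
#' @return Integer day of year.
#' @export
week_start <- function(w) {
  stopifnot(all(w >= 1))
  1L + 7L * (as.integer(w) - 1L)
}

#' Table of eight-day intervals covering one year
#'
#' @param n_days Days in the year (default 365; leap days are not modelled).
#' @return A tibble with columns `interval`, `start_doy`, `end_doy` (end
#'   truncated to `n_days` for the final interval).
#' @export
eight_day_intervals <- function(n_days = 365L) {
  k <- seq_len(ceiling(n_days / 8))
  tibble(
    interval = as.integer(k),
    start_doy = eight_day_start(k),
    end_doy = pmin(eight_day_start(k) + 7L, as.integer(n_days))
  )
}

# Day-of-year of a Date within its own calendar year.
doy_of_date <- function(date) {
  as.integer(format(date, "%j"))
}

# First day-of-year of March; "post-February" windows (green-up search)
# start at weeks whose first day is on/after this.
.POST_FEBRUARY_DOY <- 60L
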