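# Independent oracles and tiny fixture builders used across the suite.

# Trapezoid by explicit panel loop (oracle for the vectorised formula).
brute_trapezoid <- function(y) {
  a <- 0
  for (i in seq_len(length(y) - 1)) {
    a <- a + (y[i] + y[i + 1]) / 2
  }
  a
}

# Mid-ranks computed from first principles: for each value, mean of the
# order positions it occupies.
brute_midranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Spearman rho as the Pearson correlation of rank vectors, written out as
# explicit sums (no cor()).
brute_spearman <- function(x, y) {
  rx <- brute_midranks(x)
  ry <- brute_midranks(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Type-7 quantile by hand: linear interpolation between order statistics.
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Minimal spectral-summary grid: every bin at `base_db`, then optional
# overrides. `slots` is a tibble(date, hour).
make_grid <- function(slots, base_db = -88, site_id = "T1") {
  bins <- seq(0, 10900, by = 100)
  g <- tidyr::crossing(slots, bin_hz = bins)
  tibble::tibble(
    site_id = site_id,
    date = as.Date(g$date), hour = g$hour, bin_hz = g$bin_hz,
    min_db = base_db, mean_db = base_db, max_db = base_db
  )
}

set_bins <- function(grid, date, hour, bin_hz, mean_db = NULL,
                     max_db = NULL) {
  idx <- grid$date == as.Date(date) & grid$hour == hour &
    grid$bin_hz %in% bin_hz
  if (!is.null(mean_db)) grid$mean_db[idx] <- mean_db
  if (!is.null(max_db)) grid$max_db[idx] <- max_db
  grid
}

# Daily weather table from raw vectors.
make_weather <- function(tmean, precip_mm = 0, year = 2008,
                         half_range = 4) {
  n <- length(tmean)
  tibble::tibble(
    year = year, doy = seq_len(n),
    date = as.Date(sprintf("%d-01-01", year)) + seq_len(n) - 1,
    tmin = tmean - half_range, tmean = tmean, tmax = tmean + half_range,
    precip_mm = rep_len(precip_mm, n)
  )
}
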