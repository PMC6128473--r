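# Wetland hydrology: hourly pressure-logger depths to daily medians, counts
# of depth-increase and precipitation days, and their rank association.

#' Daily median water depth from hourly logger readings
#'
#' Reduces an hourly depth series to one record per calendar date. A day is
#' `valid` only when it has exactly 24 hourly readings (the full logger
#' schedule); invalid days are retained but excluded from downstream
#' increase-day counting.
#'
#' @param hourly Tibble with columns `site_id`, `date` (Date or ISO-8601
#'   string), `hour` (0--23), `depth_m`.
#' @return Tibble with one row per site-date: `site_id`, `date`,
#'   `median_depth_m`, `n_readings`, `valid`.
#' @export
daily_median_depth <- function(hourly) {
  stopifnot(all(c("site_id", "date", "hour", "depth_m") %in% names(hourly)))
  hourly <- hourly %>% mutate(date = as.Date(.data$date))
  dup <- hourly %>%
    dplyr::count(.data$site_id, .data$date, .data$hour) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "daily_median_depth(): %d duplicated site/date/hour timestamps",
      nrow(dup)
    ))
  }
  hourly %>%
    group_by(.data$site_id, .data$date) %>%
    summarise(
      median_depth_m = median(.data$depth_m),
      n_readings = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(valid = .data$n_readings == 24L) %>%
    arrange(.data$site_id, .data$date)
}

#' Count days on which water depth increased
#'
#' A day counts when it and the previous *calendar* day are both valid and
#' its median depth exceeds the previous day's by more than `tolerance`
#' (default 0 m: any positive change). With
#' `consecutive_only = FALSE` the comparison is against the most recent valid
#' day instead, bridging logger gaps.
#'
#' @param records Output of [daily_median_depth()] for one site (or with a
#'   `site_id` column; counting is per site).
#' @param window Optional Date vector of length 2 restricting the season; the
#'   default spans the record (first to last valid day).
#' @param tolerance Minimum depth change in m counted as an increase.
#' @param consecutive_only Require the comparison days to be consecutive
#'   calendar dates (default `TRUE`).
#' @return Tibble with `site_id`, `n_increase_days`, `n_valid_days`.
#' @export
count_increase_days <- function(records, window = NULL, tolerance = 0,
                                consecutive_only = TRUE) {
  stopifnot(all(c("site_id", "date", "median_depth_m", "valid")
                %in% names(records)))
  records <- records %>% arrange(.data$site_id, .data$date)
  if (!is.null(window)) {
    window <- as.Date(window)
    records <- records %>%
      filter(.data$date >= window[1], .data$date <= window[2])
  }
  one_site <- function(df) {
    v <- df %>% filter(.data$valid)
    if (nrow(v) < 2) {
      warn(sprintf(
        "count_increase_days(): fewer than 2 valid days for site %s",
        df$site_id[1]
      ))
      return(tibble(
        site_id = df$site_id[1], n_increase_days = 0L,
        n_valid_days = nrow(v)
      ))
    }
    gap_ok <- if (consecutive_only) {
      as.integer(diff(v$date)) == 1L
    } else {
      rep(TRUE, nrow(v) - 1L)
    }
    rises <- diff(v$median_depth_m) > tolerance
    tibble(
      site_id = df$site_id[1],
      n_increase_days = sum(rises & gap_ok),
      n_valid_days = nrow(v)
    )
  }
  records %>%
    group_by(.data$site_id) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(one_site)
}

#' Count days with recorded precipitation
#'
#' @param weather Daily weather tibble with `doy` (or `date`) and
#'   `precip_mm`.
#' @param window Optional numeric day-of-year range (length 2, inclusive)
#'   matching the depth-logger deployment span.
#' @return Integer count of days with precipitation strictly above 0 mm.
#' @export
count_precip_days <- function(weather, window = NULL) {
  stopifnot("precip_mm" %in% names(weather))
  if (!is.null(window)) {
    stopifnot("doy" %in% names(weather))
    weather <- weather %>%
      filter(.data$doy >= window[1], .data$doy <= window[2])
  }
  sum(weather$precip_mm > 0, na.rm = TRUE)
}

#' Spearman rank association between paired site-year counts
#'
#' Rank correlation with mid-rank handling of ties. `method = "t"` (the
#' default) takes the p-value from the t-distribution approximation, as in
#' `cor.test`; `method = "permutation"` enumerates all `n!` pairings
#' (feasible for `n <= 8`) and reports the exact two-sided permutation
#' p-value, used as an independent oracle for the approximation.
#'
#' @param x,y Equal-length numeric vectors (e.g. increase-day and
#'   precipitation-day counts per site-year).
#' @param method `"t"` or `"permutation"`.
#' @return An object of class `wetscape_assoc`: a list with `rho`, `p_value`,
#'   `n`, `method`, and `degenerate` (`TRUE` when either vector is constant,
#'   in which case `rho` is `NA`).
#' @seealso [tidy.wetscape_assoc()], [glance.wetscape_assoc()]
#' @export
spearman_association <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    warn("spearman_association(): constant or near-empty input; rho undefined")
    res <- list(
      rho = NA_real_, p_value = NA_real_, n = n,
      method = method, degenerate = TRUE
    )
    class(res) <- "wetscape_assoc"
    return(res)
  }
  rho <- cor(rank(x), rank(y))
  p <- if (method == "t") {
    if (n < 3 || abs(rho) >= 1) {
      if (abs(rho) >= 1 && n >= 3) 0 else NA_real_
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8) {
      abort("permutation p-value is enumerated exactly only for n <= 8")
    }
    rx <- rank(x) - (n + 1) / 2
    ry <- rank(y) - (n + 1) / 2
    perms <- .all_permutations(n)
    # vectorised rho over all n! pairings of the (centred) rank vectors
    rhos <- as.numeric(matrix(ry[perms], nrow(perms), n) %*% rx) /
      sqrt(sum(rx^2) * sum(ry^2))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  res <- list(rho = rho, p_value = p, n = n, method = method,
              degenerate = FALSE)
  class(res) <- "wetscape_assoc"
  res
}

# All permutations of 1..n as a matrix (n! rows); recursive, n <= 8.
.all_permutations <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' @export
print.wetscape_assoc <- function(x, ...) {
  cat("Spearman rank association\n")
  cat(sprintf("  rho = %.4f, p = %.4g (%s), n = %d\n",
              x$rho, x$p_value, x$method, x$n))
  if (x$degenerate) cat("  (degenerate input; rho undefined)\n")
  invisible(x)
}

#' Tidy a Spearman association result
#'
#' @param x A `wetscape_assoc` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `p.value`, `n`, `method`.
#' @exportS3Method generics::tidy
tidy.wetscape_assoc <- function(x, ...) {
  tibble(
    estimate = x$rho, p.value = x$p_value, n = x$n, method = x$method
  )
}

#' @rdname tidy.wetscape_assoc
#' @exportS3Method generics::glance
glance.wetscape_assoc <- function(x, ...) {
  tidy.wetscape_assoc(x)
}

#' Depth-increase vs precipitation-day association table
#'
#' Builds a per-area and pooled association report from per-site-year counts:
#' one Spearman test per study area plus one across all areas, all computed
#' from the same per-site-year count rows.
#'
#' @param counts Tibble with columns `area`, `site_id`, `year`,
#'   `n_increase_days`, `n_precip_days`.
#' @return Tibble with `area` (including `"pooled"`), `n`, `rho`, `p_value`.
#' @export
hydro_association_table <- function(counts) {
  stopifnot(all(c("area", "n_increase_days", "n_precip_days")
                %in% names(counts)))
  one <- function(df, label) {
    a <- spearman_association(df$n_increase_days, df$n_precip_days)
    tibble(area = label, n = a$n, rho = a$rho, p_value = a$p_value)
  }
  per_area <- counts %>%
    group_by(.data$area) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(function(df) one(df, df$area[1]))
  bind_rows(one(counts, "pooled"), per_area)
}
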