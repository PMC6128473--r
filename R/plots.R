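# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a daily calling-activity series
#'
#' Integrand (dB-hour above the noise floor) by date, with masked dates
#' marked.
#'
#' @param object A [calling_activity()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.wetscape_activity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$integrand)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$masked), width = 0.8) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey25", `TRUE` = "orange"),
      labels = c(`FALSE` = "clear", `TRUE` = "masked"),
      name = NULL
    ) +
    ggplot2::labs(
      x = NULL, y = "calling-activity integrand (dB·h)",
      title = unique(object$site_id)[1]
    ) +
    ggplot2::theme_minimal()
}

#' Plot event-timing distributions per area
#'
#' Boxplot-style display (middle 50% box, whiskers to min/max) of each
#' cyclo-seasonal event's timing across units, per area.
#'
#' @param records Event tibble with an `area` column (see
#'   [assemble_area_summary()]).
#' @param events Event columns to include (default: all present).
#' @return A ggplot.
#' @export
plot_event_timing <- function(records, events = NULL) {
  if (is.null(events)) {
    events <- intersect(
      c("temp0_interval", "snowfree_interval", "first_call_interval",
        "temp10_week", "snowoff_week", "greenup_week", "et_onset_week"),
      names(records)
    )
  }
  long <- records %>%
    tidyr::pivot_longer(dplyr::all_of(events), names_to = "event",
                        values_to = "value") %>%
    filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$event, y = .data$value)) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::facet_wrap(ggplot2::vars(.data$area)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "8-day interval / week index") +
    ggplot2::theme_minimal()
}

#' Plot a climatograph
#'
#' Four-week precipitation totals against the 2 mm-per-degC surplus/deficit
#' threshold line.
#'
#' @param climatograph Output of [climatograph_series()].
#' @return A ggplot.
#' @export
plot_climatograph <- function(climatograph) {
  ggplot2::ggplot(
    climatograph,
    ggplot2::aes(x = .data$end_week, y = .data$precip_total_mm)
  ) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$status), width = 0.8) +
    ggplot2::geom_line(
      ggplot2::aes(y = 2 * pmax(.data$tmean_window, 0)),
      colour = "firebrick"
    ) +
    ggplot2::scale_fill_manual(
      values = c(surplus = "steelblue", deficit = "tan3"), name = NULL
    ) +
    ggplot2::labs(
      x = "end week of 4-week window", y = "precipitation (mm)",
      caption = "line: 2 mm/°C water-demand equivalency"
    ) +
    ggplot2::theme_minimal()
}
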