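#' Plot an hourly drinking-power profile
#'
#' Bar chart of each hour's share of the day's total drinking power, the
#' standard way to show when during the day an animal drinks hardest.
#'
#' @param object A [power_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.power_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = hour, y = pct_power)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Clock hour", y = "% of total drinking power",
                  title = "Hourly drinking power") +
    ggplot2::theme_minimal()
}

#' Plot hourly drinking frequency and duration
#'
#' Side-by-side view of the diurnal pattern: events per hour and mean
#' event duration per hour.
#'
#' @param hourly An [hourly_summary()] tibble.
#' @return A ggplot object (faceted).
#' @export
plot_hourly_pattern <- function(hourly) {
  long <- hourly %>%
    select(hour, `events` = n_events, `mean duration (s)` = mean_duration_s) %>%
    tidyr::pivot_longer(-hour, names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = hour, y = value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Clock hour", y = NULL,
                  title = "Diurnal drinking pattern") +
    ggplot2::theme_minimal()
}

#' Plot an event timeline
#'
#' One point per drinking event, positioned at its start clock time and
#' sized by duration, optionally coloured per pig — the standard way to
#' eyeball inter-pig variability over a study period.
#'
#' @param events Event tibble with `start_clock` (or `start_s`) and
#'   `duration_s`; `pen_id` and `day` are used when present.
#' @param session_start Passed to the clock conversion when `events`
#'   lacks `start_clock`.
#' @return A ggplot object.
#' @export
plot_event_timeline <- function(events, session_start = NULL) {
  events <- as_tibble(events)
  events$.hour <- event_clock_hours(events, session_start)
  if (!"pen_id" %in% names(events)) events$pen_id <- "pen"
  if (!"day" %in% names(events)) events$day <- 1L
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$.hour, y = factor(day),
                               size = duration_s, colour = pen_id)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Clock hour", y = "Day", size = "Duration (s)",
                  colour = "Pig", title = "Drinking events") +
    ggplot2::theme_minimal()
}
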