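#' Hourly drinking summary
#'
#' Bins drinking events by the clock hour of their start (an event
#' spanning an hour boundary counts wholly in its start hour) and reports
#' per hour the event count, mean duration and total duration, aggregated
#' over all supplied pig-days. All 24 hours are reported; hours without
#' events get a zero-count row with zero durations.
#'
#' @param events Event tibble with `duration_s` and either a
#'   `start_clock` column or `start_s` plus a `session_start` argument.
#' @param session_start Clock time of session second 0; only needed when
#'   `events` lacks `start_clock`.
#' @param lights_on Two clock times delimiting the lit (active) window;
#'   events outside it are kept but reported with a warning.
#' @return Tibble with 24 rows: `hour`, `n_events`, `mean_duration_s`,
#'   `total_duration_s`.
#' @export
hourly_summary <- function(events, session_start = NULL,
                           lights_on = c("06:30", "18:30")) {
  hrs <- event_clock_hours(events, session_start)
  if (!is.null(lights_on)) {
    lo <- parse_clock(lights_on) / 3600
    outside <- hrs < lo[1] | hrs >= lo[2]
    if (any(outside)) {
      warn(sprintf("%d event(s) start outside the lights-on window %s-%s",
                   sum(outside), lights_on[1], lights_on[2]))
    }
  }
  per_hour <- tibble(hour = floor(hrs), duration_s = events$duration_s) %>%
    group_by(hour) %>%
    summarise(n_events = dplyr::n(),
              mean_duration_s = mean(duration_s),
              total_duration_s = sum(duration_s),
              .groups = "drop")
  tibble(hour = 0:23) %>%
    left_join(per_hour, by = "hour") %>%
    tidyr::replace_na(list(n_events = 0L, mean_duration_s = 0,
                           total_duration_s = 0))
}

event_clock_hours <- function(events, session_start = NULL) {
  if (!is.null(session_start)) {
    if (!"start_s" %in% names(events)) {
      abort("events need a start_s column when session_start is given",
            class = c("pigsip_error_validation", "pigsip_error"))
    }
    return(clock_hours(events$start_s, parse_clock(session_start)))
  }
  if ("start_clock" %in% names(events)) {
    return(parse_clock(events$start_clock) / 3600)
  }
  abort("events need start_clock, or start_s with session_start",
        class = c("pigsip_error_validation", "pigsip_error"))
}

#' Drinking-power table
#'
#' Drinking power combines how often and how long an animal drinks: per
#' clock hour, `power = n_events x mean_duration` (seconds), with each
#' hour's share expressed as a percentage of the day's total power. The
#' overall row (total events, overall mean duration `total power / total
#' events`, total power) is available through [glance()].
#'
#' @param hourly Hourly summary tibble with columns `hour`, `n_events`,
#'   `mean_duration_s` — as from [hourly_summary()] or read from an
#'   external table. Zero-count hours are dropped (power is defined over
#'   observed hours).
#' @return A `power_table`: tibble `hour`, `n_events`, `mean_duration_s`,
#'   `power_s`, `pct_power`, with attributes `total_events`,
#'   `total_power_s`, `overall_mean_s`.
#' @examples
#' h <- tibble::tibble(hour = c(14, 15), n_events = c(69, 93),
#'                     mean_duration_s = c(56.0, 38.6))
#' pt <- power_table(h)
#' glance(pt)
#' @export
power_table <- function(hourly) {
  needed <- c("hour", "n_events", "mean_duration_s")
  if (!all(needed %in% names(hourly))) {
    abort(paste0("hourly table needs columns: ",
                 paste(needed, collapse = ", ")),
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  observed <- filter(as_tibble(hourly), n_events > 0)
  if (nrow(observed) == 0 || sum(observed$n_events) == 0) {
    abort("power table needs at least one event",
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  out <- observed %>%
    mutate(power_s = n_events * mean_duration_s) %>%
    mutate(pct_power = 100 * power_s / sum(power_s)) %>%
    select(hour, n_events, mean_duration_s, power_s, pct_power) %>%
    arrange(hour)
  structure(out,
            class = c("power_table", class(out)),
            total_events = sum(out$n_events),
            total_power_s = sum(out$power_s),
            overall_mean_s = sum(out$power_s) / sum(out$n_events))
}

#' @export
glance.power_table <- function(x, ...) {
  tibble(
    n_hours = nrow(x),
    total_events = attr(x, "total_events"),
    total_power_s = attr(x, "total_power_s"),
    overall_mean_s = attr(x, "overall_mean_s")
  )
}

#' Stratify drinking power into feeding-related and other hours
#'
#' Feeding drives thirst: with dry feed delivered around 07:00 and 13:00,
#' the hour of and the hour after each feed (defaults \{8, 9\} and
#' \{13, 14, 15\}) are contrasted against the remaining lit hours. Per
#' hour set the mean of the hourly power percentages is reported, plus
#' the relative power versus the all-hours reference mean (which is
#' `100 / number of observed hours` by construction).
#'
#' @param power A [power_table()].
#' @param feeding_hours Clock hours counted as feeding-related thirst.
#' @param other_hours Remaining hours; defaults to all observed hours not
#'   in `feeding_hours`. The two sets must be disjoint and cover the
#'   observed hours.
#' @return Tibble with rows `feeding`, `non_feeding`, `all`: columns
#'   `set`, `n_hours`, `hours`, `mean_pct_power`, `relative_power_pct`.
#' @export
stratify_power <- function(power, feeding_hours = c(8, 9, 13, 14, 15),
                           other_hours = NULL) {
  stopifnot(inherits(power, "power_table"))
  observed <- power$hour
  other_hours <- other_hours %||% setdiff(observed, feeding_hours)
  if (length(intersect(feeding_hours, other_hours)) > 0) {
    abort("feeding_hours and other_hours overlap",
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  if (!setequal(union(feeding_hours, other_hours), observed)) {
    abort("hour sets must cover exactly the observed hours",
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  all_mean <- 100 / length(observed)
  set_row <- function(name, hours) {
    pct <- power$pct_power[power$hour %in% hours]
    tibble(set = name,
           n_hours = length(hours),
           hours = paste(sort(hours), collapse = ","),
           mean_pct_power = mean(pct),
           relative_power_pct = 100 * mean(pct) / all_mean)
  }
  bind_rows(
    set_row("feeding", feeding_hours),
    set_row("non_feeding", other_hours),
    tibble(set = "all", n_hours = length(observed),
           hours = paste(sort(observed), collapse = ","),
           mean_pct_power = all_mean, relative_power_pct = 100)
  )
}

#' Per pig-day drinking summaries
#'
#' For each pig-day: event count, total drinking time (seconds and
#' minutes), mean/max event duration, the population standard deviation
#' of durations, and the (fractional) clock hours of the first and last
#' event.
#'
#' @param events Event tibble with `duration_s`, a clock reference
#'   (`start_clock`, or `start_s` + `session_start`), and optionally
#'   `pen_id` and `day` columns used for grouping (absent columns default
#'   to a single group).
#' @inheritParams hourly_summary
#' @return Tibble with one row per pig-day: `pen_id`, `day`, `n_events`,
#'   `total_s`, `total_min`, `mean_s`, `max_s`, `sd_s`, `first_hour`,
#'   `last_hour`.
#' @export
daily_summary <- function(events, session_start = NULL) {
  events <- as_tibble(events)
  if (!"pen_id" %in% names(events)) events$pen_id <- NA_character_
  if (!"day" %in% names(events)) events$day <- 1L
  events$.hour <- event_clock_hours(events, session_start)
  events %>%
    group_by(pen_id, day) %>%
    summarise(
      n_events = dplyr::n(),
      total_s = sum(duration_s),
      total_min = sum(duration_s) / 60,
      mean_s = mean(duration_s),
      max_s = max(duration_s),
      sd_s = pop_sd(duration_s),
      first_hour = min(.data$.hour),
      last_hour = max(.data$.hour),
      .groups = "drop"
    )
}

# population (denominator n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Descriptive statistics of daily event counts per pig
#'
#' Mean, median, population standard deviation (denominator `n`) and
#' range of a daily metric, per pig. The population denominator matches
#' how small fixed monitoring periods (here: complete 6-day blocks, not
#' samples from a longer run) are conventionally summarised.
#'
#' @param daily Tibble with one row per pig-day, e.g. from
#'   [daily_summary()] or [minipig_daily()].
#' @param value Column to summarise (tidy-eval; default `n_events`).
#' @param group Grouping column identifying the pig (default `pen_id`).
#' @return Tibble per pig: `pen_id` (or your group name), `n_days`,
#'   `mean`, `median`, `sd`, `min`, `max`.
#' @export
descriptive_stats <- function(daily, value = n_events, group = pen_id) {
  daily %>%
    group_by({{ group }}) %>%
    summarise(
      n_days = dplyr::n(),
      mean = mean({{ value }}),
      median = median({{ value }}),
      sd = pop_sd({{ value }}),
      min = min({{ value }}),
      max = max({{ value }}),
      .groups = "drop"
    )
}
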