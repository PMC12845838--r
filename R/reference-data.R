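#' Reference minipig drinking tables
#'
#' Published summary tables from a six-day monitoring study of three
#' singly housed Göttingen minipigs under a 06:30-18:30 light cycle,
#' shipped as plain CSV so the behavioural-characterisation arithmetic
#' (power tables, stratification, descriptive statistics, inter-pig
#' tests) can be recomputed end to end:
#'
#' * `minipig_hourly()` — pooled hourly event counts and mean durations
#'   over the 18 analysed pig-days (hours 6-18).
#' * `minipig_daily()` — per pig-day event counts, total/mean/max
#'   durations, duration standard deviation and first/last event hours.
#'
#' @return A tibble; see above.
#' @examples
#' glance(power_table(minipig_hourly()))
#' @export
minipig_hourly <- function() {
  readr::read_csv(
    system.file("extdata", "minipig_hourly.csv", package = "pigsip",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

#' @rdname minipig_hourly
#' @export
minipig_daily <- function() {
  readr::read_csv(
    system.file("extdata", "minipig_daily.csv", package = "pigsip",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}
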