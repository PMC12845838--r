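#' Illness indicator from an individual drinking baseline
#'
#' Each pig acts as its own control: a healthy baseline window yields a
#' baseline median `m_b` and population standard deviation `s_b` of the
#' daily drinking metric, and later days are flagged when they deviate
#' too far from the median. Two rules are provided because the field uses
#' both phrasings of "sustained deviation":
#'
#' * `mode = "absolute"` — flag day `d` iff `|count_d - m_b| > k * s_b`
#'   (default `k = 2`);
#' * `mode = "relative"` — flag day `d` iff `|count_d - m_b| > r * m_b`
#'   (default `r = 0.4`, i.e. a 40% rise or drop).
#'
#' @param daily_counts Numeric vector of per-day counts (or any daily
#'   drinking metric), in day order, or a tibble with columns `day` and
#'   `n_events`.
#' @param baseline_days Indices (into days) of the designated healthy
#'   baseline window; at least 3 days.
#' @param k Multiplier on the baseline standard deviation (absolute
#'   mode); must be > 0.
#' @param r Relative fraction of the baseline median (relative mode); in
#'   (0, 1).
#' @param mode `"absolute"` or `"relative"`.
#' @return Tibble per day: `day`, `count`, `baseline` (logical),
#'   `deviation` (count minus `m_b`), `threshold`, `flagged`. Baseline
#'   median and sd are attached as attributes `m_b`, `s_b`.
#' @examples
#' illness_flags(c(45, 52, 49, 50, 48, 51, 80), baseline_days = 1:6)
#' @export
illness_flags <- function(daily_counts, baseline_days, k = 2, r = 0.4,
                          mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (is.data.frame(daily_counts)) {
    days <- daily_counts$day
    counts <- daily_counts$n_events
  } else {
    counts <- as.numeric(daily_counts)
    days <- seq_along(counts)
  }
  if (!is.numeric(k) || k <= 0) {
    abort("k must be > 0", class = c("pigsip_error_contract", "pigsip_error"))
  }
  if (!is.numeric(r) || r <= 0 || r >= 1) {
    abort("r must lie in (0, 1)", class = c("pigsip_error_contract", "pigsip_error"))
  }
  in_baseline <- days %in% days[baseline_days]
  if (sum(in_baseline) < 3) {
    abort("baseline window must span at least 3 days",
          class = c("pigsip_error_contract", "pigsip_error"))
  }
  m_b <- median(counts[in_baseline])
  s_b <- pop_sd(counts[in_baseline])
  threshold <- if (mode == "absolute") k * s_b else r * m_b
  out <- tibble(
    day = days,
    count = counts,
    baseline = in_baseline,
    deviation = counts - m_b,
    threshold = threshold,
    flagged = abs(counts - m_b) > threshold
  )
  structure(out, m_b = m_b, s_b = s_b, mode = mode)
}
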