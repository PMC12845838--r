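test_that("hourly summary bins events by their start hour", {
  ev <- tibble::tibble(start_clock = c("07:30:00", "07:59:59", "08:00:00"),
                       duration_s = c(10, 20, 30))
  h <- hourly_summary(ev)
  expect_equal(nrow(h), 24L)
  expect_equal(h$n_events[h$hour == 7], 2L)
  expect_equal(h$mean_duration_s[h$hour == 7], 15)
  expect_equal(h$n_events[h$hour == 8], 1L)   # boundary event counts in hour 8
  expect_equal(sum(h$n_events), 3L)

  # no events: all-zero table
  zero <- hourly_summary(ev[0, ])
  expect_equal(sum(zero$n_events), 0L)
  expect_equal(sum(zero$total_duration_s), 0)

  # session-relative times plus a session start work too
  ev2 <- tibble::tibble(start_s = 1800, duration_s = 10)
  h2 <- hourly_summary(ev2, session_start = "06:30")
  expect_equal(h2$n_events[h2$hour == 7], 1L)

  # events outside lights-on are kept but flagged
  expect_warning(hourly_summary(tibble::tibble(start_clock = "03:00:00",
                                               duration_s = 5)),
                 "lights-on")
})

test_that("power is count times mean duration, with shares of the total", {
  h <- tibble::tibble(hour = 15, n_events = 2L, mean_duration_s = 10)
  pt <- power_table(h)
  expect_equal(pt$power_s, 20)
  expect_equal(pt$pct_power, 100)
  expect_equal(glance(pt)$overall_mean_s, 10)

  # shares always sum to 100, and total power equals summed durations when
  # the hourly table came from raw events
  sim <- simulate_session(hours = 6, fps = 2, seed = 21)
  ev <- detect_events(sim$stream)
  pt2 <- power_table(hourly_summary(ev))
  expect_equal(sum(pt2$pct_power), 100, tolerance = 1e-9)
  expect_equal(attr(pt2, "total_power_s"), sum(ev$duration_s),
               tolerance = 1e-9)
  expect_error(power_table(h[0, ]), class = "pigsip_error_validation")
})

test_that("stratified power contrasts hour sets against the all-hours mean", {
  # uniform shares: both sets at the all-hours mean, relative power 100%
  h <- tibble::tibble(hour = 6:18, n_events = 10L, mean_duration_s = 30)
  s <- stratify_power(power_table(h))
  expect_equal(s$mean_pct_power, rep(100 / 13, 3), tolerance = 1e-9)
  expect_equal(s$relative_power_pct, rep(100, 3), tolerance = 1e-9)

  pt <- power_table(h)
  expect_error(stratify_power(pt, feeding_hours = c(8, 9),
                              other_hours = c(9, 10)),
               class = "pigsip_error_validation")
  expect_error(stratify_power(pt, feeding_hours = c(8, 9),
                              other_hours = c(10, 11)),
               class = "pigsip_error_validation")
})

test_that("daily summaries report totals, extremes and first/last hours", {
  ev <- tibble::tibble(
    pen_id = "pig A", day = 1L,
    start_clock = c("07:30:00", "10:15:00", "16:45:00"),
    duration_s = c(10, 20, 60)
  )
  d <- daily_summary(ev)
  expect_equal(d$n_events, 3L)
  expect_equal(d$total_s, 90)
  expect_equal(d$total_min, 1.5)
  expect_equal(d$mean_s, 30)
  expect_equal(d$max_s, 60)
  expect_equal(d$sd_s, sqrt(mean((c(10, 20, 60) - 30)^2)))  # population sd
  expect_equal(d$first_hour, 7.5)
  expect_equal(d$last_hour, 16.75)

  single <- daily_summary(tibble::tibble(start_clock = "09:00:00",
                                         duration_s = 30))
  expect_equal(single$sd_s, 0)
  expect_equal(single$first_hour, single$last_hour)
})

test_that("descriptive statistics use the population standard deviation", {
  d <- tibble::tibble(pen_id = rep("p", 3), n_events = c(5, 5, 5))
  s <- descriptive_stats(d)
  expect_equal(s$sd, 0)
  expect_equal(c(s$min, s$max), c(5, 5))

  counts <- c(22, 25, 24, 27, 73, 69)
  s2 <- descriptive_stats(tibble::tibble(pen_id = "q", n_events = counts))
  expect_equal(s2$sd, sqrt(mean((counts - mean(counts))^2)))
  expect_equal(s2$median, 26)
})

test_that("Kruskal-Wallis agrees with hand-ranked cases and the formula oracle", {
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic, 2.4,
               tolerance = 1e-12)

  # identical groups: pure midranks, no separation
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1, tolerance = 1e-12)

  # formula oracle with ties, all N <= 10
  set.seed(202)
  for (i in 1:30) {
    g <- sample(2:3, 1)
    sizes <- sample(1:4, g, replace = TRUE)
    while (sum(sizes) > 10) sizes <- sample(1:4, g, replace = TRUE)
    groups <- lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
    if (sd(unlist(groups)) == 0) next
    expect_equal(kruskal_wallis(groups)$statistic, kw_H_formula(groups),
                 tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3)), class = "pigsip_error_contract")
})

test_that("one-way ANOVA matches hand decomposition and the t-test identity", {
  expect_equal(one_way_anova(list(1:3, 4:6))$statistic, 13.5,
               tolerance = 1e-12)
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 3, 2)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(one_way_anova(list(c(2, 2), c(5, 5))),
               class = "pigsip_error_degenerate")

  # F = t^2 on any two-group input
  set.seed(303)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1), mean = 1)
    f <- one_way_anova(list(a, b))$statistic
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-10)
  }
})

test_that("normality test enforces its sample-size and variance contract", {
  expect_error(normality_test(1:2), class = "pigsip_error_contract")
  expect_error(normality_test(rnorm(51)), class = "pigsip_error_contract")
  expect_error(normality_test(rep(3, 10)), class = "pigsip_error_degenerate")
  expect_gt(normality_test(1:20)$p.value, 0.05)  # uniform grid, near-normal
})

test_that("compare_pigs bundles descriptives, normality and both tests", {
  cmp <- compare_pigs(minipig_daily(), value = n_events, group = pig)
  g <- glance(cmp)
  expect_equal(g$n_groups, 3L)
  expect_equal(g$n_total, 18L)
  expect_equal(nrow(tidy(cmp)), 2L)
  expect_equal(nrow(cmp$normality), 3L)
  # rank test identical to calling the routine on the split groups
  expect_equal(g$kw_H,
               kruskal_wallis(reference_daily_counts())$statistic)
})
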