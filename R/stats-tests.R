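#' Rank-based and parametric inter-pig tests
#'
#' Thin, contract-checked fronts over the standard routines used to
#' compare daily drinking counts between pigs:
#'
#' * `kruskal_wallis()` — Kruskal-Wallis rank-sum test with midranks for
#'   ties and the usual tie correction; p from chi-square with
#'   `groups - 1` df ([stats::kruskal.test()]).
#' * `one_way_anova()` — classical one-way ANOVA with the pooled
#'   (equal-variance) within-group error ([stats::oneway.test()] with
#'   `var.equal = TRUE`).
#' * `normality_test()` — Shapiro-Wilk normality test
#'   ([stats::shapiro.test()]), restricted to `3 <= n <= 50`.
#'
#' @param x Numeric observations, or a list of numeric group vectors
#'   (then `g` is ignored).
#' @param g Group labels aligned to `x`.
#' @return A one-row tibble: `statistic`, `df` (where defined),
#'   `p.value`, `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))
#' @export
kruskal_wallis <- function(x, g = NULL) {
  groups <- as_groups(x, g, min_groups = 2, min_per_group = 1)
  ht <- kruskal.test(groups)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, method = "Kruskal-Wallis rank sum test")
}

#' @rdname kruskal_wallis
#' @export
one_way_anova <- function(x, g = NULL) {
  groups <- as_groups(x, g, min_groups = 2, min_per_group = 2)
  if (all(vapply(groups, function(v) sd(v) == 0, logical(1)))) {
    # identical-within groups: F is 0/0 unless means differ; define the
    # degenerate all-constant case explicitly
    abort("zero within-group variance; F is undefined",
          class = c("pigsip_error_degenerate", "pigsip_error"))
  }
  y <- unlist(groups)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- oneway.test(y ~ fac, var.equal = TRUE)
  tibble(statistic = unname(ht$statistic),
         df = unname(ht$parameter[1]),
         p.value = ht$p.value,
         method = "One-way ANOVA (equal variances)")
}

#' @rdname kruskal_wallis
#' @export
normality_test <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 50) {
    abort("Shapiro-Wilk requires 3 <= n <= 50 observations here",
          class = c("pigsip_error_contract", "pigsip_error"))
  }
  if (sd(x) == 0) {
    abort("constant sample: normality test undefined",
          class = c("pigsip_error_degenerate", "pigsip_error"))
  }
  ht <- shapiro.test(x)
  tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "Shapiro-Wilk normality test")
}

as_groups <- function(x, g, min_groups, min_per_group) {
  groups <- if (is.list(x)) lapply(x, as.numeric) else {
    if (is.null(g) || length(g) != length(x)) {
      abort("supply a list of groups, or x with aligned group labels g",
            class = c("pigsip_error_contract", "pigsip_error"))
    }
    split(as.numeric(x), g)
  }
  if (length(groups) < min_groups ||
      any(lengths(groups) < min_per_group)) {
    abort(sprintf("need >= %d groups with >= %d observation(s) each",
                  min_groups, min_per_group),
          class = c("pigsip_error_contract", "pigsip_error"))
  }
  groups
}

#' Compare pigs on a daily drinking metric
#'
#' Bundles the inter-pig comparison reported for daily drinking counts:
#' per-pig descriptive statistics ([descriptive_stats()]), a per-group
#' Shapiro-Wilk normality check, the Kruskal-Wallis rank test (the
#' preferred method when any group departs from normality) and one-way
#' ANOVA. Returns a `pig_comparison` object with [tidy()] (per-test rows)
#' and [glance()] (one-row overview) methods.
#'
#' @inheritParams descriptive_stats
#' @return A `pig_comparison` object: list with `descriptives` (tibble),
#'   `normality` (tibble, per pig), `tests` (tibble: Kruskal-Wallis and
#'   ANOVA rows), `groups` (named list of the raw values).
#' @examples
#' compare_pigs(minipig_daily(), value = n_events, group = pig)
#' @export
compare_pigs <- function(daily, value = n_events, group = pen_id) {
  dat <- daily %>%
    select(group = {{ group }}, value = {{ value }})
  groups <- split(dat$value, dat$group)
  desc <- descriptive_stats(dat, value = value, group = group)
  normality <- purrr::imap_dfr(groups, function(v, nm) {
    res <- tryCatch(normality_test(v),
                    pigsip_error = function(e) {
                      tibble(statistic = NA_real_, p.value = NA_real_,
                             method = conditionMessage(e))
                    },
                    error = function(e) {
                      tibble(statistic = NA_real_, p.value = NA_real_,
                             method = conditionMessage(e))
                    })
    mutate(res, group = nm, .before = 1)
  })
  tests <- bind_rows(kruskal_wallis(groups), one_way_anova(groups))
  structure(
    list(descriptives = desc, normality = normality, tests = tests,
         groups = groups),
    class = "pig_comparison"
  )
}

#' @export
print.pig_comparison <- function(x, ...) {
  cat("<pig_comparison>\n\nDescriptives:\n")
  print(x$descriptives)
  cat("\nNormality (Shapiro-Wilk):\n")
  print(x$normality)
  cat("\nTests:\n")
  print(x$tests)
  invisible(x)
}

#' @export
tidy.pig_comparison <- function(x, ...) {
  x$tests
}

#' @export
glance.pig_comparison <- function(x, ...) {
  kw <- x$tests[grepl("Kruskal", x$tests$method), ]
  av <- x$tests[grepl("ANOVA", x$tests$method), ]
  tibble(
    n_groups = length(x$groups),
    n_total = sum(lengths(x$groups)),
    kw_H = kw$statistic, kw_p = kw$p.value,
    anova_F = av$statistic, anova_p = av$p.value,
    min_shapiro_p = suppressWarnings(min(x$normality$p.value, na.rm = TRUE))
  )
}
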