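Package: pigsip
Title: Drinking-Event Detection and Behavioural Analytics for
    Camera-Monitored Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detector-agnostic pipeline for inferring drinking events of
    singly housed pigs from per-frame object-detection streams (pig-head
    and water-faucet bounding boxes). Fixes faucet positions from the
    opening frames of a session, scores head-faucet proximity normalised
    by the frame diagonal, flags frames above a proximity threshold, and
    segments flagged runs into drinking events with a minimum-duration
    filter. Includes frame-level confusion metrics and event-level
    temporal intersection-over-union against human ground truth, hourly
    drinking-power tables, feeding-hour stratification, daily summaries,
    inter-pig comparison (Kruskal-Wallis, one-way ANOVA, Shapiro-Wilk),
    an individual-baseline illness indicator, and a synthetic single-pen
    scene simulator with a bimodal diurnal visit schedule and a
    configurable detector-noise model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
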