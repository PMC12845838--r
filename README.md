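# pigsip

Drinking-event detection and behavioural analytics for camera-monitored
pigs.

Singly housed research pigs (e.g. Göttingen minipigs) drink from one or
two fixed wall faucets, and deviations from an individual's normal
drinking pattern are an early indicator of illness. A top-down camera
plus an object detector yields per-frame bounding boxes for pig heads and
water faucets; `pigsip` turns those detection streams into drinking
events and the statistics used to characterise drinking behaviour. It is
for animal-facility and precision-livestock researchers who have (or
simulate) detector output and need the event logic, validation metrics
and analytics — not for training detectors or decoding video.

## The method

Drinking is inferred geometrically, not classified directly:

1. **Faucet localization** — faucet positions are fixed once per session
   from the highest-confidence `Water-Faucet` detections in the first 30
   frames (greedy centroid clustering, radius 5% of the frame diagonal,
   at most two faucets).
2. **Proximity score** — per frame, for each pig-head/faucet centroid
   pair at Euclidean pixel distance *d*,

   *P* = 1 − *d* / *d*<sub>diag</sub>,

   where *d*<sub>diag</sub> is the frame diagonal; *P* = 1 means
   coincident centroids.
3. **Flagging** — a frame is flagged when the best pair reaches
   *P* ≥ 0.98 (16 px on a 640×480 frame).
4. **Segmentation** — maximal flagged runs become events; events shorter
   than 5 s are discarded (brief sniffing at the faucet is not
   drinking). Durations are half-open frame intervals divided by fps.

On top of the events: frame-level confusion metrics and event-level
temporal intersection-over-union against human annotation; hourly
"drinking power" tables (count × mean duration per clock hour),
feeding-hour stratification, per-pig-day summaries, inter-pig tests
(Kruskal–Wallis, one-way ANOVA, Shapiro–Wilk) and a baseline-deviation
illness indicator. A synthetic pen simulator (bimodal diurnal visit
schedule, configurable detector-noise model) generates detection streams
with exact ground truth, so the whole pipeline is testable without video.
See the vignette in `vignettes/drinking-event-detection.Rmd` for the full
model description and design choices.

## Worked example

```r
library(pigsip)

# simulate a noise-free 2 h morning session at 5 fps and detect events
sim    <- simulate_session(hours = 2, fps = 5, seed = 7,
                           session_start = "08:00:00")
events <- detect_events(sim$stream)
nrow(events)
#> [1] 11
events[6, c("faucet_id", "start_clock", "duration_s", "mean_proximity")]
#> # A tibble: 1 × 4
#>   faucet_id start_clock  duration_s mean_proximity
#>       <int> <chr>             <dbl>          <dbl>
#> 1         2 08:23:52.000       81.8          0.995

# noise-free recovery is exact
temporal_concordance(events, sim$events)
#> # A tibble: 1 × 5
#>   overlap_s union_s   iou pred_only_frac truth_only_frac
#>       <dbl>   <dbl> <dbl>          <dbl>           <dbl>
#> 1      209.    209.     1              0               0
```

Eleven visits were injected and all eleven recovered; the IoU of 1 says
the detected and true drinking time coincide second for second. The
shipped reference tables (`minipig_hourly()`, `minipig_daily()`: 18
pig-days from three minipigs) feed the analytics:

```r
pt <- power_table(minipig_hourly())
glance(pt)
#> # A tibble: 1 × 4
#>   n_hours total_events total_power_s overall_mean_s
#>     <int>        <dbl>         <dbl>          <dbl>
#> 1      13          612        25360.           41.4

stratify_power(pt)
#> # A tibble: 3 × 5
#>   set         n_hours hours                 mean_pct_power relative_power_pct
#>   <chr>         <int> <chr>                          <dbl>              <dbl>
#> 1 feeding           5 8,9,13,14,15                   10.9               142.
#> 2 non_feeding       8 6,7,10,11,12,16,17,18           5.69               73.9
#> 3 all              13 6,7,8,9,10,11,12,...            7.69              100

glance(compare_pigs(minipig_daily(), value = n_events, group = pig))
#> # A tibble: 1 × 7
#>   n_groups n_total  kw_H    kw_p anova_F anova_p min_shapiro_p
#>      <int>   <int> <dbl>   <dbl>   <dbl>   <dbl>         <dbl>
#> 1        3      18  11.8 0.00274    6.97 0.00722       0.00908
```

The 612 events carry 25,360 s of total drinking power at a 41.4 s mean
duration; feeding-related hours hold 10.9% of the day's power per hour
against 5.7% in the other lit hours (142% vs 74% of the all-hours mean),
and the three pigs differ significantly in daily event counts
(H = 11.8, p = 0.003), with one pig's counts clearly non-normal — which
is why the rank test is the preferred comparison.

A thin command-line wrapper over the same functions ships at
`inst/cli/pigsip.R` (`simulate`, `detect-events`, `validate`,
`summarize`, `power`, `stats`, `illness`).

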