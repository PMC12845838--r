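---
title: "Proximity-based drinking-event detection and behavioural analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity-based drinking-event detection and behavioural analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigsip)
```

## The problem

Singly housed research pigs (typically Göttingen minipigs) drink from one
or two wall-mounted nipple faucets, and changes in their drinking pattern
are an early, non-invasive indicator of illness. A fixed top-down camera
with an object detector provides, per video frame, a set of labelled
bounding boxes — pig head, water faucet, posture classes, keeper, feces.
`pigsip` turns such per-frame detection streams into drinking events and
the behavioural statistics built on them. It is detector-agnostic: any
model that emits the six-class vocabulary in the supported JSONL/CSV
dialects can feed the pipeline.

## The detection model

Drinking is not a class the detector predicts; it is inferred from
geometry in four steps.

**1. Faucet localization.** Faucets do not move, so their positions are
fixed once per session from the `Water-Faucet` detections in the first 30
frames. Detections are greedily clustered by centroid distance
(radius 5% of the frame diagonal, visiting detections in descending
confidence order so each cluster is represented by its most confident
box), clusters are ranked by that confidence, and at most two are kept.
A session with no faucet detection in the window cannot be monitored and
fails loudly. The 30-frame window and two-faucet cap are configurable;
the clustering radius is a package choice — repeated detections of one
physical faucet jitter by a few pixels, far less than 5% of the diagonal,
while two real faucets sit much further apart.

**2. Centroids.** Each box contributes its exact geometric centre
$(x_c, y_c) = ((x_1+x_2)/2,\,(y_1+y_2)/2)$, kept real-valued.

**3. Proximity score.** For a head centroid at Euclidean pixel distance
$d$ from a faucet centroid,

$$P = 1 - \frac{d}{d_\mathrm{diag}},$$

where $d_\mathrm{diag}$ is the frame diagonal. $P = 1$ means coincident
centroids; for centroids inside the frame $P \in [0, 1]$, and $P$ is
strictly decreasing in $d$. Normalising by the diagonal makes the score,
and the threshold below, independent of resolution.

**4. Flagging and segmentation.** A frame is flagged when the best
head–faucet pair reaches $P \ge 0.98$ — on a 640×480 frame (diagonal
800 px) that is a 16 px centroid distance. The comparison is inclusive:
the published constant should itself count as a detection, and a
boundary-exact case must behave deterministically. Maximal runs of
flagged frames become candidate events (`max_gap_frames` can bridge
single-frame dropouts, but defaults to 0: a drinking visit is a
continuous sequence); candidates shorter than 5 s are discarded, because
a pig sniffing past the faucet produces brief proximity without
meaningful water intake. Durations use half-open frame intervals,
`duration = (end_frame - start_frame) / fps`, and each event is
attributed to the faucet with the highest mean $P$ over its flagged
frames, ties to the lower faucet id.

With several heads detected in one frame (single-pig pens, but real
detectors emit duplicates) the frame-level maximum over pairs is used;
there is no identity tracking. The frame cadence is the caller's choice:
the pipeline is exact at any `fps`, and `downsample_frames()` reproduces
the reduced-rate regime (stride 18 on 25 fps ≈ 1.39 fps) used when
aligning long sessions with human annotation.

## Validation metrics

`frame_confusion()` compares predicted and annotated per-frame binary
tracks (accuracy, precision, recall, F1). A degenerate track with zero
predicted positives reports precision 0 with a warning instead of `NaN`,
so batch validation never crashes. `temporal_concordance()` works at the
event level: each side's intervals are unioned first, then the
intersection-over-union of total drinking time is reported, together
with the model-only and truth-only fractions of the union. The minimum
duration filter is applied to both sides before comparison. Both metrics
are checked in the test suite against independent oracles — a
frame-by-frame scan for segmentation and a per-millisecond rasterization
for interval IoU (agreement to 1e-9 on sessions up to an hour).

## Behavioural characterisation

All analytics operate on plain event tibbles and are aggregated per clock
hour or per pig-day:

* **Hourly summaries** bin events by the clock hour of their start; an
  event spanning a boundary counts wholly in its start hour (binning by
  start is the only choice that keeps counts integral, and at
  tens-of-seconds durations the distortion is negligible).
* **Drinking power** per hour is `count × mean duration` (seconds), a
  combined frequency–duration load measure; each hour's share of total
  power, and the overall mean duration `total power / total events`, are
  exposed via `glance()`. Power is always recomputed from count and mean
  rather than taken from any pre-tabulated power column, which also
  makes the table self-consistent under rounding of the inputs.
* **Feeding-hour stratification** contrasts the mean hourly power share
  of feeding-related hours (defaults {8, 9} and {13, 14, 15}, following
  feeds around 07:00 and 13:00) against the remaining lit hours and the
  all-hours reference (which is `100 / number of observed hours` by
  construction).
* **Daily summaries and descriptive statistics** use the *population*
  (denominator *n*) standard deviation throughout: a fixed six-day
  monitoring block is summarised as a complete period, not as a sample
  from a longer run.
* **Inter-pig comparison** (`compare_pigs()`) bundles per-group
  Shapiro–Wilk checks, the Kruskal–Wallis rank test (preferred when any
  group departs from normality) and classical equal-variance one-way
  ANOVA. These are standard procedures and are delegated to the stats
  routines (`kruskal.test`, `oneway.test(var.equal = TRUE)`,
  `shapiro.test`) behind contract-checking fronts; the test suite
  re-derives the tie-corrected H statistic from its defining formula as
  an independent oracle.
* **Illness indicator.** Each pig acts as its own control: from a
  designated healthy window (at least 3 days) a baseline median $m_b$
  and population sd $s_b$ are estimated, and a later day is flagged when
  `|count − m_b| > k·s_b` (absolute mode, default `k = 2`) or
  `|count − m_b| > r·m_b` (relative mode, default `r = 0.4`). Both modes
  exist because the two published phrasings of the rule are mutually
  inconsistent; neither is asserted as the canonical one, and the
  defaults follow the prose (two baseline standard deviations, or a 40%
  excursion). Note that with very short baselines the estimated $s_b$
  is noisy and systematically small, which inflates the false-flag rate
  well above its asymptotic level (simulations in the test suite use a
  two-week baseline, where a stationary Poisson day-count process flags
  under 10% of healthy days at `k = 2`; Chebyshev alone guarantees 25%).

## The synthetic pen simulator

No public detection streams of this kind exist, so `pen_scene()`,
`sample_visit_schedule()` and `render_stream()` generate them. The
generator is first-class, tested code — every pipeline stage is exercised
against it.

* **Scene.** 640×480 px, 25 fps by default, session start 06:30 (lights
  on), one or two fixed faucet boxes slightly inside the pen wall (so the
  larger head box stays within frame when the pig drinks), head box 12%
  of frame width. No published head-box dimensions exist; the fraction is
  configurable.
* **Schedule.** Visit starts follow an inhomogeneous Poisson process
  with a bimodal hourly intensity (peaks 08:00–10:00 and 14:00–16:00
  inside the 06:30–18:30 lit window, ~38 expected visits per 12 h day),
  thinned to prevent overlap. Durations are lognormal (median 25 s,
  mean ≈ 37 s) with a floor of 6 s — just above the 5 s event filter, so
  noise-free schedules survive filtering intact and recovery is exact.
  Visits optionally never cross an hour boundary (the default), which
  makes hourly-binning tests exact.
* **Rendering.** During a visit the head centroid sits within 1% of the
  diagonal of the visited faucet ($P \ge 0.99$); between visits a
  bounded random walk (steps 2% of the diagonal, an arbitrary,
  configurable plausibility choice) is folded into the pen and kept at
  least 5% of the diagonal from every faucet ($P \le 0.95$). The head
  repositions to the faucet between consecutive frames rather than along
  a modelled approach path: an approach path would cross the threshold
  shortly before the scheduled start and blur event boundaries, whereas
  the jump construction makes the noise-free flag track *identical* to
  the ground truth, which is what the recovery invariants require.
  Returned true events are quantised to the frame grid for the same
  reason.
* **Noise.** Head misses, Gaussian box jitter, spurious low-confidence
  detections (feces or phantom pig heads, echoing the background
  confusions typical of pen detectors), and faucet misses during the
  localization window. Confidences are Beta-distributed (true boxes
  Beta(20, 2), spurious Beta(2, 5)) so confidence-ranked faucet
  localization is genuinely exercised. The zero-noise configuration is
  the default and the reference condition: under it the pipeline must —
  and in the test suite does — reproduce the injected visits exactly
  (IoU 1.0, frame accuracy 1.0).

What the simulator does **not** emulate: occlusion structure, correlated
miss bursts, multi-pig interaction, camera motion, lens distortion, or
any appearance-level property. Passing the recovery tests therefore
demonstrates the correctness of the event logic and analytics, not the
performance of any real detector on real video; published headline
accuracies from multi-day recordings cannot be reproduced without the
original footage and are out of scope here.

## Problem sizes and numerical choices

The suite and the acceptance script run synthetic sessions of 0.5–6 h at
2–5 fps (up to ~10^5 frames), which exercise every code path at full
fidelity — the pipeline is cadence-exact, so higher frame rates change
cost, not behaviour. Proximity is computed in double precision with no
rounding anywhere in the pipeline; table-style rounding (durations and
power to 1 decimal, percentages to 2) is applied only in reproduction
tests against printed reference values, never internally. Interval
endpoints are half-open throughout, which makes unions, intersections
and frame counts exact without epsilon handling; the only tolerance in
the package is the 1e-9 agreement demanded of the rasterization oracle.

## Known limitations

Proximity is an indirect measure: a pig resting with its head at the
faucet is indistinguishable from one drinking, and water volume is not
estimated. Events are attributed to a faucet but pigs are not identified
across pens. The frame-confusion and concordance metrics assume a single
annotation track per stream. The reference tables shipped in
`inst/extdata` contain two internal inconsistencies inherited from their
source (one hour's pre-tabulated power cell disagrees with its own count
× mean — the package always recomputes; and one summary row mixing group
means into a median column); both are documented in the tests and
excluded from reproduction checks.
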