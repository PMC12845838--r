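#' Synthetic single-pen scene
#'
#' Describes the fixed geometry a top-down pen camera sees: frame size,
#' frame rate, session start clock time, one or two wall-mounted faucet
#' boxes, and the size of the moving pig-head box. Every pipeline stage
#' can be exercised against streams rendered from such a scene, with no
#' video involved.
#'
#' @param frame_width,frame_height Frame size in pixels (default
#'   640 x 480, diagonal 800).
#' @param fps Frames per second of the rendered stream.
#' @param session_start Clock time of frame 0 (lights-on is 06:30 in the
#'   emulated facility).
#' @param n_faucets 1 or 2 fixed faucets on the left pen wall.
#' @param head_size_frac Width of the pig-head box as a fraction of the
#'   frame width (the head box is always much smaller than the pen).
#' @param pen_id Identifier stamped on rendered streams.
#' @return A `pen_scene` list: `faucets` (tibble of boxes with
#'   centroids), `head_w`, `head_h`, plus the scene metadata as
#'   attributes.
#' @export
pen_scene <- function(frame_width = 640, frame_height = 480, fps = 25,
                      session_start = "06:30:00", n_faucets = 2,
                      head_size_frac = 0.12, pen_id = "pig1") {
  stopifnot(n_faucets %in% c(1, 2))
  fw <- 0.05 * frame_width
  fh <- 0.09 * frame_height
  ys <- if (n_faucets == 2) c(0.3, 0.65) else 0.45
  # faucets sit a little inside the pen wall so the (larger) head box
  # still fits the frame when the head is at a faucet
  faucets <- tibble(
    faucet_id = seq_len(n_faucets),
    x1 = 0.08 * frame_width,
    y1 = ys * frame_height,
    x2 = 0.08 * frame_width + fw,
    y2 = ys * frame_height + fh
  )
  faucets <- dplyr::bind_cols(faucets, box_centroid(faucets))
  head_w <- head_size_frac * frame_width
  head_h <- 0.75 * head_w
  structure(
    list(faucets = faucets, head_w = head_w, head_h = head_h),
    class = "pen_scene",
    frame_width = frame_width, frame_height = frame_height,
    fps = fps, session_start_s = parse_clock(session_start),
    pen_id = pen_id
  )
}

#' Bimodal diurnal visit intensity
#'
#' Default hourly drinking-visit intensity (expected visits per clock
#' hour) emulating the diurnal pattern of singly housed pigs under a
#' 06:30-18:30 light cycle with feeds around 07:00 and 13:00: a morning
#' peak around 08:00-10:00, an afternoon peak around 14:00-16:00, and no
#' activity in the dark hours. The default totals ~38 expected visits per
#' 12 h day, matching the tens-of-events-per-day scale seen in single-pen
#' monitoring.
#'
#' @return Numeric vector of length 24, indexed by clock hour 0-23.
#' @export
bimodal_lambda <- function() {
  lambda <- numeric(24)
  lambda[7:19] <- c(0.5, 2, 4, 4, 3.5, 2.5, 2.5, 3, 4.5, 5, 4, 2, 0.5)
  lambda
}

#' Detector noise model for rendered streams
#'
#' Emulates the error structure of a real-time object detector: missed
#' head detections, pixel jitter on box corners, spurious low-confidence
#' detections (drawn from the classes a pen background is typically
#' confused with: feces and pig heads), and missed faucet detections
#' during the localization window. The all-zero default renders a
#' noise-free stream, the reference condition for recovery tests.
#'
#' @param head_miss_prob Probability a frame's head detection is dropped.
#' @param jitter_sd Gaussian pixel jitter applied to box centroids and
#'   sizes.
#' @param spurious_rate Per-frame probability of one spurious detection.
#' @param faucet_miss_prob Probability a faucet detection is dropped in
#'   the localization window.
#' @param conf_shape1,conf_shape2 Beta parameters of true-detection
#'   confidences (default Beta(20, 2), mean ~0.91).
#' @param spurious_conf_shape1,spurious_conf_shape2 Beta parameters of
#'   spurious-detection confidences (default Beta(2, 5), low).
#' @return A `noise_model` list.
#' @export
noise_model <- function(head_miss_prob = 0, jitter_sd = 0,
                        spurious_rate = 0, faucet_miss_prob = 0,
                        conf_shape1 = 20, conf_shape2 = 2,
                        spurious_conf_shape1 = 2, spurious_conf_shape2 = 5) {
  probs <- c(head_miss_prob, spurious_rate, faucet_miss_prob)
  if (any(probs < 0 | probs > 1) || jitter_sd < 0) {
    abort("noise probabilities must lie in [0, 1] and jitter_sd >= 0",
          class = c("pigsip_error_contract", "pigsip_error"))
  }
  structure(
    list(head_miss_prob = head_miss_prob, jitter_sd = jitter_sd,
         spurious_rate = spurious_rate, faucet_miss_prob = faucet_miss_prob,
         conf_shape1 = conf_shape1, conf_shape2 = conf_shape2,
         spurious_conf_shape1 = spurious_conf_shape1,
         spurious_conf_shape2 = spurious_conf_shape2),
    class = "noise_model"
  )
}

#' Sample a diurnal drinking-visit schedule
#'
#' Visit start times follow an inhomogeneous Poisson process with the
#' hourly intensity `lambda`, thinned so visits never overlap (a pig
#' cannot start a second visit during one); durations are lognormal with
#' a configurable floor. Visits optionally never span a clock-hour
#' boundary, which makes hourly-binning tests exact.
#'
#' @param hours Session length in hours.
#' @param lambda Length-24 hourly intensity (expected visits per clock
#'   hour); default [bimodal_lambda()].
#' @param session_start Clock time of session second 0.
#' @param duration_meanlog,duration_sdlog Lognormal duration parameters
#'   (default `log(25)` and 0.9: median 25 s, mean ~37 s, matching the
#'   tens-of-seconds drinking bouts of adult minipigs).
#' @param min_duration_s Duration floor in seconds (default 6, just above
#'   the 5 s event filter so noise-free schedules survive it intact).
#' @param n_faucets Number of faucets visits are assigned to.
#' @param gap_s Minimum gap enforced between consecutive visits.
#' @param avoid_hour_boundaries Truncate visits at clock-hour boundaries
#'   (dropping any that fall below the floor), so each visit lies wholly
#'   in its start hour.
#' @param seed Optional RNG seed.
#' @return A `visit_schedule` tibble: `start_s`, `end_s`, `duration_s`
#'   (session-relative seconds), `faucet_id`; session metadata as
#'   attributes.
#' @export
sample_visit_schedule <- function(hours = 12, lambda = bimodal_lambda(),
                                  session_start = "06:30:00",
                                  duration_meanlog = log(25),
                                  duration_sdlog = 0.9,
                                  min_duration_s = 6, n_faucets = 2,
                                  gap_s = 2, avoid_hour_boundaries = TRUE,
                                  seed = NULL) {
  stopifnot(length(lambda) == 24, all(lambda >= 0))
  if (!is.null(seed)) set.seed(seed)
  start_clock_s <- parse_clock(session_start)
  session_len <- hours * 3600

  # expected count per clock hour, scaled by how much of the hour the
  # session covers
  starts <- numeric(0)
  for (h in 0:23) {
    hour_lo <- h * 3600
    hour_hi <- hour_lo + 3600
    # session window on the clock axis (single day; sessions <= 24 h)
    lo <- max(hour_lo, start_clock_s)
    hi <- min(hour_hi, start_clock_s + session_len)
    if (hi <= lo || lambda[h + 1] == 0) next
    k <- rpois(1, lambda[h + 1] * (hi - lo) / 3600)
    if (k > 0) starts <- c(starts, runif(k, lo, hi) - start_clock_s)
  }
  if (length(starts) == 0) {
    sched <- tibble(start_s = double(), end_s = double(),
                    duration_s = double(), faucet_id = integer())
    return(structure(sched, class = c("visit_schedule", class(sched)),
                     session_start_s = start_clock_s,
                     session_len_s = session_len))
  }
  starts <- sort(starts)
  durations <- pmax(rlnorm(length(starts), duration_meanlog, duration_sdlog),
                    min_duration_s)
  ends <- pmin(starts + durations, session_len)

  if (avoid_hour_boundaries) {
    boundary <- (floor((start_clock_s + starts) / 3600) + 1) * 3600 -
      start_clock_s
    ends <- pmin(ends, boundary)
  }

  keep <- logical(length(starts))
  last_end <- -Inf
  for (i in seq_along(starts)) {
    if (starts[i] >= last_end + gap_s &&
        ends[i] - starts[i] >= min_duration_s) {
      keep[i] <- TRUE
      last_end <- ends[i]
    }
  }
  sched <- tibble(
    start_s = starts[keep],
    end_s = ends[keep],
    duration_s = ends[keep] - starts[keep],
    faucet_id = sample.int(n_faucets, sum(keep), replace = TRUE)
  )
  structure(sched, class = c("visit_schedule", class(sched)),
            session_start_s = start_clock_s, session_len_s = session_len)
}

#' Render a detection stream from a scene and visit schedule
#'
#' Produces what a detector watching the scene would emit, frame by
#' frame: the fixed faucet boxes during the 30-frame localization window,
#' a pig body box and a moving pig-head box every frame, and noise per
#' the [noise_model()]. During a visit the head centroid sits within 1%
#' of the frame diagonal of the visited faucet (proximity >= 0.99);
#' between visits a bounded random walk keeps it at least 5% of the
#' diagonal away from every faucet (proximity <= ~0.95), so the flagging
#' rule separates the two regimes cleanly. The returned ground truth
#' marks exactly the visit frames, and the true events are quantised to
#' the frame grid so a noise-free pipeline run reproduces them exactly.
#'
#' @param scene A [pen_scene()].
#' @param schedule A [sample_visit_schedule()] result (or a tibble with
#'   `start_s`, `end_s`, `faucet_id` in session-relative seconds).
#' @param noise A [noise_model()]; default noise-free.
#' @param session_len_s Session length in seconds; defaults to the
#'   schedule's attribute.
#' @param n_init_frames Number of opening frames carrying faucet
#'   detections.
#' @param seed Optional RNG seed.
#' @return A list: `stream` ([detection_stream()]), `truth` (dense 0/1
#'   frame track), `events` (frame-quantised true-event tibble with
#'   `start_s`, `end_s`, `duration_s`, `faucet_id`), `schedule`.
#' @export
render_stream <- function(scene, schedule, noise = noise_model(),
                          session_len_s = NULL, n_init_frames = 30,
                          seed = NULL) {
  stopifnot(inherits(scene, "pen_scene"))
  if (!is.null(seed)) set.seed(seed)
  fps <- attr(scene, "fps")
  W <- attr(scene, "frame_width")
  H <- attr(scene, "frame_height")
  d_diag <- frame_diagonal(scene)
  session_len_s <- session_len_s %||% attr(schedule, "session_len_s")
  if (is.null(session_len_s)) {
    abort("session_len_s not given and schedule carries no session length",
          class = c("pigsip_error_contract", "pigsip_error"))
  }
  n_frames <- as.integer(round(session_len_s * fps))
  if (nrow(schedule) > 0 &&
      (any(schedule$start_s < 0) || any(schedule$end_s > session_len_s))) {
    abort("visit outside the session window", class = c("pigsip_error_validation", "pigsip_error"))
  }

  hw <- scene$head_w / 2
  hh <- scene$head_h / 2
  t_frame <- (seq_len(n_frames) - 1L) / fps

  # which visit (if any) covers each frame; visits are disjoint
  visit_of <- integer(n_frames)
  truth <- integer(n_frames)
  true_events <- NULL
  if (nrow(schedule) > 0) {
    f0 <- as.integer(ceiling(schedule$start_s * fps - 1e-9))
    f1 <- as.integer(ceiling(schedule$end_s * fps - 1e-9))  # exclusive
    ok <- f1 > f0
    for (i in which(ok)) {
      visit_of[(f0[i] + 1L):f1[i]] <- i
      truth[(f0[i] + 1L):f1[i]] <- 1L
    }
    true_events <- tibble(
      start_s = f0[ok] / fps,
      end_s = f1[ok] / fps,
      duration_s = (f1[ok] - f0[ok]) / fps,
      faucet_id = schedule$faucet_id[ok]
    )
  } else {
    true_events <- tibble(start_s = double(), end_s = double(),
                          duration_s = double(), faucet_id = integer())
  }

  # between-visit trajectory: bounded random walk folded into the pen and
  # pushed out of an exclusion disc around each faucet
  step_sd <- 0.02 * d_diag
  xs <- cumsum(c(W / 2, rnorm(n_frames - 1L, 0, step_sd)))
  ys <- cumsum(c(H / 2, rnorm(n_frames - 1L, 0, step_sd)))
  fold <- function(v, lo, hi) {
    r <- (v - lo) %% (2 * (hi - lo))
    lo + pmin(r, 2 * (hi - lo) - r)
  }
  xs <- fold(xs, hw, W - hw)
  ys <- fold(ys, hh, H - hh)
  excl_r <- 0.05 * d_diag
  for (j in seq_len(nrow(scene$faucets))) {
    fx <- scene$faucets$xc[j]
    fy <- scene$faucets$yc[j]
    d <- sqrt((xs - fx)^2 + (ys - fy)^2)
    inside <- d < excl_r
    if (any(inside)) {
      scale <- excl_r / pmax(d[inside], 1e-6)
      xs[inside] <- fx + (xs[inside] - fx) * scale
      ys[inside] <- fy + (ys[inside] - fy) * scale
    }
  }
  xs <- pmin(pmax(xs, hw), W - hw)
  ys <- pmin(pmax(ys, hh), H - hh)
  # clamping can drag a pushed point back towards a wall-mounted faucet;
  # re-park such frames on the pen-interior side of the exclusion disc
  for (j in seq_len(nrow(scene$faucets))) {
    fx <- scene$faucets$xc[j]
    fy <- scene$faucets$yc[j]
    d <- sqrt((xs - fx)^2 + (ys - fy)^2)
    inside <- d < excl_r - 1e-9
    if (any(inside)) {
      xs[inside] <- fx + excl_r
      ys[inside] <- fy
    }
  }

  # on visit frames the head sits at the faucet (small in-visit wobble)
  at_visit <- visit_of > 0L
  if (any(at_visit)) {
    fid <- schedule$faucet_id[visit_of[at_visit]]
    ang <- runif(sum(at_visit), 0, 2 * pi)
    rad <- runif(sum(at_visit), 0, 0.01 * d_diag)
    xs[at_visit] <- scene$faucets$xc[fid] + rad * cos(ang)
    ys[at_visit] <- scene$faucets$yc[fid] + rad * sin(ang)
  }

  head_det <- tibble(
    frame = seq_len(n_frames) - 1L,
    label = "Pig-Head",
    conf = rbeta(n_frames, noise$conf_shape1, noise$conf_shape2),
    x1 = xs - hw, y1 = ys - hh, x2 = xs + hw, y2 = ys + hh
  )
  if (noise$head_miss_prob > 0) {
    head_det <- head_det[runif(n_frames) >= noise$head_miss_prob, ]
  }

  body_det <- tibble(
    frame = seq_len(n_frames) - 1L,
    label = "Pig-Standing",
    conf = rbeta(n_frames, noise$conf_shape1, noise$conf_shape2),
    x1 = pmax(xs - 2.2 * hw, 0), y1 = pmax(ys - 2.2 * hh, 0),
    x2 = pmin(xs + 2.2 * hw, W), y2 = pmin(ys + 2.2 * hh, H)
  )

  n_init <- min(n_init_frames, n_frames)
  faucet_det <- tidyr::expand_grid(
    frame = seq_len(n_init) - 1L,
    faucet_id = scene$faucets$faucet_id
  ) %>%
    left_join(select(scene$faucets, faucet_id, x1, y1, x2, y2),
              by = "faucet_id") %>%
    mutate(label = "Water-Faucet",
           conf = rbeta(dplyr::n(), noise$conf_shape1, noise$conf_shape2)) %>%
    select(frame, label, conf, x1, y1, x2, y2)
  if (noise$faucet_miss_prob > 0) {
    faucet_det <- faucet_det[runif(nrow(faucet_det)) >= noise$faucet_miss_prob, ]
  }

  spurious_det <- NULL
  if (noise$spurious_rate > 0) {
    sp_frames <- which(runif(n_frames) < noise$spurious_rate) - 1L
    if (length(sp_frames) > 0) {
      k <- length(sp_frames)
      sw <- hw
      sh <- hh
      sx <- runif(k, sw, W - sw)
      sy <- runif(k, sh, H - sh)
      spurious_det <- tibble(
        frame = sp_frames,
        label = sample(c("Feces", "Pig-Head"), k, replace = TRUE,
                       prob = c(2 / 3, 1 / 3)),
        conf = rbeta(k, noise$spurious_conf_shape1, noise$spurious_conf_shape2),
        x1 = sx - sw, y1 = sy - sh, x2 = sx + sw, y2 = sy + sh
      )
    }
  }

  detections <- bind_rows(head_det, body_det, faucet_det, spurious_det)

  if (noise$jitter_sd > 0) {
    k <- nrow(detections)
    jx <- rnorm(k, 0, noise$jitter_sd)
    jy <- rnorm(k, 0, noise$jitter_sd)
    js <- abs(rnorm(k, 0, noise$jitter_sd / 2))
    detections <- detections %>%
      mutate(
        x1 = pmin(pmax(x1 + jx - js, 0), W - 2),
        y1 = pmin(pmax(y1 + jy - js, 0), H - 2),
        x2 = pmax(pmin(x2 + jx + js, W), x1 + 1),
        y2 = pmax(pmin(y2 + jy + js, H), y1 + 1)
      )
  }

  stream <- detection_stream(
    arrange(detections, frame),
    frame_width = W, frame_height = H, fps = fps,
    session_start = attr(scene, "session_start_s"),
    n_frames = n_frames,
    pen_id = attr(scene, "pen_id")
  )
  list(stream = stream, truth = truth, events = true_events,
       schedule = schedule)
}

#' Simulate a full monitoring session
#'
#' Convenience wrapper: sample a diurnal visit schedule and render the
#' detection stream in one seeded call.
#'
#' @inheritParams sample_visit_schedule
#' @inheritParams render_stream
#' @param fps Frames per second of the rendered stream.
#' @param scene Optional [pen_scene()]; by default one is built with
#'   `fps` and `session_start`.
#' @param ... Further arguments to [sample_visit_schedule()].
#' @return As [render_stream()].
#' @examples
#' sim <- simulate_session(hours = 0.5, fps = 5, seed = 42)
#' nrow(sim$events)
#' @export
simulate_session <- function(hours = 12, fps = 25,
                             session_start = "06:30:00", scene = NULL,
                             noise = noise_model(), seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  scene <- scene %||% pen_scene(fps = fps, session_start = session_start)
  schedule <- sample_visit_schedule(hours = hours,
                                    session_start = session_start,
                                    n_faucets = nrow(scene$faucets), ...)
  render_stream(scene, schedule, noise = noise)
}
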