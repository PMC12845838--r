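test_that("box centroids are exact midpoints, without integer truncation", {
  expect_equal(box_centroid(c(0, 0, 10, 10)), tibble::tibble(xc = 5, yc = 5))
  expect_equal(box_centroid(c(2, 4, 6, 8)), tibble::tibble(xc = 4, yc = 6))
  expect_equal(box_centroid(c(0, 0, 1, 1)), tibble::tibble(xc = 0.5, yc = 0.5))
})

test_that("proximity is diagonal-normalised and strictly decreasing in distance", {
  expect_equal(proximity_score(c(100, 100), c(100, 100), 800), 1.0)
  expect_equal(proximity_score(c(320, 240), c(320, 256), 800), 0.98)
  expect_equal(proximity_score(c(0, 0), c(640, 480), 800), 0.0)
  expect_error(proximity_score(c(0, 0), c(1, 1), 0),
               class = "pigsip_error_contract")

  d <- sort(runif(50, 0, 800))
  p <- proximity_score(tibble::tibble(xc = d, yc = 0),
                       tibble::tibble(xc = 0, yc = 0), 800)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("faucet localization fixes the highest-confidence box per cluster", {
  # one faucet seen on every init frame, confidence peaking on frame 7
  conf <- 0.80 + 0.01 * (0:29 %% 14)
  conf[8] <- 0.93  # frame 7
  one <- purrr::map_dfr(0:29, function(f) {
    box_at(f, "Water-Faucet", conf[f + 1], 60 + (f %% 3), 150 - (f %% 2))
  })
  fm <- localize_faucets(make_stream(one, n_frames = 40))
  expect_equal(nrow(fm), 1L)
  expect_equal(fm$conf, 0.93)
  expect_equal(fm$xc, 60 + 7 %% 3)  # frame 7's box
  expect_equal(fm$n_detections, 30L)

  # three well-separated clusters: the two strongest are kept, in rank order
  three <- dplyr::bind_rows(
    box_at(0, "Water-Faucet", 0.9, 60, 150),
    box_at(0, "Water-Faucet", 0.8, 60, 350),
    box_at(1, "Water-Faucet", 0.85, 62, 151),
    box_at(2, "Water-Faucet", 0.4, 400, 240)
  )
  fm <- localize_faucets(make_stream(three, n_frames = 30))
  expect_equal(nrow(fm), 2L)
  expect_equal(fm$conf, c(0.9, 0.8))
  expect_equal(fm$faucet_id, c(1L, 2L))
  expect_equal(fm$yc, c(150, 350))

  # detections beyond the init window are ignored
  late <- dplyr::bind_rows(three, box_at(35, "Water-Faucet", 0.99, 500, 100))
  fm2 <- localize_faucets(make_stream(late, n_frames = 60))
  expect_equal(fm2$conf, c(0.9, 0.8))

  # no faucets at all: monitoring cannot start
  heads <- box_at(0:29, "Pig-Head", 0.9, 300, 200)
  expect_error(localize_faucets(make_stream(heads, n_frames = 30)),
               class = "pigsip_error_localization")

  # short stream: all frames used, with a warning
  expect_warning(
    localize_faucets(make_stream(box_at(0, "Water-Faucet", 0.9, 60, 150),
                                 n_frames = 5)),
    "fewer")
})

test_that("frame flagging takes the per-frame max over head-faucet pairs, inclusive at the threshold", {
  faucet <- box_at(0, "Water-Faucet", 0.9, 320, 240)
  # d = 16 px on a 800 px diagonal: P = 0.98 exactly -> flagged (inclusive)
  # d = 20 px: P = 0.975 -> unflagged
  dets <- dplyr::bind_rows(
    faucet,
    box_at(0, "Pig-Head", 0.9, 320, 256, half = 30),   # P = 0.98
    box_at(1, "Pig-Head", 0.9, 320, 260, half = 30),   # P = 0.975
    box_at(2, "Pig-Head", 0.9, 320, 260, half = 30),   # duplicate heads:
    box_at(2, "Pig-Head", 0.8, 320, 248, half = 30),   # best P = 0.99
    box_at(3, "Keeper", 0.9, 320, 240, half = 30)      # not a head
  )
  flags <- flag_frames(make_stream(dets, n_frames = 5),
                       localize_faucets(make_stream(dets, n_frames = 5),
                                        n_init_frames = 5))
  expect_equal(flags$flagged, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(flags$proximity[1], 0.98)
  expect_equal(flags$proximity[3], 0.99)
  expect_true(is.na(flags$proximity[4]))  # Keeper ignored
  expect_true(is.na(flags$proximity[5]))  # no detections at all
})

test_that("event segmentation applies the run, gap and minimum-duration rules", {
  # 150 consecutive flagged frames at 25 fps -> one 6 s event, kept
  ev <- segment_events(manual_flags(rep(TRUE, 150)), fps = 25)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 6.0)
  expect_equal(c(ev$start_frame, ev$end_frame), c(0L, 150L))

  # 100 frames -> 4 s, discarded by the 5 s rule
  expect_equal(nrow(segment_events(manual_flags(rep(TRUE, 100)), fps = 25)), 0L)

  # two 200-frame runs split by one unflagged frame: two events at gap 0,
  # one merged event at gap 1
  track <- c(rep(TRUE, 200), FALSE, rep(TRUE, 200))
  expect_equal(nrow(segment_events(manual_flags(track), fps = 25)), 2L)
  merged <- segment_events(manual_flags(track), fps = 25, max_gap_frames = 1)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$duration_s, 401 / 25)

  # empty track
  expect_equal(nrow(segment_events(manual_flags(logical(10)), fps = 25)), 0L)

  # faucet attribution goes to the highest mean proximity, ties to lower id
  flags <- manual_flags(rep(TRUE, 150),
                        proximity = c(rep(0.985, 75), rep(0.995, 75)),
                        faucet_id = c(rep(1L, 75), rep(2L, 75)))
  ev <- segment_events(flags, fps = 25)
  expect_equal(ev$faucet_id, 2L)
  expect_equal(ev$max_proximity, 0.995)
  expect_equal(ev$mean_proximity, 0.99)
})

test_that("segmentation matches a brute-force frame scan on random tracks", {
  set.seed(401)
  for (rep in 1:40) {
    n <- sample(50:2000, 1)
    p_flag <- runif(1, 0.05, 0.9)
    track <- runif(n) < p_flag
    fps <- sample(c(5, 10, 25), 1)
    min_dur <- sample(c(0.2, 1, 5), 1)
    gap <- sample(0:3, 1)
    got <- segment_events(manual_flags(track, fps = fps), fps = fps,
                          min_duration_s = min_dur, max_gap_frames = gap)
    want <- brute_segment(track, fps = fps, min_duration_s = min_dur,
                          max_gap_frames = gap)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
  }
})

test_that("events are disjoint, ordered, and composed of flagged frames", {
  set.seed(77)
  track <- runif(3000) < 0.6
  flags <- manual_flags(track, fps = 25)
  ev <- segment_events(flags, fps = 25, min_duration_s = 0.2)
  if (nrow(ev) > 1) {
    expect_true(all(diff(ev$start_frame) > 0))
    expect_true(all(ev$start_frame[-1] >= ev$end_frame[-nrow(ev)]))
  }
  for (i in seq_len(nrow(ev))) {
    expect_true(all(track[(ev$start_frame[i] + 1):ev$end_frame[i]]))
  }
})

test_that("raising the threshold never increases flagged frames", {
  sim <- simulate_session(hours = 1, fps = 5, seed = 5,
                          noise = noise_model(jitter_sd = 4,
                                              spurious_rate = 0.1))
  faucets <- localize_faucets(sim$stream)
  counts <- vapply(c(0.9, 0.95, 0.98, 0.99),
                   function(th) sum(flag_frames(sim$stream, faucets,
                                                threshold = th)$flagged),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the pipeline recovers injected visits exactly at zero noise", {
  scene <- pen_scene(fps = 5)
  schedule <- tibble::tibble(
    start_s = c(10, 40, 80, 130, 200),
    end_s = c(10, 40, 80, 130, 200) + c(8, 6.5, 12, 7, 20),
    duration_s = c(8, 6.5, 12, 7, 20),
    faucet_id = c(1L, 2L, 1L, 1L, 2L)
  )
  sim <- render_stream(scene, schedule, session_len_s = 300, seed = 31)
  ev <- detect_events(sim$stream)
  expect_equal(nrow(ev), 5L)
  # boundaries within one frame of the injected truth
  expect_true(all(abs(ev$start_s - schedule$start_s) <= 1 / 5 + 1e-9))
  expect_true(all(abs(ev$end_s - schedule$end_s) <= 1 / 5 + 1e-9))
  # localization ranks faucets by confidence, so map detected ids back to
  # scene faucets by centroid before comparing attribution
  fm <- localize_faucets(sim$stream)
  to_scene <- vapply(seq_len(nrow(fm)), function(i) {
    which.min((scene$faucets$xc - fm$xc[i])^2 + (scene$faucets$yc - fm$yc[i])^2)
  }, integer(1))
  expect_equal(to_scene[ev$faucet_id], schedule$faucet_id)

  # a pig that never approaches the faucet produces no events
  idle <- render_stream(scene, schedule[0, ], session_len_s = 120, seed = 32)
  expect_equal(nrow(detect_events(idle$stream)), 0L)

  # a single 3 s visit is killed by the minimum-duration filter,
  # though its frames are flagged
  short <- render_stream(scene,
                         tibble::tibble(start_s = 20, end_s = 23,
                                        duration_s = 3, faucet_id = 1L),
                         session_len_s = 60, seed = 33)
  faucets <- localize_faucets(short$stream)
  expect_gt(sum(flag_frames(short$stream, faucets)$flagged), 0)
  expect_equal(nrow(detect_events(short$stream)), 0L)
})
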