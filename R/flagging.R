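#' Flag frames where a pig head is at a faucet
#'
#' Per frame, the proximity score [proximity_score()] is evaluated for
#' every (Pig-Head, faucet) pair and the frame keeps its best pair. A
#' frame is flagged when that best score reaches the threshold
#' (`P >= threshold`, inclusive, so the printed constant 0.98 is itself a
#' flagging score). Frames with no Pig-Head detection are unflagged;
#' detections of other classes are ignored. With several heads in a frame
#' (single-pig pens, but detectors emit duplicates) the frame-level max
#' over pairs is used — no identity tracking. Ties between faucets break
#' towards the lower `faucet_id`.
#'
#' @param stream A [detection_stream()].
#' @param faucets A `faucet_map` from [localize_faucets()].
#' @param threshold Proximity threshold in (0, 1); default 0.98.
#' @return A tibble with one row per frame: `frame`, `flagged` (logical),
#'   `proximity` (best P, `NA` when no head), `faucet_id` (best faucet,
#'   `NA` when no head). Attributes `fps` and `session_start_s` are
#'   carried over from the stream.
#' @export
flag_frames <- function(stream, faucets, threshold = 0.98) {
  stopifnot(inherits(stream, "detection_stream"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1)", class = c("pigsip_error_contract", "pigsip_error"))
  }
  d_diag <- attr(faucets, "d_diag") %||% frame_diagonal(stream)
  n_frames <- attr(stream, "n_frames")

  heads <- as_tibble(stream) %>%
    filter(label == "Pig-Head") %>%
    dplyr::bind_cols(box_centroid(.)) %>%
    select(frame, head_xc = xc, head_yc = yc)

  grid <- tibble(frame = seq_len(n_frames) - 1L)
  if (nrow(heads) == 0) {
    best <- grid %>%
      mutate(proximity = NA_real_, faucet_id = NA_integer_, flagged = FALSE)
  } else {
    pairs <- heads %>%
      cross_join(select(as_tibble(faucets), faucet_id,
                        faucet_xc = xc, faucet_yc = yc)) %>%
      mutate(proximity = 1 - sqrt((head_xc - faucet_xc)^2 +
                                  (head_yc - faucet_yc)^2) / d_diag)
    best <- pairs %>%
      arrange(frame, desc(proximity), faucet_id) %>%
      distinct(frame, .keep_all = TRUE) %>%
      select(frame, proximity, faucet_id) %>%
      left_join(x = grid, y = ., by = "frame") %>%
      mutate(flagged = !is.na(proximity) & proximity >= threshold)
  }
  structure(
    best[c("frame", "flagged", "proximity", "faucet_id")],
    fps = attr(stream, "fps"),
    session_start_s = attr(stream, "session_start_s"),
    pen_id = attr(stream, "pen_id")
  )
}

#' Segment flagged frames into drinking events
#'
#' A drinking event is a maximal run of consecutive flagged frames
#' interpreted as one visit to a faucet. Runs separated by at most
#' `max_gap_frames` unflagged frames are merged (default 0: strictly
#' continuous); candidate events shorter than `min_duration_s` are
#' discarded — brief proximity such as sniffing past the faucet does not
#' permit meaningful water intake. Frame intervals are half-open
#' `[start_frame, end_frame)` and `duration_s = (end_frame - start_frame)
#' / fps`. Each event is attributed to the faucet with the highest mean
#' proximity over its flagged frames (ties to the lower `faucet_id`).
#'
#' @param flags Per-frame flag tibble from [flag_frames()] (columns
#'   `frame`, `flagged`, `proximity`, `faucet_id`).
#' @param fps Frames per second; defaults to the `fps` attribute of
#'   `flags`.
#' @param min_duration_s Minimum event duration in seconds (default 5).
#' @param max_gap_frames Longest unflagged gap bridged inside one event
#'   (default 0).
#' @param session_start Clock time of frame 0 (`"HH:MM:SS"` or seconds);
#'   defaults to the attribute carried on `flags`.
#' @param pen_id Pen identifier stamped on each event.
#' @return Tibble of events ordered by start time: `event_id`, `pen_id`,
#'   `faucet_id`, `start_frame`, `end_frame`, `start_s`, `end_s`,
#'   `duration_s`, `start_clock`, `mean_proximity`, `max_proximity`.
#' @export
segment_events <- function(flags, fps = NULL, min_duration_s = 5,
                           max_gap_frames = 0, session_start = NULL,
                           pen_id = NULL) {
  fps <- fps %||% attr(flags, "fps")
  if (is.null(fps) || fps <= 0) {
    abort("fps must be positive", class = c("pigsip_error_contract", "pigsip_error"))
  }
  session_start_s <- parse_clock(session_start %||%
                                   attr(flags, "session_start_s") %||% 0)
  pen_id <- pen_id %||% attr(flags, "pen_id") %||% NA_character_

  empty <- tibble(
    event_id = integer(), pen_id = character(), faucet_id = integer(),
    start_frame = integer(), end_frame = integer(), start_s = double(),
    end_s = double(), duration_s = double(), start_clock = character(),
    mean_proximity = double(), max_proximity = double()
  )
  flagged <- flags$flagged
  if (length(flagged) == 0 || !any(flagged)) return(empty)

  r <- rle(flagged)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L  # 1-based positions into flags
  runs <- tibble(start = run_start[r$values], end = run_end[r$values])

  # merge runs across short unflagged gaps
  if (nrow(runs) > 1 && max_gap_frames > 0) {
    gap <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
    grp <- cumsum(c(0L, as.integer(gap > max_gap_frames)))
    runs <- runs %>%
      mutate(grp = grp) %>%
      group_by(.data$grp) %>%
      summarise(start = min(start), end = max(end), .groups = "drop") %>%
      select(start, end)
  }

  events <- purrr::pmap_dfr(runs, function(start, end) {
    idx <- start:end
    span <- flags[idx, ]
    span <- span[span$flagged, ]  # gap frames carry no proximity vote
    per_faucet <- span %>%
      group_by(faucet_id) %>%
      summarise(mean_P = mean(proximity), .groups = "drop") %>%
      arrange(desc(mean_P), faucet_id)
    start_frame <- flags$frame[start]
    end_frame <- flags$frame[end] + 1L
    tibble(
      faucet_id = per_faucet$faucet_id[1],
      start_frame = start_frame,
      end_frame = end_frame,
      mean_proximity = mean(span$proximity),
      max_proximity = max(span$proximity)
    )
  })

  events <- events %>%
    mutate(
      start_s = start_frame / fps,
      end_s = end_frame / fps,
      duration_s = (end_frame - start_frame) / fps
    ) %>%
    filter(duration_s >= min_duration_s)
  if (nrow(events) == 0) return(empty)

  events %>%
    arrange(start_frame) %>%
    mutate(
      event_id = row_number(),
      pen_id = pen_id,
      start_clock = format_clock(session_start_s + start_s)
    ) %>%
    select(event_id, pen_id, faucet_id, start_frame, end_frame,
           start_s, end_s, duration_s, start_clock,
           mean_proximity, max_proximity)
}

#' Run the full drinking-event pipeline on one stream
#'
#' Composes [localize_faucets()], [flag_frames()] and [segment_events()]:
#' fix faucet positions from the opening frames, score head-faucet
#' proximity per frame, flag frames above threshold, and segment flagged
#' runs into drinking events. Deterministic for fixed inputs.
#'
#' @inheritParams localize_faucets
#' @inheritParams flag_frames
#' @inheritParams segment_events
#' @return Event tibble as from [segment_events()].
#' @examples
#' sim <- simulate_session(hours = 0.2, fps = 5, seed = 1)
#' detect_events(sim$stream)
#' @export
detect_events <- function(stream, threshold = 0.98, min_duration_s = 5,
                          n_init_frames = 30, max_faucets = 2,
                          max_gap_frames = 0, cluster_radius_frac = 0.05) {
  faucets <- localize_faucets(stream, n_init_frames = n_init_frames,
                              max_faucets = max_faucets,
                              cluster_radius_frac = cluster_radius_frac)
  flags <- flag_frames(stream, faucets, threshold = threshold)
  segment_events(flags, min_duration_s = min_duration_s,
                 max_gap_frames = max_gap_frames)
}
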