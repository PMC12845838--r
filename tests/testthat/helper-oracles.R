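# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (scans, rasterization, direct formulas)
# and share no code with the implementation they check.

# build a detection stream from a plain detections data frame
make_stream <- function(detections, w = 640, h = 480, fps = 25,
                        session_start = "06:30:00", n_frames = NULL) {
  detection_stream(detections, frame_width = w, frame_height = h, fps = fps,
                   session_start = session_start, n_frames = n_frames)
}

# one detection row
det_row <- function(frame, label, conf, x1, y1, x2, y2) {
  tibble::tibble(frame = frame, label = label, conf = conf,
                 x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

# a box of side 10 centred at (xc, yc)
box_at <- function(frame, label, conf, xc, yc, half = 5) {
  det_row(frame, label, conf, xc - half, yc - half, xc + half, yc + half)
}

# flag tibble as flag_frames() would produce, from a logical vector
manual_flags <- function(flagged, proximity = 0.99, faucet_id = 1L,
                         fps = 25, session_start = 0) {
  structure(
    tibble::tibble(
      frame = seq_along(flagged) - 1L,
      flagged = flagged,
      proximity = ifelse(flagged, proximity, NA_real_),
      faucet_id = ifelse(flagged, as.integer(faucet_id), NA_integer_)
    ),
    fps = fps, session_start_s = session_start, pen_id = "pen"
  )
}

# brute-force event segmentation: linear scan over frames
brute_segment <- function(flagged, fps, min_duration_s = 5,
                          max_gap_frames = 0) {
  n <- length(flagged)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (!flagged[i]) {
      i <- i + 1
      next
    }
    j <- i
    repeat {
      while (j < n && flagged[j + 1]) j <- j + 1
      nxt <- j + 1
      while (nxt <= n && !flagged[nxt]) nxt <- nxt + 1
      if (nxt <= n && (nxt - j - 1) <= max_gap_frames) j <- nxt else break
    }
    out <- rbind(out, c(i - 1L, j))  # 0-based [start, end)
    i <- j + 1
  }
  if (is.null(out)) {
    return(tibble::tibble(start_frame = integer(), end_frame = integer()))
  }
  keep <- (out[, 2] - out[, 1]) / fps >= min_duration_s
  tibble::tibble(start_frame = as.integer(out[keep, 1]),
                 end_frame = as.integer(out[keep, 2]))
}

# rasterized interval IoU at millisecond resolution; endpoints must be
# millisecond-aligned for the rasterization to be exact
raster_iou <- function(a, b, res = 1000) {
  to_ms <- function(iv) round(iv * res)
  a <- to_ms(a)
  b <- to_ms(b)
  n <- max(a, b, 1)
  mark <- function(iv) {
    v <- logical(n)
    for (i in seq_len(nrow(iv))) {
      if (iv[i, 2] > iv[i, 1]) v[(iv[i, 1] + 1):iv[i, 2]] <- TRUE
    }
    v
  }
  va <- mark(a)
  vb <- mark(b)
  u <- sum(va | vb)
  if (u == 0) 1 else sum(va & vb) / u
}

# Kruskal-Wallis H from the defining formula: midranks, tie correction,
# no shared code with stats::kruskal.test
kw_H_formula <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)  # midranks
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  R <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / sizes) - 3 * (N + 1)
  t <- table(x)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  if (corr > 0) H / corr else 0
}

# daily event counts of the published three-pig, six-day reference block
reference_daily_counts <- function() {
  split(minipig_daily()$n_events, minipig_daily()$pig)
}
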