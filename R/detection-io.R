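#' Read and write detection streams
#'
#' Two on-disk dialects are supported, both carrying the scene metadata the
#' proximity algorithm needs (frame size, fps, session start, frame count):
#'
#' * **jsonl** — first line a metadata record
#'   `{"type":"meta","frame_width":...,...}`, then one record per frame
#'   `{"frame":0,"detections":[{"label":...,"conf":...,"box":[x1,y1,x2,y2]}]}`.
#'   Frames with no detections may be omitted.
#' * **csv** — long format, one detection per row
#'   (`frame,label,conf,x1,y1,x2,y2`), preceded by a `#meta {...}` comment
#'   line holding the same metadata as JSON.
#'
#' Confidences and coordinates are written with shortest round-trip
#' precision, so write-then-read reproduces a stream exactly.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; the default infers it from the file
#'   extension.
#' @return `read_detection_stream()` returns a validated
#'   [detection_stream()]; `write_detection_stream()` returns `path`
#'   invisibly.
#' @export
read_detection_stream <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = c("pigsip_error_io", "pigsip_error"))
  }
  switch(format,
    jsonl = read_stream_jsonl(path),
    csv = read_stream_csv(path)
  )
}

#' @rdname read_detection_stream
#' @param stream A [detection_stream()] to serialise.
#' @export
write_detection_stream <- function(stream, path,
                                   format = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(stream, "detection_stream"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  switch(format,
    jsonl = write_stream_jsonl(stream, path),
    csv = write_stream_csv(stream, path)
  )
  invisible(path)
}

stream_meta_list <- function(stream) {
  list(
    type = "meta",
    frame_width = attr(stream, "frame_width"),
    frame_height = attr(stream, "frame_height"),
    fps = attr(stream, "fps"),
    session_start = attr(stream, "session_start_s"),
    n_frames = attr(stream, "n_frames"),
    pen_id = attr(stream, "pen_id")
  )
}

check_meta <- function(meta, path) {
  needed <- c("frame_width", "frame_height", "fps", "session_start", "n_frames")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("metadata record in %s is missing field(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = c("pigsip_error_format", "pigsip_error"))
  }
  meta
}

stream_from_parts <- function(detections, meta) {
  detection_stream(
    detections,
    frame_width = meta$frame_width,
    frame_height = meta$frame_height,
    fps = meta$fps,
    session_start = meta$session_start,
    n_frames = meta$n_frames,
    pen_id = meta$pen_id %||% NA_character_
  )
}

write_stream_jsonl <- function(stream, path) {
  lines <- jsonlite::toJSON(stream_meta_list(stream), auto_unbox = TRUE,
                            digits = NA)
  d <- as_tibble(stream)
  if (nrow(d) > 0) {
    per_frame <- split(d, d$frame)
    frame_lines <- vapply(per_frame, function(fd) {
      dets <- purrr::pmap(fd[c("label", "conf", "x1", "y1", "x2", "y2")],
        function(label, conf, x1, y1, x2, y2) {
          list(label = label, conf = conf, box = c(x1, y1, x2, y2))
        })
      jsonlite::toJSON(list(frame = fd$frame[1], detections = dets),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    lines <- c(lines, frame_lines)
  }
  writeLines(lines, path)
}

read_stream_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("empty detection file: ", path), class = c("pigsip_error_format", "pigsip_error"))
  }
  meta <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (is.null(meta$type) || !identical(meta$type, "meta")) {
    abort(paste0("first JSONL record must be the metadata record in ", path),
          class = c("pigsip_error_format", "pigsip_error"))
  }
  check_meta(meta, path)
  records <- lapply(lines[-1], jsonlite::fromJSON, simplifyVector = FALSE)
  detections <- purrr::map_dfr(records, function(rec) {
    dets <- rec$detections
    if (length(dets) == 0) return(NULL)
    tibble(
      frame = as.integer(rec$frame),
      label = purrr::map_chr(dets, "label"),
      conf = purrr::map_dbl(dets, "conf"),
      x1 = purrr::map_dbl(dets, ~ .x$box[[1]]),
      y1 = purrr::map_dbl(dets, ~ .x$box[[2]]),
      x2 = purrr::map_dbl(dets, ~ .x$box[[3]]),
      y2 = purrr::map_dbl(dets, ~ .x$box[[4]])
    )
  })
  if (nrow(detections) == 0) {
    detections <- tibble(frame = integer(), label = character(),
                         conf = double(), x1 = double(), y1 = double(),
                         x2 = double(), y2 = double())
  }
  stream_from_parts(detections, meta)
}

write_stream_csv <- function(stream, path) {
  meta_line <- paste0("#meta ", jsonlite::toJSON(stream_meta_list(stream),
                                                 auto_unbox = TRUE, digits = NA))
  writeLines(meta_line, path)
  readr::write_csv(as_tibble(stream), path, append = TRUE, col_names = TRUE)
}

read_stream_csv <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (!startsWith(first, "#meta ")) {
    abort(paste0("missing '#meta' metadata line in ", path),
          class = c("pigsip_error_format", "pigsip_error"))
  }
  meta <- jsonlite::fromJSON(sub("^#meta ", "", first), simplifyVector = TRUE)
  check_meta(meta, path)
  detections <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      frame = readr::col_integer(), label = readr::col_character(),
      conf = readr::col_double(), x1 = readr::col_double(),
      y1 = readr::col_double(), x2 = readr::col_double(),
      y2 = readr::col_double()
    )
  )
  stream_from_parts(detections, meta)
}

#' Read and write drinking-event tables
#'
#' Events are plain CSV, one row per event, with columns `pen_id`,
#' `start_s`, `end_s`, `duration_s`, `start_clock`, `faucet_id`,
#' `mean_proximity`, `max_proximity`, `start_frame`, `end_frame`. A
#' write-then-read round trip is lossless.
#'
#' @param events An event tibble as produced by [segment_events()] or
#'   [detect_events()].
#' @param path File path.
#' @return `read_events()` returns the event tibble; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("pen_id", "start_s", "end_s", "duration_s", "start_clock",
            "faucet_id", "mean_proximity", "max_proximity",
            "start_frame", "end_frame")
  missing <- setdiff(c("start_s", "end_s", "duration_s", "faucet_id"),
                     names(events))
  if (length(missing) > 0) {
    abort(paste0("events table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  for (col in setdiff(cols, names(events))) events[[col]] <- NA
  readr::write_csv(events[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = c("pigsip_error_io", "pigsip_error"))
  }
  readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      pen_id = readr::col_character(), start_s = readr::col_double(),
      end_s = readr::col_double(), duration_s = readr::col_double(),
      start_clock = readr::col_character(),
      faucet_id = readr::col_integer(),
      mean_proximity = readr::col_double(),
      max_proximity = readr::col_double(),
      start_frame = readr::col_integer(),
      end_frame = readr::col_integer()
    )
  )
}

#' Read a frame-level ground-truth drinking track
#'
#' Ground truth is a sparse CSV of `(frame_index, drinking)` rows with
#' `drinking` in \{0, 1\}; frames not listed default to 0. The result is a
#' dense 0/1 integer vector aligned to the stream's frames.
#'
#' @param path CSV path with columns `frame_index`, `drinking`.
#' @param stream The [detection_stream()] the annotations refer to (sets
#'   the track length and permitted frame range).
#' @return Integer vector of length `n_frames` with values in \{0, 1\}.
#' @export
read_ground_truth <- function(path, stream) {
  stopifnot(inherits(stream, "detection_stream"))
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = c("pigsip_error_io", "pigsip_error"))
  }
  n_frames <- attr(stream, "n_frames")
  gt <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(frame_index = readr::col_integer(),
                            drinking = readr::col_integer())
  )
  track <- integer(n_frames)
  if (nrow(gt) > 0) {
    if (any(!gt$drinking %in% c(0L, 1L))) {
      abort("ground-truth labels must be 0 or 1",
            class = c("pigsip_error_validation", "pigsip_error"))
    }
    if (any(gt$frame_index < 0 | gt$frame_index >= n_frames)) {
      abort(sprintf("ground-truth frame index outside [0, %d)", n_frames),
            class = c("pigsip_error_validation", "pigsip_error"))
    }
    track[gt$frame_index + 1L] <- gt$drinking
  }
  track
}

#' @rdname read_ground_truth
#' @param track Dense 0/1 vector to serialise; only positive frames are
#'   written (absent frames are 0 by convention).
#' @export
write_ground_truth <- function(track, path) {
  pos <- which(track == 1L) - 1L
  readr::write_csv(tibble(frame_index = pos, drinking = 1L), path,
                   progress = FALSE)
  invisible(path)
}
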