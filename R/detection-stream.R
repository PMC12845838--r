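#' The closed detection vocabulary
#'
#' The six object classes a pen-monitoring detector emits. Only
#' `"Pig-Head"` and `"Water-Faucet"` drive drinking inference; the other
#' classes are carried through unchanged so streams round-trip losslessly.
#'
#' @format Character vector of length six.
#' @export
pig_classes <- c("Pig-Standing", "Pig-Laying", "Pig-Head",
                 "Water-Faucet", "Keeper", "Feces")

#' Build a detection stream
#'
#' A detection stream is the unit of input for drinking inference: every
#' per-frame bounding box a detector produced over one monitoring session,
#' together with the scene metadata needed to interpret it (frame size,
#' frame rate, session start clock time). It is stored as a tibble of
#' detections (one row per box) with metadata attached as attributes, so
#' it pipes straight into dplyr verbs.
#'
#' @param detections A data frame with columns `frame` (0-based frame
#'   index), `label` (one of [pig_classes]), `conf` (detector confidence
#'   in \[0, 1\]) and pixel box corners `x1, y1, x2, y2` (origin top-left,
#'   x rightward, y downward, `x1 < x2`, `y1 < y2`). May have zero rows.
#' @param frame_width,frame_height Frame size in pixels.
#' @param fps Frames per second (> 0).
#' @param session_start Wall-clock time of frame 0, `"HH:MM:SS"` or
#'   seconds since midnight.
#' @param n_frames Number of frames in the session. Defaults to
#'   `max(frame) + 1` (at least 1).
#' @param pen_id Identifier of the monitored pen/pig (optional).
#'
#' @return A `detection_stream`: a tibble of detections sorted stably by
#'   `frame`, with attributes `frame_width`, `frame_height`, `fps`,
#'   `session_start_s`, `n_frames`, `pen_id`.
#' @examples
#' detection_stream(
#'   tibble::tibble(frame = 0L, label = "Water-Faucet", conf = 0.9,
#'                  x1 = 10, y1 = 10, x2 = 40, y2 = 50),
#'   frame_width = 640, frame_height = 480, fps = 25
#' )
#' @export
detection_stream <- function(detections, frame_width, frame_height, fps,
                             session_start = "06:30:00", n_frames = NULL,
                             pen_id = NA_character_) {
  if (!is.numeric(frame_width) || !is.numeric(frame_height) ||
      frame_width <= 0 || frame_height <= 0) {
    abort("frame_width and frame_height must be positive",
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    abort("fps must be a positive number", class = c("pigsip_error_validation", "pigsip_error"))
  }
  detections <- as_tibble(detections)
  required <- c("frame", "label", "conf", "x1", "y1", "x2", "y2")
  missing_cols <- setdiff(required, names(detections))
  if (length(missing_cols) > 0) {
    abort(paste0("detections is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = c("pigsip_error_format", "pigsip_error"))
  }
  detections <- detections[required]
  detections$frame <- as.integer(detections$frame)
  validate_detections(detections, frame_width, frame_height)

  if (is.unsorted(detections$frame)) {
    warn("detections were not sorted by frame; repairing order")
    detections <- detections[order(detections$frame), , drop = FALSE]
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(detections) == 0) 1L else max(detections$frame) + 1L
  }
  n_frames <- as.integer(n_frames)
  if (nrow(detections) > 0 && max(detections$frame) >= n_frames) {
    abort("frame index beyond n_frames", class = c("pigsip_error_validation", "pigsip_error"))
  }

  structure(
    detections,
    class = c("detection_stream", class(detections)),
    frame_width = as.numeric(frame_width),
    frame_height = as.numeric(frame_height),
    fps = as.numeric(fps),
    session_start_s = parse_clock(session_start),
    n_frames = n_frames,
    pen_id = pen_id
  )
}

validate_detections <- function(d, frame_width, frame_height) {
  bad <- function(which, msg) {
    abort(sprintf("invalid detection at row %d: %s", which, msg),
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  if (nrow(d) == 0) return(invisible(d))
  unknown <- !(d$label %in% pig_classes)
  if (any(unknown)) {
    i <- which(unknown)[1]
    bad(i, sprintf("unknown label '%s'", d$label[i]))
  }
  if (any(d$frame < 0)) bad(which(d$frame < 0)[1], "negative frame index")
  oob_conf <- d$conf < 0 | d$conf > 1 | is.na(d$conf)
  if (any(oob_conf)) bad(which(oob_conf)[1], "confidence outside [0, 1]")
  degenerate <- d$x1 >= d$x2 | d$y1 >= d$y2
  if (any(degenerate)) bad(which(degenerate)[1], "box with x1 >= x2 or y1 >= y2")
  neg <- d$x1 < 0 | d$y1 < 0
  if (any(neg)) bad(which(neg)[1], "negative box coordinate")
  oob <- d$x2 > frame_width | d$y2 > frame_height
  if (any(oob)) bad(which(oob)[1], "box extends beyond frame bounds")
  invisible(d)
}

#' Frame diagonal of a stream or scene
#'
#' The pixel length of the frame diagonal, the normalising constant of the
#' proximity score.
#'
#' @param x A `detection_stream`, a `pen_scene`, or a numeric
#'   `c(width, height)` pair.
#' @return Diagonal length in pixels.
#' @export
frame_diagonal <- function(x) {
  if (inherits(x, "detection_stream") || inherits(x, "pen_scene")) {
    w <- attr(x, "frame_width")
    h <- attr(x, "frame_height")
  } else {
    w <- x[1]
    h <- x[2]
  }
  sqrt(w^2 + h^2)
}

#' @export
print.detection_stream <- function(x, ...) {
  cat(sprintf(
    "<detection_stream> %d detections over %d frames (%gx%g px, %g fps, start %s)\n",
    nrow(x), attr(x, "n_frames"), attr(x, "frame_width"),
    attr(x, "frame_height"), attr(x, "fps"),
    format_clock(attr(x, "session_start_s"))
  ))
  NextMethod()
}

# rebuild a stream around a modified detections tibble, keeping metadata
restream <- function(detections, template, n_frames = attr(template, "n_frames"),
                     fps = attr(template, "fps")) {
  detection_stream(
    detections,
    frame_width = attr(template, "frame_width"),
    frame_height = attr(template, "frame_height"),
    fps = fps,
    session_start = attr(template, "session_start_s"),
    n_frames = n_frames,
    pen_id = attr(template, "pen_id")
  )
}
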