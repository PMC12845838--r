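#' Downsample a stream or per-frame track by a frame stride
#'
#' Human validation of long sessions is done at a reduced frame rate; a
#' 25 fps stream thinned with stride 18 gives an effective ~1.39 fps.
#' `downsample_frames()` keeps frames whose index is divisible by
#' `stride` and renumbers them consecutively; for a [detection_stream()]
#' the fps metadata becomes `fps / stride`.
#'
#' @param x A [detection_stream()] or a dense per-frame vector (e.g. a
#'   ground-truth track).
#' @param stride Positive integer frame stride; `stride_for()` computes it
#'   as `round(native_fps / target_fps)`.
#' @return Object of the same kind as `x`, reduced.
#' @examples
#' stride_for(25, 1.38)       # 18
#' 25 / stride_for(25, 1.38)  # effective rate ~1.389 fps
#' @export
downsample_frames <- function(x, stride) {
  if (!is.numeric(stride) || length(stride) != 1 || stride < 1 ||
      stride != round(stride)) {
    abort("stride must be a positive integer", class = c("pigsip_error_contract", "pigsip_error"))
  }
  stride <- as.integer(stride)
  if (inherits(x, "detection_stream")) {
    n_frames <- attr(x, "n_frames")
    kept <- as_tibble(x) %>%
      filter(frame %% stride == 0L) %>%
      mutate(frame = frame %/% stride)
    return(restream(kept, x,
                    n_frames = (n_frames - 1L) %/% stride + 1L,
                    fps = attr(x, "fps") / stride))
  }
  if (is.atomic(x)) {
    return(x[seq(1L, length(x), by = stride)])
  }
  abort("downsample_frames() handles detection streams and dense vectors",
        class = c("pigsip_error_contract", "pigsip_error"))
}

#' @rdname downsample_frames
#' @param native_fps,target_fps Native and desired frame rates.
#' @export
stride_for <- function(native_fps, target_fps) {
  stride <- round(native_fps / target_fps)
  if (stride < 1) {
    abort("target_fps must not exceed native_fps", class = c("pigsip_error_contract", "pigsip_error"))
  }
  as.integer(stride)
}

#' Frame-level confusion metrics against ground truth
#'
#' Compares two equal-length binary per-frame tracks (predicted drinking
#' vs human-annotated drinking) and reports the confusion counts and the
#' derived metrics: accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and their harmonic mean F1. With zero predicted (or zero
#' true) positives the undefined ratio is reported as 0 with a warning so
#' batch validation never crashes.
#'
#' @param pred,truth Equal-length vectors of 0/1 (or logical) frame
#'   labels.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `n`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' frame_confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
frame_confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort(sprintf("track lengths differ (%d vs %d)",
                  length(pred), length(truth)),
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  pred <- as.integer(as.logical(pred))
  truth <- as.integer(as.logical(truth))
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  n <- length(pred)

  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); reporting 0", what))
      0
    } else {
      num / den
    }
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
         accuracy = (tp + tn) / n,
         precision = precision, recall = recall, f1 = f1)
}

#' Event-level temporal concordance (interval IoU)
#'
#' How much of the time identified as drinking is shared between two
#' event lists (typically model vs human annotation). Each side's
#' half-open `[start_s, end_s)` intervals are unioned first; the score is
#' the measure of the intersection of the two unions over the measure of
#' their union (intersection-over-union on the time axis). The companion
#' fractions report what part of the union is covered by one side only.
#'
#' @param pred_events,truth_events Event tibbles with columns `start_s`
#'   and `end_s` (as from [detect_events()]), or two-column matrices of
#'   `(start, end)` in seconds.
#' @return One-row tibble: `overlap_s`, `union_s`, `iou`,
#'   `pred_only_frac`, `truth_only_frac`.
#' @examples
#' temporal_concordance(cbind(0, 10), cbind(5, 15))  # iou = 1/3
#' @export
temporal_concordance <- function(pred_events, truth_events) {
  a <- merge_intervals(as_intervals(pred_events))
  b <- merge_intervals(as_intervals(truth_events))
  len <- function(iv) if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])
  overlap <- intersect_length(a, b)
  union_s <- len(a) + len(b) - overlap
  iou <- if (union_s == 0) 1 else overlap / union_s
  tibble(
    overlap_s = overlap,
    union_s = union_s,
    iou = iou,
    pred_only_frac = if (union_s == 0) 0 else (len(a) - overlap) / union_s,
    truth_only_frac = if (union_s == 0) 0 else (len(b) - overlap) / union_s
  )
}

as_intervals <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("start_s", "end_s") %in% names(x))) {
      abort("event table needs start_s and end_s columns",
            class = c("pigsip_error_validation", "pigsip_error"))
    }
    x <- cbind(x$start_s, x$end_s)
  }
  x <- matrix(as.numeric(x), ncol = 2)
  if (nrow(x) > 0 && any(x[, 2] <= x[, 1])) {
    abort("malformed interval with end <= start",
          class = c("pigsip_error_validation", "pigsip_error"))
  }
  x
}

# merge overlapping/touching half-open intervals into a disjoint sorted set
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out_start <- iv[1, 1]
  out_end <- iv[1, 2]
  starts <- numeric(0)
  ends <- numeric(0)
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out_end) {
      out_end <- max(out_end, iv[i, 2])
    } else {
      starts <- c(starts, out_start)
      ends <- c(ends, out_end)
      out_start <- iv[i, 1]
      out_end <- iv[i, 2]
    }
  }
  cbind(c(starts, out_start), c(ends, out_end))
}

# total overlap length between two disjoint sorted interval sets
intersect_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    total <- total + sum(pmax(0, hi - lo))
  }
  total
}
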