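#' Localise fixed faucet positions from the opening frames
#'
#' Water faucets do not move, so their positions are fixed once per
#' session and used as the stable reference for every later distance
#' computation. All `Water-Faucet` detections in the first `n_init_frames`
#' frames are greedily clustered by centroid distance: detections are
#' visited in descending confidence order and join the first cluster whose
#' seed centroid lies within `cluster_radius_frac * d_diag`, otherwise
#' they seed a new cluster. Each cluster is represented by its
#' highest-confidence box, clusters are ranked by that confidence, and up
#' to `max_faucets` are kept.
#'
#' @param stream A [detection_stream()].
#' @param n_init_frames Number of opening frames to scan (default 30). If
#'   the stream is shorter, all frames are used with a warning.
#' @param max_faucets Maximum number of faucets to fix (default 2).
#' @param cluster_radius_frac Clustering radius as a fraction of the frame
#'   diagonal (default 0.05).
#' @return A `faucet_map`: tibble with columns `faucet_id`, `x1, y1, x2,
#'   y2`, `xc`, `yc`, `conf`, `n_detections`, ordered by descending
#'   confidence, with the frame diagonal attached as attribute `d_diag`.
#' @seealso [flag_frames()], [detect_events()]
#' @export
localize_faucets <- function(stream, n_init_frames = 30, max_faucets = 2,
                             cluster_radius_frac = 0.05) {
  stopifnot(inherits(stream, "detection_stream"))
  n_frames <- attr(stream, "n_frames")
  if (n_frames < n_init_frames) {
    warn(sprintf(
      "stream has %d frames, fewer than the %d requested for faucet localization; using all",
      n_frames, n_init_frames))
    n_init_frames <- n_frames
  }
  d_diag <- frame_diagonal(stream)
  radius <- cluster_radius_frac * d_diag

  cand <- as_tibble(stream) %>%
    filter(label == "Water-Faucet", frame < n_init_frames) %>%
    dplyr::bind_cols(box_centroid(.)) %>%
    arrange(desc(conf))
  if (nrow(cand) == 0) {
    abort("no Water-Faucet detections in the initialization window; monitoring cannot start",
          class = c("pigsip_error_localization", "pigsip_error"))
  }

  # greedy single-link-to-seed clustering in confidence order: the first
  # (highest-confidence) member of a cluster is its seed and representative
  seed_x <- numeric(0)
  seed_y <- numeric(0)
  assignment <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (length(seed_x) > 0) {
      dists <- sqrt((cand$xc[i] - seed_x)^2 + (cand$yc[i] - seed_y)^2)
      hit <- which(dists <= radius)
    } else {
      hit <- integer(0)
    }
    if (length(hit) > 0) {
      assignment[i] <- hit[1]
    } else {
      seed_x <- c(seed_x, cand$xc[i])
      seed_y <- c(seed_y, cand$yc[i])
      assignment[i] <- length(seed_x)
    }
  }
  cand$cluster <- assignment

  reps <- cand %>%
    group_by(.data$cluster) %>%
    summarise(
      x1 = x1[1], y1 = y1[1], x2 = x2[1], y2 = y2[1],
      xc = xc[1], yc = yc[1], conf = conf[1],
      n_detections = dplyr::n(), .groups = "drop"
    ) %>%
    arrange(desc(conf)) %>%
    head(max_faucets) %>%
    mutate(faucet_id = row_number()) %>%
    select(faucet_id, x1, y1, x2, y2, xc, yc, conf, n_detections)

  structure(reps, class = c("faucet_map", class(reps)), d_diag = d_diag)
}
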