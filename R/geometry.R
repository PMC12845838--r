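#' Bounding-box centroid
#'
#' The geometric centre of an axis-aligned pixel box, kept real-valued (no
#' integer truncation): `((x1 + x2) / 2, (y1 + y2) / 2)`.
#'
#' @param box Either a numeric `c(x1, y1, x2, y2)` or a data frame with
#'   columns `x1, y1, x2, y2` (vectorised).
#' @return A tibble with columns `xc`, `yc`, one row per box.
#' @examples
#' box_centroid(c(0, 0, 10, 10))
#' @export
box_centroid <- function(box) {
  if (is.numeric(box)) {
    stopifnot(length(box) == 4)
    box <- tibble(x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4])
  }
  tibble(xc = (box$x1 + box$x2) / 2, yc = (box$y1 + box$y2) / 2)
}

#' Head-faucet proximity score
#'
#' Proximity between a pig-head centroid and a fixed faucet centroid,
#' normalised by the frame diagonal: `P = 1 - d / d_diag`, where `d` is
#' the Euclidean pixel distance. `P = 1` means coincident centroids and
#' values fall towards 0 as the head moves away; for centroids inside the
#' frame `P` stays in \[0, 1\].
#'
#' @param head,faucet Centroids: length-2 numeric `c(xc, yc)` vectors, or
#'   data frames with columns `xc`, `yc` (vectorised, recycled row-wise).
#' @param d_diag Frame diagonal in pixels (> 0); see [frame_diagonal()].
#' @return Numeric vector of proximity scores.
#' @examples
#' proximity_score(c(320, 240), c(320, 256), d_diag = 800)  # d = 16 -> 0.98
#' @export
proximity_score <- function(head, faucet, d_diag) {
  if (!is.numeric(d_diag) || any(d_diag <= 0)) {
    abort("d_diag must be positive", class = c("pigsip_error_contract", "pigsip_error"))
  }
  pt <- function(p) {
    if (is.numeric(p)) tibble(xc = p[1], yc = p[2]) else as_tibble(p)
  }
  h <- pt(head)
  f <- pt(faucet)
  d <- sqrt((h$xc - f$xc)^2 + (h$yc - f$yc)^2)
  1 - d / d_diag
}
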