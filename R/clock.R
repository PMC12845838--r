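#' Clock-time helpers
#'
#' Sessions are anchored to a wall-clock start time ("lights on" in a pig
#' facility is typically 06:30). Internally all clock times are seconds
#' since midnight; these helpers convert to and from `"HH:MM:SS"` strings.
#'
#' @param x For `parse_clock()`, a character vector of `"HH:MM"` or
#'   `"HH:MM:SS"` times (numeric input is passed through). For
#'   `format_clock()`, a numeric vector of seconds since midnight.
#' @return `parse_clock()` returns seconds since midnight (numeric);
#'   `format_clock()` returns `"HH:MM:SS"` strings.
#' @examples
#' parse_clock("06:30")
#' format_clock(23400 + 4521.5)
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2 || length(p) > 3 || anyNA(p)) {
      abort("clock times must be 'HH:MM' or 'HH:MM:SS'",
            class = c("pigsip_error_validation", "pigsip_error"))
    }
    if (length(p) == 2) p <- c(p, 0)
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

#' @rdname parse_clock
#' @export
format_clock <- function(x) {
  x <- as.numeric(x) %% 86400
  h <- floor(x / 3600)
  m <- floor((x - h * 3600) / 60)
  s <- x - h * 3600 - m * 60
  sprintf("%02d:%02d:%06.3f", h, m, s)
}

# clock hour (possibly fractional) of a session-relative time in seconds
clock_hours <- function(start_s, session_start_s) {
  ((session_start_s + start_s) %% 86400) / 3600
}
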