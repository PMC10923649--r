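# Interval plumbing. Internal convention: 0-based, half-open, on the
# canonical linearization. Intervals that cross the linearization origin of
# a circular molecule carry wraps = TRUE, in which case start > end and the
# interval covers [start, n) followed by [0, end).

#' Create an interval
#'
#' Intervals are 0-based half-open internally; every exported report
#' converts to 1-based inclusive coordinates.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param wraps Does the interval cross the circular origin?
#' @return An object of class `psv_interval`.
#' @export
interval <- function(start, end, wraps = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < 0L) {
    psv_error("psv_bad_interval", "interval bounds must be non-negative integers")
  }
  if (!wraps && end < start) {
    psv_error("psv_bad_interval", sprintf("non-wrapping interval has end (%d) < start (%d)", end, start))
  }
  structure(list(start = start, end = end, wraps = isTRUE(wraps)), class = "psv_interval")
}

interval_len <- function(iv, n = NULL) {
  if (!iv$wraps) return(iv$end - iv$start)
  stopifnot(!is.null(n))
  (n - iv$start) + iv$end
}

# Extract the bases covered by an interval from a circular sequence.
interval_seq <- function(seq, iv) {
  n <- nchar(seq)
  circ_substr(seq, iv$start, interval_len(iv, n))
}

# Do two non-wrapping intervals overlap (>= 1 base)?
intervals_overlap <- function(a, b) {
  a$start < b$end && b$start < a$end
}

# 1-based inclusive view for reports.
interval_1based <- function(iv, n = NULL) {
  len <- interval_len(iv, n)
  list(start = iv$start + 1L, end = if (!iv$wraps) iv$end else iv$end, length = len)
}

#' @export
print.psv_interval <- function(x, ...) {
  cat(sprintf(
    "[%d, %d)%s (0-based half-open)\n", x$start, x$end,
    if (x$wraps) " wrapping origin" else ""
  ))
  invisible(x)
}
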