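#' Wrap clock times onto the 24-hour circle
#'
#' @param x numeric vector of times in hours (any real values).
#' @return times wrapped to `[0, 24)`.
#' @export
wrap24 <- function(x) x %% 24

#' Minimal signed difference between two clock times
#'
#' Computes `t1 - t2` on the 24-h circle, returning the representative in
#' `(-12, 12]`. So `circular_diff(23, 1)` is `-2` (23:00 is two hours before
#' 01:00), and `circular_diff(1, 23)` is `+2`.
#'
#' @param t1,t2 numeric vectors of clock times in hours, `[0, 24)`.
#' @return signed hours in `(-12, 12]`, recycled to common length.
#' @export
circular_diff <- function(t1, t2) {
  d <- (t1 - t2) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Circular mean of clock times
#'
#' Mean direction of times mapped to angles at period 24 h. Undefined
#' (returns `NA`) when the resultant length is numerically zero.
#'
#' @param x clock times in hours.
#' @param na.rm drop missing values first.
#' @return circular mean in `[0, 24)`, or `NA` for a degenerate input.
#' @export
circular_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  ang <- x * pi / 12
  s <- mean(sin(ang)); c <- mean(cos(ang))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap24(atan2(s, c) * 12 / pi)
}

#' Test circular containment of a clock time in an arc
#'
#' The arc runs clockwise from `low` to `high`; arcs may wrap midnight
#' (e.g. `low = 23.5, high = 0.5`). Endpoints are inclusive.
#'
#' @param x clock time(s), hours in `[0, 24)`.
#' @param low,high arc endpoints in hours. If given unwrapped (`high` up to
#'   `low + 24`), they are wrapped; a span exceeding 24 h is an error.
#' @return logical vector.
#' @export
in_circular_interval <- function(x, low, high) {
  if (any(high - low > 24 + 1e-9)) {
    stop("interval spans more than 24 h")
  }
  width <- (high - low) %% 24
  # unwrapped span of exactly 24 h means the full circle, not a point
  width[(high - low) >= 24 - 1e-12] <- 24
  pos <- (x - low) %% 24
  pos <= width + 1e-12
}
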