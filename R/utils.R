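#' Simulation clock
#'
#' Small helper shared by every time-discretized stage: holds the sampling
#' frequency `fs` (Hz) and step `dt = 1/fs` (s).
#'
#' @param fs sampling frequency in Hz.
#' @return object of class `semg_clock` with elements `fs` and `dt`.
#' @export
semg_clock <- function(fs = 2000) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  structure(list(fs = fs, dt = 1 / fs), class = "semg_clock")
}

#' @export
print.semg_clock <- function(x, ...) {
  cat(sprintf("<semg_clock> fs = %g Hz (dt = %g s)\n", x$fs, x$dt))
  invisible(x)
}

# seconds -> nearest sample index (1-based), clamped to [1, n]
time_to_sample <- function(t, clock, n = NULL) {
  i <- as.integer(round(t * clock$fs)) + 1L
  if (!is.null(n)) i <- pmin(pmax(i, 1L), n)
  i
}

# cumulative arc length (mm) along a polyline given as an n x 3 matrix
polyline_arclength <- function(pts) {
  if (nrow(pts) == 1L) return(0)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# point on polyline at arc-length s (vectorized over s); clamps to ends
polyline_point <- function(pts, s) {
  cs <- polyline_arclength(pts)
  L <- cs[length(cs)]
  s <- pmin(pmax(s, 0), L)
  if (nrow(pts) == 1L) return(matrix(pts[1L, ], nrow = length(s), ncol = 3, byrow = TRUE))
  seg <- findInterval(s, cs, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(pts) - 1L)
  seglen <- cs[seg + 1L] - cs[seg]
  w <- ifelse(seglen > 0, (s - cs[seg]) / seglen, 0)
  pts[seg, , drop = FALSE] * (1 - w) + pts[seg + 1L, , drop = FALSE] * w
}

# Gaussian draw truncated to positive values: redraw up to `max_try` times,
# then clamp stragglers to avg/10.
rnorm_pos <- function(n, mean, sd, max_try = 100L) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) > 0L && tries < max_try) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) x[bad] <- mean / 10
  x
}

# first index i >= 1 with nondecreasing v[i] >= thr, or NA if none
first_at_least <- function(v, thr) {
  i <- findInterval(thr, v, left.open = TRUE) + 1L
  if (i > length(v)) NA_integer_ else i
}

`%||%` <- function(a, b) if (is.null(a)) b else a
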