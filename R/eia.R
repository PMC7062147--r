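#' EIA configuration
#'
#' @param iterations Number of smoothing iterations (>= 0); 2 by default.
#' @param min_extrema_density Convergence guard: an iteration is applied only
#'   while the current signal still carries a fast component, operationally at
#'   least this many interior extrema per sample (default 0.01, i.e. one
#'   extremum per 100 samples). Once the extrema thin out below this density
#'   the remaining oscillations are the trend itself and a further
#'   midpoint pass would start eroding it, so iteration stops. Set to 0 to
#'   force all iterations unconditionally.
#' @return Object of class `eia_config`.
#' @export
eia_config <- function(iterations = 2L, min_extrema_density = 0.01) {
  if (iterations < 0) stopf("iterations must be >= 0")
  if (min_extrema_density < 0) stopf("min_extrema_density must be >= 0")
  structure(list(iterations = as.integer(iterations),
                 min_extrema_density = min_extrema_density),
            class = "eia_config")
}

#' Strict interior local extrema
#'
#' An interior sample is a local maximum if it is strictly greater than both
#' neighbors (minimum: strictly smaller). A plateau of equal values counts as
#' one extremum at its central index (ties broken to the left); plateaus
#' touching the signal boundary are not extrema. Returned indices are 1-based
#' and maxima and minima alternate along the signal.
#'
#' @param x Numeric vector of length >= 3 (shorter inputs yield no extrema).
#' @return List with integer vectors `maxima` and `minima`.
#' @export
#' @examples
#' find_extrema(c(0, 1, 0, 1, 0))  # maxima 2, 4; minima 3
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  maxima <- integer(0)
  minima <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      v <- r$values[j]
      center <- starts[j] + (ends[j] - starts[j]) %/% 2L
      if (v > r$values[j - 1] && v > r$values[j + 1]) maxima <- c(maxima, center)
      if (v < r$values[j - 1] && v < r$values[j + 1]) minima <- c(minima, center)
    }
  }
  list(maxima = maxima, minima = minima)
}

#' Empirical Iterative Algorithm: extrema-midpoint spline smoothing
#'
#' Data-driven low-pass smoothing of a (predicted) joint angle trace. Each
#' iteration (i) locates the strict interior local maxima and minima, (ii)
#' merges them in time order, (iii) forms the midpoint of every consecutive
#' extremum pair, `((t_j + t_{j+1})/2, (x_j + x_{j+1})/2)`, (iv) anchors the
#' knot list with the first and last signal samples, and (v) evaluates a
#' natural cubic spline through the knots on the original sample grid; the
#' spline becomes the next iterate. A signal with fewer than two interior
#' extrema (constant, monotone, too short) passes through unchanged, as does
#' `iterations = 0`. Because the midpoint construction estimates the local
#' mean, it removes whatever oscillation currently dominates the extrema --
#' applied to an already-smooth signal it would erode the trend itself, so
#' iteration additionally stops once the extrema density falls below
#' `cfg$min_extrema_density` (the fast component is exhausted).
#'
#' @param x Finite numeric vector, typically degrees.
#' @param cfg An [eia_config()]; the default runs 2 iterations.
#' @return Object of class `eia_result`: `smoothed` (same length as `x`),
#'   `intermediates` (list of per-iteration outputs) and `extrema_counts`
#'   (iterations x 2 matrix of maxima/minima counts found at each iteration).
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' noisy <- sin(2 * pi * t) + 0.2 * sin(2 * pi * 20 * t)
#' res <- eia_smooth(noisy)
#' res$extrema_counts
eia_smooth <- function(x, cfg = eia_config()) {
  stopifnot(inherits(cfg, "eia_config"))
  if (!is.numeric(x) || length(x) == 0) stopf("input must be a numeric vector")
  if (any(!is.finite(x))) stopf("input contains non-finite values")
  n <- length(x)
  cur <- as.numeric(x)
  intermediates <- list()
  counts <- matrix(0L, 0, 2, dimnames = list(NULL, c("n_max", "n_min")))
  for (it in seq_len(cfg$iterations)) {
    ext <- find_extrema(cur)
    counts <- rbind(counts, c(length(ext$maxima), length(ext$minima)))
    idx <- sort(c(ext$maxima, ext$minima))
    if (length(idx) < 2) break  # identity on extrema-free signals
    if (length(idx) < cfg$min_extrema_density * n) break  # fast component gone
    tm <- (idx[-length(idx)] + idx[-1]) / 2
    vm <- (cur[idx[-length(idx)]] + cur[idx[-1]]) / 2
    kt <- c(1, tm, n)
    kv <- c(cur[1], vm, cur[n])
    cur <- spline(kt, kv, xout = seq_len(n), method = "natural")$y
    intermediates[[it]] <- cur
  }
  structure(list(smoothed = cur, intermediates = intermediates,
                 extrema_counts = counts, iterations = cfg$iterations),
            class = "eia_result")
}

#' @export
print.eia_result <- function(x, ...) {
  cat(sprintf("<eia_result> %d samples, %d iteration(s) requested, %d performed\n",
              length(x$smoothed), x$iterations, length(x$intermediates)))
  if (nrow(x$extrema_counts) > 0) {
    cat("  extrema per iteration (max/min):",
        paste(apply(x$extrema_counts, 1, paste, collapse = "/"),
              collapse = ", "), "\n")
  }
  invisible(x)
}
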