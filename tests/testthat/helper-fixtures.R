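# shared fixture builders; everything is generated in code at test time

tiny_sim <- function(seed = 1L, duration_s = 2) {
  sim_config(duration_s = duration_s, seed = seed)
}

# small network: 64-sample windows keep the pooling chain integral (64/16 = 4)
tiny_lrcn <- function(seed = 1L, ...) {
  lrcn_config(window = 64L, n_filters = 6L, lstm_units = c(8L, 12L),
              batch_size = 8L, epochs = 2L, seed = seed, ...)
}

# balanced set of short windows cut from synthetic recordings of all classes
tiny_segments <- function(duration_s = 3, seed = 2L, window_ms = 64,
                          overlap_ms = 16, normalized = TRUE) {
  recs <- gen_dataset(1, sim_config(duration_s = duration_s, seed = seed))
  segs <- bind_segments(lapply(recs, segment_windows, window_ms = window_ms,
                               overlap_ms = overlap_ms))
  if (normalized) apply_normalizer(fit_normalizer(segs), segs) else segs
}

# central finite differences of f at x
num_grad <- function(f, x, eps = 1e-3) {
  g <- array(0, if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a) + abs(b)))
}

# fraction of spectral power outside [lo, hi] Hz, via a plain FFT periodogram
band_power_outside <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  p <- p[half]
  f <- f[half]
  sum(p[f < lo | f > hi]) / sum(p)
}

total_variation <- function(x) sum(abs(diff(x)))

# band power in [lo, hi) Hz
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= lo & f < hi])
}

# the seeded sine + ripple family used by the EIA properties
ripple_signal <- function(seed, n = 1000, fs = 1000) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    t <- (seq_len(n) - 1) / fs
    phase <- runif(1, 0, 2 * pi)
    clean <- sin(2 * pi * 1 * t + phase)
    list(clean = clean,
         noisy = clean + 0.2 * sin(2 * pi * 20 * t + runif(1, 0, 2 * pi)))
  })
}
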