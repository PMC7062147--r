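#' Segment sets
#'
#' A segment set holds fixed-length windows cut from one or more recordings:
#' the sEMG windows as an `n x W x C` array, the per-window angle-sequence
#' target (`n x W`, degrees), the per-window movement class (0-based integer
#' codes), the originating subject and start sample of each window, and a
#' virtual-copy flag set by [augment_wgn()].
#'
#' @param x Numeric array `n x W x C`.
#' @param y_angle Numeric matrix `n x W` of angle targets in degrees.
#' @param y_class Integer vector of 0-based class codes.
#' @param subject_id Character vector of origins.
#' @param start 0-based start samples within the source recording.
#' @param is_virtual Logical vector; `TRUE` for augmented copies.
#' @param fs Sampling frequency in Hz.
#' @return Object of class `segment_set`.
#' @export
segment_set <- function(x, y_angle, y_class, subject_id, start,
                        is_virtual = rep(FALSE, dim(x)[1]), fs = 1000) {
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]
  if (!is.matrix(y_angle) || nrow(y_angle) != n || ncol(y_angle) != dim(x)[2]) {
    stopf("y_angle must be an n x W matrix matching x")
  }
  stopifnot(length(y_class) == n, length(subject_id) == n,
            length(start) == n, length(is_virtual) == n)
  structure(list(x = x, y_angle = y_angle, y_class = as.integer(y_class),
                 subject_id = as.character(subject_id),
                 start = as.integer(start), is_virtual = is_virtual, fs = fs),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<segment_set> %d windows of %d samples x %d channels @ %g Hz (%d virtual)\n",
              d[1], d[2], d[3], x$fs, sum(x$is_virtual)))
  print(table(factor(movement_classes()[x$y_class + 1L],
                     levels = movement_classes())))
  invisible(x)
}

#' Number of segments in a segment set
#' @param segs A `segment_set`.
#' @return Integer count.
#' @export
n_segments <- function(segs) dim(segs$x)[1]

#' @export
`[.segment_set` <- function(x, i, ...) {
  segment_set(x$x[i, , , drop = FALSE], x$y_angle[i, , drop = FALSE],
              x$y_class[i], x$subject_id[i], x$start[i], x$is_virtual[i],
              fs = x$fs)
}

#' Concatenate segment sets
#' @param ... `segment_set` objects with identical window shape.
#' @return A single `segment_set`.
#' @export
bind_segments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "segment_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]$x)
  for (s in sets) stopifnot(identical(dim(s$x)[2:3], d[2:3]))
  xs <- array(0, c(sum(vapply(sets, n_segments, 1L)), d[2], d[3]))
  ya <- matrix(0, dim(xs)[1], d[2])
  at <- 0L
  for (s in sets) {
    n <- n_segments(s)
    if (n > 0) {
      xs[at + seq_len(n), , ] <- s$x
      ya[at + seq_len(n), ] <- s$y_angle
    }
    at <- at + n
  }
  segment_set(xs, ya,
              unlist(lapply(sets, `[[`, "y_class")),
              unlist(lapply(sets, `[[`, "subject_id")),
              unlist(lapply(sets, `[[`, "start")),
              unlist(lapply(sets, `[[`, "is_virtual")),
              fs = sets[[1]]$fs)
}

#' Cut a recording into overlapping windows
#'
#' Slides a window of `window_ms` milliseconds over the recording with
#' `window_ms - overlap_ms` milliseconds of stride (default 256 ms windows
#' with 64 ms overlap, i.e. stride 192 ms), producing half-open windows
#' `[s, s + W)` for `s = 0, stride, 2*stride, ...` while `s + W <= n`. Each
#' window carries the angle trace over the same samples as its regression
#' target. A recording shorter than one window yields an empty segment set.
#'
#' @param rec An `emg_recording`.
#' @param window_ms Window length in milliseconds.
#' @param overlap_ms Overlap between consecutive windows in milliseconds.
#' @param stride_ms Optional explicit stride in milliseconds, overriding
#'   `window_ms - overlap_ms`.
#' @return A [segment_set()].
#' @export
#' @examples
#' rec <- gen_recording("walking", sim_config(duration_s = 1, seed = 1))
#' segs <- segment_windows(rec)
#' segs$start  # 0, 192, 384, 576
segment_windows <- function(rec, window_ms = 256, overlap_ms = 64,
                            stride_ms = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  if (window_ms <= 0 || overlap_ms <= 0) stopf("window_ms and overlap_ms must be positive")
  if (is.null(stride_ms)) {
    if (overlap_ms >= window_ms) stopf("overlap_ms must be smaller than window_ms")
    stride_ms <- window_ms - overlap_ms
  }
  W <- round(window_ms * rec$fs / 1000)
  stride <- round(stride_ms * rec$fs / 1000)
  n <- nrow(rec$emg)
  C <- ncol(rec$emg)
  starts <- if (n >= W) seq(0L, n - W, by = stride) else integer(0)
  m <- length(starts)
  x <- array(0, c(m, W, C))
  ya <- matrix(0, m, W)
  for (i in seq_len(m)) {
    idx <- starts[i] + seq_len(W)
    x[i, , ] <- rec$emg[idx, ]
    ya[i, ] <- rec$angle[idx]
  }
  segment_set(x, ya, rep(rec$cls, m), rep(rec$subject_id, m), starts, fs = rec$fs)
}

#' Augmentation configuration
#'
#' White-Gaussian-noise augmentation creates virtual windows
#' `D_v = D_o + wgn(m, n, p)` where the noise power `p` is solved per window
#' so that the signal-to-noise ratio of the augmented data equals
#' `snr_target`. The target is interpreted in dB by default
#' (`p = P_s / 10^(snr/10)`); set `snr_convention = "linear"` for
#' `p = P_s / snr`.
#'
#' @param snr_target Target signal-to-noise ratio (> 0). Default 25.
#' @param snr_convention `"dB"` or `"linear"`.
#' @param factor Total size multiple after augmentation (>= 1); the default 10
#'   yields a 10x larger dataset.
#' @param seed Integer seed for the noise draws.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(snr_target = 25, snr_convention = c("dB", "linear"),
                           factor = 10L, seed = 1L) {
  snr_convention <- match.arg(snr_convention)
  if (snr_target <= 0) stopf("snr_target must be positive")
  if (factor < 1) stopf("factor must be >= 1")
  structure(list(snr_target = snr_target, snr_convention = snr_convention,
                 factor = as.integer(factor), seed = as.integer(seed)),
            class = "augment_config")
}

#' Solve the white-noise power for a target SNR
#'
#' Given a window with signal power `P_s` (mean square over all samples and
#' channels), returns the per-sample noise power `p` such that adding white
#' Gaussian noise of that power attains the configured signal-to-noise ratio:
#' `p = P_s / snr` under the linear convention, `p = P_s / 10^(snr/10)` under
#' the dB convention.
#'
#' @param x Numeric vector, matrix or `W x C` window of signal samples.
#' @param cfg An [augment_config()].
#' @return Noise power `p` (noise variance per sample).
#' @export
#' @examples
#' solve_noise_power(matrix(5, 2, 2), augment_config(25, "linear"))  # 1
solve_noise_power <- function(x, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  ps <- mean(as.numeric(x)^2)
  if (!is.finite(ps) || ps == 0) stopf("degenerate input: window has zero signal power")
  switch(cfg$snr_convention,
         linear = ps / cfg$snr_target,
         dB = ps / 10^(cfg$snr_target / 10))
}

#' Augment windows with white Gaussian noise
#'
#' Returns the original windows plus `factor - 1` virtual copies of each,
#' every copy being the original plus fresh i.i.d. Gaussian noise whose power
#' is solved per window by [solve_noise_power()]. Virtual copies keep the
#' angle target and class label unchanged and are flagged `is_virtual`.
#' Output is deterministic given `cfg$seed`.
#'
#' @param segs A [segment_set()].
#' @param cfg An [augment_config()].
#' @return A `segment_set` with `factor * n_segments(segs)` windows: the
#'   originals first, then the virtual copies in replicate-major order.
#' @export
augment_wgn <- function(segs, cfg = augment_config()) {
  stopifnot(inherits(segs, "segment_set"), inherits(cfg, "augment_config"))
  n <- n_segments(segs)
  if (n == 0) stopf("cannot augment an empty segment set")
  if (cfg$factor == 1L) return(segs)
  d <- dim(segs$x)
  p <- vapply(seq_len(n), function(i) solve_noise_power(segs$x[i, , ], cfg), 0)
  reps <- cfg$factor - 1L
  xv <- array(0, c(n * reps, d[2], d[3]))
  with_seed(cfg$seed, {
    for (r in seq_len(reps)) {
      noise <- array(rnorm(n * d[2] * d[3]), c(n, d[2], d[3])) *
        rep(sqrt(p), times = d[2] * d[3])
      xv[(r - 1L) * n + seq_len(n), , ] <- segs$x + noise
    }
  })
  virt <- segment_set(xv,
                      segs$y_angle[rep(seq_len(n), reps), , drop = FALSE],
                      rep(segs$y_class, reps),
                      rep(segs$subject_id, reps),
                      rep(segs$start, reps),
                      is_virtual = rep(TRUE, n * reps), fs = segs$fs)
  bind_segments(segs, virt)
}

#' Random k-fold partition of segments
#'
#' Assigns every segment to exactly one of `k` folds uniformly at random
#' (sizes differ by at most one). Over the `k` cross-validation rounds each
#' segment is therefore in the test set exactly once.
#'
#' @param n_segments Number of segments to partition.
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return Object of class `fold_split` with fields `k`, `assignments`
#'   (fold index 1..k per segment) and `seed`.
#' @export
kfold_split <- function(n_segments, k = 3L, seed = 1L) {
  if (n_segments < k) stopf("need at least k = %d segments, got %d", k, n_segments)
  assignments <- integer(n_segments)
  with_seed(seed, {
    assignments[sample.int(n_segments)] <- rep_len(seq_len(k), n_segments)
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)),
            class = "fold_split")
}

#' Per-channel z-score normalization fitted on training data
#'
#' `fit_normalizer()` estimates per-channel mean and standard deviation from
#' the training segments only; `apply_normalizer()` transforms any segment set
#' with those training statistics (never the segments' own), as required to
#' avoid train/test leakage. A zero-variance channel is guarded with a small
#' epsilon and a warning.
#'
#' @param train_segs Training [segment_set()].
#' @param eps Lower bound on the standard deviation.
#' @return `fit_normalizer()` returns an object of class `normalizer` with
#'   per-channel `mean` and `sd`; `apply_normalizer()` the transformed
#'   `segment_set`.
#' @export
fit_normalizer <- function(train_segs, eps = 1e-8) {
  stopifnot(inherits(train_segs, "segment_set"), n_segments(train_segs) > 0)
  C <- dim(train_segs$x)[3]
  mu <- vapply(seq_len(C), function(c) mean(train_segs$x[, , c]), 0)
  sg <- vapply(seq_len(C), function(c) sd(as.numeric(train_segs$x[, , c])), 0)
  if (any(sg < eps)) {
    warning("zero-variance channel(s) guarded with eps: ",
            paste(which(sg < eps), collapse = ", "))
    sg <- pmax(sg, eps)
  }
  structure(list(mean = mu, sd = sg), class = "normalizer")
}

#' @rdname fit_normalizer
#' @param norm A fitted `normalizer`.
#' @param segs Segment set to transform.
#' @export
apply_normalizer <- function(norm, segs) {
  stopifnot(inherits(norm, "normalizer"), inherits(segs, "segment_set"))
  C <- dim(segs$x)[3]
  stopifnot(length(norm$mean) == C)
  out <- segs
  for (c in seq_len(C)) {
    out$x[, , c] <- (segs$x[, , c] - norm$mean[c]) / norm$sd[c]
  }
  out
}
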