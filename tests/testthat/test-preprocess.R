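make_rec <- function(n, fs = 1000) {
  recording(matrix(seq_len(n * 4) / 100, n, 4), seq_len(n) %% 120, fs = fs,
            cls = 0, cohort = "synthetic")
}

test_that("default segmentation gives 256-sample windows at stride 192", {
  segs <- segment_windows(make_rec(1000))
  expect_equal(n_segments(segs), 4)
  expect_equal(segs$start, c(0L, 192L, 384L, 576L))
  expect_equal(dim(segs$x)[2], 256)        # 256 ms at 1000 Hz
  expect_lte(dim(segs$x)[2] / 1000 * 1000, 300)  # within the real-time bound
  # targets are the angle over the same half-open index range
  expect_equal(segs$y_angle[2, ], (193:448) %% 120)
  expect_equal(segment_windows(make_rec(255)) |> n_segments(), 0)
})

test_that("segment count matches the enumeration oracle", {
  W <- 256L; stride <- 192L
  set.seed(42)
  for (n in sample(1:4000, 100)) {
    got <- n_segments(segment_windows(make_rec(max(n, 1))))
    starts <- integer(0)
    s <- 0L
    while (s + W <= n) {           # exhaustive enumeration
      starts <- c(starts, s)
      s <- s + stride
    }
    expect_identical(got, length(starts))
    if (n >= W) expect_identical(got, (n - W) %/% stride + 1L)
  }
})

test_that("noise power solves the SNR equation in both conventions", {
  x <- matrix(5, 4, 4)                       # P_s = 25
  expect_equal(solve_noise_power(x, augment_config(25, "linear")), 1)
  expect_equal(solve_noise_power(x, augment_config(25, "dB")), 25 / 10^2.5)
  # noiseless limit: infinite SNR target drives p to zero
  expect_lt(solve_noise_power(x, augment_config(1e12, "linear")), 1e-9)
  expect_error(solve_noise_power(matrix(0, 4, 4), augment_config()),
               "degenerate")
})

test_that("augmentation multiplies the set and leaves labels untouched", {
  segs <- tiny_segments(normalized = FALSE)[1:12]
  out <- augment_wgn(segs, augment_config(factor = 10, seed = 4))
  expect_equal(n_segments(out), 120)
  expect_identical(out$y_class, rep(segs$y_class, 10))
  expect_identical(out$y_angle[13:24, ], segs$y_angle)
  expect_identical(out$is_virtual, rep(c(FALSE, TRUE), c(12, 108)))
  # originals are recoverable and factor = 1 is the identity
  expect_identical(out[1:12]$x, segs$x)
  expect_identical(augment_wgn(segs, augment_config(factor = 1)), segs)
  # seeded determinism
  expect_identical(out, augment_wgn(segs, augment_config(factor = 10, seed = 4)))
})

test_that("empirical SNR of virtual copies matches the target", {
  segs <- bind_segments(lapply(gen_dataset(1, sim_config(duration_s = 10, seed = 6)),
                               segment_windows))
  n <- n_segments(segs)
  expect_gte(n, 100)
  for (conv in c("dB", "linear")) {
    aug <- augment_wgn(segs, augment_config(25, conv, factor = 2, seed = 8))
    snr <- vapply(seq_len(n), function(i) {
      po <- mean(aug$x[i, , ]^2)
      pn <- mean((aug$x[n + i, , ] - aug$x[i, , ])^2)
      if (conv == "dB") 10 * log10(po / pn) else po / pn
    }, 0)
    expect_lt(abs(mean(snr) - 25), 0.05 * 25)
  }
})

test_that("k-fold split is a balanced partition", {
  sp <- kfold_split(9, k = 3, seed = 1)
  expect_equal(sort(unique(sp$assignments)), 1:3)
  expect_equal(as.vector(table(sp$assignments)), c(3, 3, 3))
  # each segment is in the test set exactly once across the k rounds
  test_count <- rowSums(vapply(1:3, function(f) sp$assignments == f,
                               logical(9)))
  expect_true(all(test_count == 1))
  sp2 <- kfold_split(10, k = 3, seed = 2)
  expect_lte(diff(range(table(sp2$assignments))), 1)
  expect_identical(kfold_split(50, 3, seed = 5), kfold_split(50, 3, seed = 5))
  expect_error(kfold_split(2, k = 3), "at least k")
})

test_that("normalizer gives zero-mean unit-variance training channels only", {
  segs <- tiny_segments(normalized = FALSE)
  norm <- fit_normalizer(segs)
  z <- apply_normalizer(norm, segs)
  for (c in seq_len(dim(z$x)[3])) {
    expect_lt(abs(mean(z$x[, , c])), 1e-6)
    expect_lt(abs(stats::var(as.numeric(z$x[, , c])) - 1), 1e-3)
  }
  # held-out data transformed with training statistics is not its own z-score
  held <- tiny_segments(normalized = FALSE, seed = 99)[1:4]
  zh <- apply_normalizer(norm, held)
  own <- apply_normalizer(fit_normalizer(held), held)
  expect_gt(max(abs(zh$x - own$x)), 1e-3)
})

test_that("zero-variance channels are guarded with a warning", {
  segs <- tiny_segments(normalized = FALSE)[1:5]
  segs$x[, , 2] <- 5
  expect_warning(norm <- fit_normalizer(segs), "zero-variance")
  z <- apply_normalizer(norm, segs)
  expect_true(all(abs(z$x[, , 2]) < 1e-6))
  expect_true(all(is.finite(z$x)))
})
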