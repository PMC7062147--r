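# gradient and oracle checks for the compiled network kernels
ns <- asNamespace("emglrcn")

test_that("conv1d forward matches a direct loop oracle", {
  set.seed(1)
  B <- 2; T <- 9; Cin <- 3; Cout <- 2; K <- 3
  X <- array(rnorm(B * T * Cin), c(B, T, Cin))
  W <- array(rnorm(K * Cin * Cout), c(K, Cin, Cout))
  b <- rnorm(Cout)
  for (padding in c("same", "valid")) {
    Y <- ns$.conv1d_fwd(X, W, b, padding, FALSE)
    Tout <- if (padding == "same") T else T - K + 1
    half <- (K - 1) / 2
    ref <- array(0, c(B, Tout, Cout))
    for (bb in 1:B) for (t in 1:Tout) for (o in 1:Cout) {
      s <- b[o]
      for (k in 1:K) for (c in 1:Cin) {
        tt <- if (padding == "same") t + k - 1 - half else t + k - 1
        if (tt >= 1 && tt <= T) s <- s + X[bb, tt, c] * W[k, c, o]
      }
      ref[bb, t, o] <- s
    }
    expect_lt(max(abs(Y - ref)), 1e-5)
  }
})

test_that("conv1d gradients match finite differences", {
  set.seed(2)
  B <- 2; T <- 9; Cin <- 3; Cout <- 2; K <- 3
  X <- array(rnorm(B * T * Cin), c(B, T, Cin))
  W <- array(rnorm(K * Cin * Cout), c(K, Cin, Cout))
  b <- rnorm(Cout)
  for (padding in c("same", "valid")) {
    Y <- ns$.conv1d_fwd(X, W, b, padding, TRUE)
    R <- array(rnorm(length(Y)), dim(Y))
    loss <- function(X, W, b) sum(ns$.conv1d_fwd(X, W, b, padding, TRUE) * R)
    bw <- ns$.conv1d_bwd(X, W, R, Y, padding, TRUE)
    expect_lt(max_rel_err(bw$dX, num_grad(function(v) loss(array(v, dim(X)), W, b), X)), 2e-3)
    expect_lt(max_rel_err(bw$dW, num_grad(function(v) loss(X, array(v, dim(W)), b), W)), 2e-3)
    expect_lt(max_rel_err(as.numeric(bw$db), num_grad(function(v) loss(X, W, v), b)), 2e-3)
  }
})

test_that("max-pooling routes gradients to the earliest maximum", {
  set.seed(3)
  X <- array(rnorm(3 * 8 * 2), c(3, 8, 2))
  mp <- ns$.maxpool_fwd(X, 4L)
  R <- array(rnorm(length(mp$Y)), dim(mp$Y))
  bw <- ns$.maxpool_bwd(R, mp$argmax, 3L, 8L, 2L)
  ng <- num_grad(function(v) sum(ns$.maxpool_fwd(array(v, dim(X)), 4L)$Y * R), X)
  expect_lt(max_rel_err(bw, ng), 1e-6)
  # exact ties go to the first occurrence
  Xt <- array(7, c(1, 4, 1))
  mpt <- ns$.maxpool_fwd(Xt, 4L)
  expect_equal(as.integer(mpt$argmax), 1L)
})

test_that("LSTM gradients match finite differences", {
  set.seed(4)
  B <- 2; T <- 5; D <- 3; H <- 4
  X <- array(rnorm(B * T * D), c(B, T, D))
  Wx <- matrix(rnorm(D * 4 * H), D, 4 * H) * 0.5
  Wh <- matrix(rnorm(H * 4 * H), H, 4 * H) * 0.5
  b <- rnorm(4 * H) * 0.1
  fw <- ns$.lstm_fwd(X, Wx, Wh, b)
  R <- array(rnorm(B * T * H), c(B, T, H))
  bw <- ns$.lstm_bwd(X, Wx, Wh, b, fw$h, fw$c, fw$g, R)
  loss <- function(X, Wx, Wh, b) sum(ns$.lstm_fwd(X, Wx, Wh, b)$h * R)
  expect_lt(max_rel_err(bw$dX, num_grad(function(v) loss(array(v, dim(X)), Wx, Wh, b), X)), 2e-3)
  expect_lt(max_rel_err(bw$dWx, num_grad(function(v) loss(X, matrix(v, D, 4 * H), Wh, b), Wx)), 2e-3)
  expect_lt(max_rel_err(bw$dWh, num_grad(function(v) loss(X, Wx, matrix(v, H, 4 * H), b), Wh)), 2e-3)
  expect_lt(max_rel_err(as.numeric(bw$db), num_grad(function(v) loss(X, Wx, Wh, v), b)), 2e-3)
})

test_that("fused training step equals the modular reference implementation", {
  # dropout 0 so both paths consume no RNG inside the step
  segs <- tiny_segments()[1:8]
  cfg <- tiny_lrcn(dropout = 0)  # batch size 8 covers the set in one batch
  model <- build_lrcn(cfg)
  ctr <- mean(segs$y_angle)
  scl <- sd(as.numeric(segs$y_angle))
  Yt <- (segs$y_angle - ctr) / scl

  # reference: one Adam step with the modular layer path in R
  trainable <- names(model$params)[!startsWith(names(model$params), "ch.")]
  fe <- ns$fe_forward(model$params, segs$x, cfg, training = FALSE)
  ah <- ns$angle_forward(model$params, fe$feat, cfg)
  lg <- ns$reg_loss_grad(ah$pred, Yt, "mse")
  ab <- ns$angle_backward(model$params, ah$cache, lg$grad, cfg)
  grads <- c(ab$grads, ns$fe_backward(model$params, fe$cache, ab$dFeat, cfg))
  st <- ns$adam_step(model$params[trainable], grads[trainable],
                     ns$adam_init(model$params[trainable]),
                     lr = cfg$learning_rate)

  # fused C++ trainer, one epoch over the single batch
  trained <- train_angle_predictor(model, segs, epochs = 1)
  expect_equal(trained$history$angle_loss[1], lg$loss, tolerance = 1e-4)
  for (nm in trainable) {
    expect_lt(max_rel_err(trained$params[[nm]], st$params[[nm]]), 1e-3)
  }
  # classification head untouched by angle training
  expect_identical(trained$params[["ch.dense.W"]], model$params[["ch.dense.W"]])
})

test_that("batched prediction is permutation-equivariant", {
  segs <- tiny_segments()
  model <- transfer_to_classifier(
    train_angle_predictor(build_lrcn(tiny_lrcn()), segs, epochs = 2),
    segs, epochs = 2)
  perm <- sample(n_segments(segs))
  a <- predict_angle(model, segs)
  expect_equal(predict_angle(model, segs[perm]), a[perm, ], tolerance = 1e-5)
  pm <- predict_movement(model, segs)
  pmp <- predict_movement(model, segs[perm])
  expect_equal(pmp$probs, pm$probs[perm, ], tolerance = 1e-5)
})
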