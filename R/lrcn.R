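#' LRCN architecture and training configuration
#'
#' Architecture of the three-block network: a convolutional feature extractor
#' (four per-channel branches of conv(20 filters, 11x1, stride 1) + ReLU +
#' 4x1 max-pooling + dropout, concatenated and passed through one more such
#' conv stage), an angle head (two stacked LSTM layers of 32 and 64 units,
#' the second layer's final hidden state feeding a linear dense layer with
#' one output per window sample), and a classification head (flatten + dense
#' + softmax over the three movements). With the default window of 256
#' samples and 'same' padding, the pooled feature map is 16 x 20, the angle
#' dense layer has 64 x 256 + 256 = 16640 parameters and the classification
#' dense layer 320 x 3 + 3 = 963.
#'
#' @param window Input window length W in samples; the angle output has the
#'   same length.
#' @param n_channels Number of sEMG input channels.
#' @param n_filters Filters per convolutional layer.
#' @param kernel Convolution kernel length (11x1).
#' @param pool Max-pooling size (4x1).
#' @param dropout Dropout probability after each pooling layer (training only).
#' @param lstm_units Hidden sizes of the two stacked LSTM layers.
#' @param n_classes Number of movement classes.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param padding Convolution padding, `"same"` (default) or `"valid"`. Under
#'   `"valid"` the window must keep the pooling chain integral.
#' @param loss Regression loss for angle training, `"mse"` (default) or
#'   `"mae"`.
#' @param seed Master seed fanned out to initialization, shuffling and
#'   dropout.
#' @return Object of class `lrcn_config`.
#' @export
lrcn_config <- function(window = 256L, n_channels = 4L, n_filters = 20L,
                        kernel = 11L, pool = 4L, dropout = 0.5,
                        lstm_units = c(32L, 64L), n_classes = 3L,
                        batch_size = 25L, epochs = 70L, learning_rate = 0.001,
                        padding = c("same", "valid"), loss = c("mse", "mae"),
                        seed = 1L) {
  padding <- match.arg(padding)
  loss <- match.arg(loss)
  stopifnot(window > 0, n_channels > 0, n_filters > 0, kernel > 0, pool > 1,
            batch_size > 0, epochs >= 0, learning_rate > 0,
            length(lstm_units) == 2, all(lstm_units > 0), n_classes > 1)
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (kernel %% 2 == 0 && padding == "same") {
    stopf("'same' padding requires an odd kernel length")
  }
  cfg <- structure(list(
    window = as.integer(window), n_channels = as.integer(n_channels),
    n_filters = as.integer(n_filters), kernel = as.integer(kernel),
    stride = 1L, pool = as.integer(pool), dropout = dropout,
    lstm_units = as.integer(lstm_units), n_classes = as.integer(n_classes),
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    learning_rate = learning_rate, optimizer = "adam", padding = padding,
    loss = loss, seed = as.integer(seed)
  ), class = "lrcn_config")
  lrcn_shapes(cfg)  # errors early if the pooling chain is not integral
  cfg
}

#' Feature-map shapes implied by a configuration
#'
#' @param cfg An [lrcn_config()].
#' @return List with the per-branch feature-map length after the first pool
#'   (`t1`), the length after the second conv stage's pool (`t2`), the flatten
#'   size feeding the classification head, and the parameter counts of the two
#'   dense layers.
#' @export
lrcn_shapes <- function(cfg) {
  conv_len <- function(t) if (cfg$padding == "same") t else t - cfg$kernel + 1L
  pool_len <- function(t) {
    if (t < 1) stopf("window too short for the convolution/pooling chain")
    if (t %% cfg$pool != 0) {
      stopf("feature-map length %d is not divisible by pool size %d under '%s' padding",
            t, cfg$pool, cfg$padding)
    }
    t %/% cfg$pool
  }
  t1 <- pool_len(conv_len(cfg$window))
  t2 <- pool_len(conv_len(t1))
  flatten <- t2 * cfg$n_filters
  list(t1 = t1, t2 = t2, flatten = flatten,
       angle_dense_params = cfg$lstm_units[2] * cfg$window + cfg$window,
       class_dense_params = flatten * cfg$n_classes + cfg$n_classes)
}

#' Build an untrained LRCN model
#'
#' Initializes all weights (Glorot-uniform, LSTM forget bias 1) from
#' `cfg$seed`; the same configuration always yields identical initial
#' weights. Parameters are organized in three named blocks accessible via
#' [model_blocks()]: `feature_extractor`, `angle_head`,
#' `classification_head`.
#'
#' @param cfg An [lrcn_config()].
#' @return Object of class `lrcn_model` with `training_stage = "untrained"`.
#' @export
build_lrcn <- function(cfg = lrcn_config()) {
  stopifnot(inherits(cfg, "lrcn_config"))
  K <- cfg$kernel; Fm <- cfg$n_filters
  sh <- lrcn_shapes(cfg)
  with_seed(cfg$seed, {
    params <- list()
    for (c in seq_len(cfg$n_channels)) {
      params[[sprintf("fe.br%d.W", c)]] <- glorot(c(K, 1, Fm), K, K * Fm)
      params[[sprintf("fe.br%d.b", c)]] <- numeric(Fm)
    }
    cin2 <- cfg$n_channels * Fm
    params[["fe.conv2.W"]] <- glorot(c(K, cin2, Fm), K * cin2, K * Fm)
    params[["fe.conv2.b"]] <- numeric(Fm)
    l1 <- lstm_init(Fm, cfg$lstm_units[1])
    params[["ah.lstm1.Wx"]] <- l1$Wx; params[["ah.lstm1.Wh"]] <- l1$Wh
    params[["ah.lstm1.b"]] <- l1$b
    l2 <- lstm_init(cfg$lstm_units[1], cfg$lstm_units[2])
    params[["ah.lstm2.Wx"]] <- l2$Wx; params[["ah.lstm2.Wh"]] <- l2$Wh
    params[["ah.lstm2.b"]] <- l2$b
    params[["ah.dense.W"]] <- glorot(c(cfg$lstm_units[2], cfg$window),
                                     cfg$lstm_units[2], cfg$window)
    params[["ah.dense.b"]] <- numeric(cfg$window)
    params[["ch.dense.W"]] <- glorot(c(sh$flatten, cfg$n_classes),
                                     sh$flatten, cfg$n_classes)
    params[["ch.dense.b"]] <- numeric(cfg$n_classes)
    structure(list(cfg = cfg, params = params, training_stage = "untrained",
                   target_center = NA_real_, target_scale = NA_real_,
                   history = list()),
              class = "lrcn_model")
  })
}

#' @export
print.lrcn_model <- function(x, ...) {
  sh <- lrcn_shapes(x$cfg)
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<lrcn_model> stage: %s | window %d x %d channels | %d parameters\n",
              x$training_stage, x$cfg$window, x$cfg$n_channels, np))
  cat(sprintf("  feature maps: branch %d x %d -> concat %d x %d -> %d x %d (flatten %d)\n",
              sh$t1, x$cfg$n_filters, sh$t1, x$cfg$n_channels * x$cfg$n_filters,
              sh$t2, x$cfg$n_filters, sh$flatten))
  invisible(x)
}

#' Named weight blocks of a model
#'
#' @param model An `lrcn_model`.
#' @return List with elements `feature_extractor`, `angle_head` and
#'   `classification_head`, each a named list of weight arrays.
#' @export
model_blocks <- function(model) {
  stopifnot(inherits(model, "lrcn_model"))
  nm <- names(model$params)
  list(feature_extractor = model$params[startsWith(nm, "fe.")],
       angle_head = model$params[startsWith(nm, "ah.")],
       classification_head = model$params[startsWith(nm, "ch.")])
}

# ---- forward / backward ----------------------------------------------------

# feature extractor forward; returns features (B, t2, F) and a cache for
# backprop. Dropout draws come from the current RNG stream when training.
fe_forward <- function(params, X, cfg, training = FALSE) {
  B <- dim(X)[1]
  Fm <- cfg$n_filters
  branches <- vector("list", cfg$n_channels)
  pooled <- vector("list", cfg$n_channels)
  for (c in seq_len(cfg$n_channels)) {
    Xc <- X[, , c, drop = FALSE]
    act <- .conv1d_fwd(Xc, params[[sprintf("fe.br%d.W", c)]],
                       params[[sprintf("fe.br%d.b", c)]], cfg$padding, TRUE)
    mp <- .maxpool_fwd(act, cfg$pool)
    mask <- if (training) dropout_mask(dim(mp$Y), cfg$dropout) else NULL
    out <- if (is.null(mask)) mp$Y else mp$Y * mask
    branches[[c]] <- list(Xc = Xc, act = act, argmax = mp$argmax, mask = mask)
    pooled[[c]] <- out
  }
  t1 <- dim(pooled[[1]])[2]
  concat <- array(unlist(pooled, use.names = FALSE),
                  c(B, t1, cfg$n_channels * Fm))
  act2 <- .conv1d_fwd(concat, params[["fe.conv2.W"]], params[["fe.conv2.b"]],
                      cfg$padding, TRUE)
  mp2 <- .maxpool_fwd(act2, cfg$pool)
  mask2 <- if (training) dropout_mask(dim(mp2$Y), cfg$dropout) else NULL
  feat <- if (is.null(mask2)) mp2$Y else mp2$Y * mask2
  list(feat = feat,
       cache = list(branches = branches, concat = concat, act2 = act2,
                    argmax2 = mp2$argmax, mask2 = mask2))
}

fe_backward <- function(params, cache, dFeat, cfg) {
  grads <- list()
  if (!is.null(cache$mask2)) dFeat <- dFeat * cache$mask2
  d2 <- dim(cache$act2)
  dAct2 <- .maxpool_bwd(dFeat, cache$argmax2, d2[1], d2[2], d2[3])
  bw2 <- .conv1d_bwd(cache$concat, params[["fe.conv2.W"]], dAct2, cache$act2,
                     cfg$padding, TRUE)
  grads[["fe.conv2.W"]] <- bw2$dW
  grads[["fe.conv2.b"]] <- as.numeric(bw2$db)
  Fm <- cfg$n_filters
  for (c in seq_len(cfg$n_channels)) {
    br <- cache$branches[[c]]
    dP <- bw2$dX[, , (c - 1L) * Fm + seq_len(Fm), drop = FALSE]
    if (!is.null(br$mask)) dP <- dP * br$mask
    d1 <- dim(br$act)
    dAct <- .maxpool_bwd(dP, br$argmax, d1[1], d1[2], d1[3])
    bw <- .conv1d_bwd(br$Xc, params[[sprintf("fe.br%d.W", c)]], dAct, br$act,
                      cfg$padding, FALSE)
    grads[[sprintf("fe.br%d.W", c)]] <- bw$dW
    grads[[sprintf("fe.br%d.b", c)]] <- as.numeric(bw$db)
  }
  grads
}

angle_forward <- function(params, feat, cfg) {
  l1 <- .lstm_fwd(feat, params[["ah.lstm1.Wx"]], params[["ah.lstm1.Wh"]],
                  params[["ah.lstm1.b"]])
  l2 <- .lstm_fwd(l1$h, params[["ah.lstm2.Wx"]], params[["ah.lstm2.Wh"]],
                  params[["ah.lstm2.b"]])
  T2 <- dim(feat)[2]
  hT <- matrix(l2$h[, T2, ], dim(feat)[1], cfg$lstm_units[2])
  pred <- hT %*% params[["ah.dense.W"]] +
    matrix(params[["ah.dense.b"]], nrow(hT), cfg$window, byrow = TRUE)
  list(pred = pred, cache = list(l1 = l1, l2 = l2, hT = hT, feat = feat))
}

angle_backward <- function(params, cache, dPred, cfg) {
  grads <- list()
  grads[["ah.dense.W"]] <- crossprod(cache$hT, dPred)
  grads[["ah.dense.b"]] <- colSums(dPred)
  dhT <- dPred %*% t(params[["ah.dense.W"]])
  d <- dim(cache$feat)
  dH2 <- array(0, c(d[1], d[2], cfg$lstm_units[2]))
  dH2[, d[2], ] <- dhT
  bw2 <- .lstm_bwd(cache$l1$h, params[["ah.lstm2.Wx"]], params[["ah.lstm2.Wh"]],
                   params[["ah.lstm2.b"]], cache$l2$h, cache$l2$c, cache$l2$g,
                   dH2)
  grads[["ah.lstm2.Wx"]] <- bw2$dWx
  grads[["ah.lstm2.Wh"]] <- bw2$dWh
  grads[["ah.lstm2.b"]] <- as.numeric(bw2$db)
  bw1 <- .lstm_bwd(cache$feat, params[["ah.lstm1.Wx"]], params[["ah.lstm1.Wh"]],
                   params[["ah.lstm1.b"]], cache$l1$h, cache$l1$c, cache$l1$g,
                   bw2$dX)
  grads[["ah.lstm1.Wx"]] <- bw1$dWx
  grads[["ah.lstm1.Wh"]] <- bw1$dWh
  grads[["ah.lstm1.b"]] <- as.numeric(bw1$db)
  list(grads = grads, dFeat = bw1$dX)
}

class_logits <- function(params, feat) {
  B <- dim(feat)[1]
  flat <- matrix(feat, B, dim(feat)[2] * dim(feat)[3])
  flat %*% params[["ch.dense.W"]] +
    matrix(params[["ch.dense.b"]], B, length(params[["ch.dense.b"]]),
           byrow = TRUE)
}

# eval-mode feature extraction over all segments, in batches
extract_features <- function(model, segs, batch = 128L) {
  n <- n_segments(segs)
  sh <- lrcn_shapes(model$cfg)
  out <- array(0, c(n, sh$t2, model$cfg$n_filters))
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch - 1L)
    out[idx, , ] <- fe_forward(model$params, segs$x[idx, , , drop = FALSE],
                               model$cfg, training = FALSE)$feat
    at <- at + batch
  }
  out
}

# ---- training operations ---------------------------------------------------

#' Train the feature extractor and angle head end to end
#'
#' First training stage: the feature extractor and the LSTM angle head are
#' optimized jointly by minibatch gradient descent (Adam, learning rate
#' 0.001, batch size 25, 70 epochs by default) on a regression loss between
#' the predicted and actual per-window angle sequence. Angle targets are
#' standardized internally with statistics stored in the model, so
#' [predict_angle()] returns degrees. Per-epoch training loss is recorded in
#' `model$history$angle_loss`. With a fixed seed and single-threaded BLAS the
#' loss trajectory is reproducible. `epochs = 0` returns the model unchanged.
#'
#' @param model An `lrcn_model` with stage `"untrained"` or `"angle_trained"`.
#' @param segs Normalized training [segment_set()].
#' @param epochs Number of epochs; defaults to `model$cfg$epochs`.
#' @param verbose Print one line per epoch.
#' @return The trained model with `training_stage = "angle_trained"`.
#' @export
train_angle_predictor <- function(model, segs, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "lrcn_model"), inherits(segs, "segment_set"))
  if (!model$training_stage %in% c("untrained", "angle_trained")) {
    stopf("angle training requires an untrained or angle_trained model, got '%s'",
          model$training_stage)
  }
  n <- n_segments(segs)
  if (n == 0) stopf("empty training set")
  if (dim(segs$x)[2] != model$cfg$window) {
    stopf("segment window %d does not match model window %d",
          dim(segs$x)[2], model$cfg$window)
  }
  if (is.null(epochs)) epochs <- model$cfg$epochs
  if (epochs == 0) return(model)
  cfg <- model$cfg
  if (is.na(model$target_center)) {
    model$target_center <- mean(segs$y_angle)
    model$target_scale <- max(sd(as.numeric(segs$y_angle)), 1e-6)
  }
  Yt <- (segs$y_angle - model$target_center) / model$target_scale
  res <- with_seed(cfg$seed + 1000L, {
    perms <- vapply(seq_len(epochs), function(i) sample.int(n), integer(n))
    .lrcn_train_angle(model$params, segs$x, Yt, perms, cfg$batch_size,
                      cfg$learning_rate, cfg$dropout, cfg$padding, cfg$pool,
                      cfg$kernel, cfg$n_filters, cfg$lstm_units[1],
                      cfg$lstm_units[2], cfg$loss)
  })
  if (isTRUE(res$error)) {
    stopf("non-finite angle loss at epoch %d, batch starting %d (diverged; lower the learning rate or check inputs)",
          res$epoch, res$batch)
  }
  model$params <- res$params
  losses <- as.numeric(res$losses)
  if (verbose) {
    for (ep in seq_len(epochs)) message(sprintf("epoch %d, loss %.5f", ep, losses[ep]))
  }
  model$history$angle_loss <- c(model$history$angle_loss, losses)
  model$training_stage <- "angle_trained"
  model
}

#' Transfer the trained feature extractor to the movement classifier
#'
#' Second training stage: the feature extractor learned during angle
#' regression is frozen (its weights are bit-identical before and after this
#' call) and only the classification head (flatten + dense + softmax) is
#' fitted with cross-entropy. Because the extractor is frozen, its features
#' are computed once in inference mode and the head is trained on them.
#'
#' @param model An `lrcn_model` with `training_stage = "angle_trained"`.
#' @param segs Normalized training [segment_set()] with class labels.
#' @param epochs Number of epochs; defaults to `model$cfg$epochs`.
#' @param verbose Print one line per epoch.
#' @return The model with `training_stage = "transfer_complete"`.
#' @export
transfer_to_classifier <- function(model, segs, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "lrcn_model"), inherits(segs, "segment_set"))
  if (!identical(model$training_stage, "angle_trained")) {
    stopf("transfer learning requires an angle_trained model, got '%s'",
          model$training_stage)
  }
  n <- n_segments(segs)
  if (n == 0) stopf("empty training set")
  if (is.null(epochs)) epochs <- model$cfg$epochs
  cfg <- model$cfg
  feat <- extract_features(model, segs)
  flat <- matrix(feat, n, dim(feat)[2] * dim(feat)[3])
  head <- model$params[c("ch.dense.W", "ch.dense.b")]
  opt <- adam_init(head)
  losses <- numeric(epochs)
  with_seed(cfg$seed + 2000L, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      bl <- 0
      nb <- 0L
      for (at in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[at:min(n, at + cfg$batch_size - 1L)]
        fb <- flat[idx, , drop = FALSE]
        logits <- fb %*% head[["ch.dense.W"]] +
          matrix(head[["ch.dense.b"]], length(idx), cfg$n_classes, byrow = TRUE)
        lg <- xent_loss_grad(logits, segs$y_class[idx])
        if (!is.finite(lg$loss)) {
          stopf("non-finite classification loss at epoch %d, batch starting %d",
                ep, at)
        }
        grads <- list("ch.dense.W" = crossprod(fb, lg$grad),
                      "ch.dense.b" = colSums(lg$grad))
        st <- adam_step(head, grads, opt, lr = cfg$learning_rate)
        head <- st$params
        opt <- st$state
        bl <- bl + lg$loss
        nb <- nb + 1L
      }
      losses[ep] <- bl / nb
      if (verbose) message(sprintf("epoch %d, class loss %.5f", ep, losses[ep]))
    }
  })
  model$params[c("ch.dense.W", "ch.dense.b")] <- head
  model$history$class_loss <- c(model$history$class_loss, losses)
  model$training_stage <- "transfer_complete"
  model
}

#' Predict per-window knee angle sequences
#'
#' @param model An `lrcn_model` trained at least through the angle stage.
#' @param segs Normalized [segment_set()].
#' @param batch Internal batch size for inference.
#' @return Numeric matrix `n x W` of predicted angles in degrees, rows in
#'   input order.
#' @export
predict_angle <- function(model, segs, batch = 128L) {
  stopifnot(inherits(model, "lrcn_model"), inherits(segs, "segment_set"))
  if (model$training_stage == "untrained") {
    stopf("angle prediction requires a trained model")
  }
  n <- n_segments(segs)
  out <- matrix(0, n, model$cfg$window)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch - 1L)
    fe <- fe_forward(model$params, segs$x[idx, , , drop = FALSE], model$cfg,
                     training = FALSE)
    out[idx, ] <- angle_forward(model$params, fe$feat, model$cfg)$pred
    at <- at + batch
  }
  out * model$target_scale + model$target_center
}

#' Classify movements
#'
#' @param model An `lrcn_model` with `training_stage = "transfer_complete"`.
#' @param segs Normalized [segment_set()].
#' @param batch Internal batch size for inference.
#' @return List with `labels` (0-based integer class codes; argmax with
#'   lowest-index tie-break) and `probs` (`n x 3` softmax rows summing to 1).
#' @export
predict_movement <- function(model, segs, batch = 128L) {
  stopifnot(inherits(model, "lrcn_model"), inherits(segs, "segment_set"))
  if (!identical(model$training_stage, "transfer_complete")) {
    stopf("movement classification requires a transfer_complete model, got '%s'",
          model$training_stage)
  }
  feat <- extract_features(model, segs, batch = batch)
  probs <- softmax_rows(class_logits(model$params, feat))
  labels <- max.col(probs, ties.method = "first") - 1L
  list(labels = labels, probs = probs)
}
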