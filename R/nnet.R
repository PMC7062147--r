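# R-side neural-network plumbing around the compiled kernels: dropout, losses,
# parameter initialization and Adam. All parameters live in a flat named list;
# block membership is encoded in the name prefix (fe. / ah. / ch.).

# inverted dropout; draws from the current RNG stream
dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dims)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy of softmax probabilities against 0-based labels;
# gradient w.r.t. logits is (p - onehot)/B
xent_loss_grad <- function(logits, labels) {
  B <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / B)
}

# regression loss over all elements of a B x W prediction
reg_loss_grad <- function(pred, target, kind = "mse") {
  n <- length(pred)
  e <- pred - target
  if (kind == "mse") {
    list(loss = mean(e^2), grad = 2 * e / n)
  } else {
    list(loss = mean(abs(e)), grad = sign(e) / n)
  }
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

lstm_init <- function(d_in, h) {
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias at 1 stabilizes early training
  list(Wx = glorot(c(d_in, 4 * h), d_in, h),
       Wh = glorot(c(h, 4 * h), h, h),
       b = b)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim1(p))),
       v = lapply(params, function(p) array(0, dim1(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
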