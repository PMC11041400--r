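# Internal neural-network primitives.
#
# All layers operate on batches stored as dense arrays:
#   sequence tensors  [N, T, C]   (batch, time, feature channels)
#   state matrices    [N, H]
# The convolution, pooling and LSTM kernels live in src/nn_kernels.cpp
# (single-threaded RcppArmadillo, deterministic); slow but transparent
# pure-R reference forwards (`*_ref`) are kept for the property tests.

# ---- 1-D convolution (same padding, odd kernel) ---------------------------

conv1d_fwd <- function(X, W, b) {
  r <- .cpp_conv1d_fwd(X, W, b)
  list(out = r$out, X = X)
}

conv1d_bwd <- function(cache, W, dY, need_dx = TRUE) {
  r <- .cpp_conv1d_bwd(cache$X, W, dY, need_dx)
  list(dX = r$dX, dW = r$dW, db = as.numeric(r$db))
}

# Reference forward: direct triple loop over output positions.
conv1d_fwd_ref <- function(X, W, b) {
  d <- dim(X); N <- d[1]; Tn <- d[2]; Cin <- d[3]
  Fo <- ncol(W); k <- nrow(W) / Cin; P <- (k - 1) / 2
  Y <- array(0, c(N, Tn, Fo))
  for (t in seq_len(Tn)) {
    for (dd in seq_len(k)) {
      src <- t + dd - 1 - P
      if (src < 1 || src > Tn) next
      Xs <- X[, src, , drop = FALSE]; dim(Xs) <- c(N, Cin)
      Y[, t, ] <- Y[, t, ] + Xs %*% W[((dd - 1) * Cin + 1):(dd * Cin), ,
                                      drop = FALSE]
    }
    Y[, t, ] <- Y[, t, ] + rep(b, each = N)
  }
  Y
}

# ---- max pooling over time (width 2, stride 2) ----------------------------

pool2_fwd <- function(X) {
  if (dim(X)[2] < 2L) return(list(out = X, identity = TRUE))
  r <- .cpp_pool2_fwd(X)
  list(out = r$out, mask = r$mask, Tin = dim(X)[2], identity = FALSE)
}

pool2_bwd <- function(cache, dY) {
  if (isTRUE(cache$identity)) return(dY)
  .cpp_pool2_bwd(cache$mask, cache$Tin, dY)
}

pool2_fwd_ref <- function(X) {
  d <- dim(X); T2 <- d[2] %/% 2L
  if (T2 < 1L) return(X)
  A <- X[, seq(1, 2 * T2, by = 2), , drop = FALSE]
  B <- X[, seq(2, 2 * T2, by = 2), , drop = FALSE]
  M <- (A >= B) * 1
  A * M + B * (1 - M)
}

# ---- LSTM (returns the final hidden state) --------------------------------
# Gate order in the 4H blocks: input, forget, cell, output.

sigm <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(X, Wx, Wh, b) {
  r <- .cpp_lstm_fwd(X, Wx, Wh, b)
  list(h = r$h, X = X, G = r$G, C = r$C, TC = r$TC)
}

lstm_bwd <- function(cache, Wx, Wh, dh_last) {
  r <- .cpp_lstm_bwd(cache$X, Wx, Wh, cache$G, cache$C, cache$TC, dh_last)
  list(dX = r$dX, dWx = r$dWx, dWh = r$dWh, db = as.numeric(r$db))
}

lstm_fwd_ref <- function(X, Wx, Wh, b) {
  d <- dim(X); N <- d[1]; Tn <- d[2]; D <- d[3]
  H <- ncol(Wh) / 4
  h <- matrix(0, N, H); cs <- matrix(0, N, H)
  for (t in seq_len(Tn)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(N, D)
    Z <- xt %*% Wx + h %*% Wh + rep(b, each = N)
    i <- sigm(Z[, 1:H, drop = FALSE])
    f <- sigm(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigm(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    cs <- f * cs + i * g
    h <- o * tanh(cs)
  }
  h
}

# ---- softmax cross-entropy -------------------------------------------------

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_xent <- function(logits, yidx) {
  N <- nrow(logits)
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(N), yidx)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(N), yidx)] <- dlogits[cbind(seq_len(N), yidx)] - 1
  list(loss = loss, probs = p, dlogits = dlogits / N)
}

# ---- parameter initialization ---------------------------------------------
# He-style for convolutions and dense layers; uniform(-1/sqrt(H), 1/sqrt(H))
# for the LSTM with a +1 forget-gate bias. Draws come from R's global RNG,
# which build_classifier seeds.

init_conv <- function(k, cin, f) {
  list(W = matrix(stats::rnorm(k * cin * f, sd = sqrt(2 / (k * cin))),
                  k * cin, f),
       b = numeric(f))
}

init_dense <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

init_lstm <- function(din, h) {
  r <- 1 / sqrt(h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1
  list(Wx = matrix(stats::runif(din * 4 * h, -r, r), din, 4 * h),
       Wh = matrix(stats::runif(h * 4 * h, -r, r), h, 4 * h),
       b = b)
}

params_flatten <- function(params) unlist(params, use.names = FALSE)

params_unflatten <- function(flat, skeleton) utils::relist(flat, skeleton)

# ---- Adam ------------------------------------------------------------------
# Moment estimates mirror the (two-level: layer -> leaf) parameter
# structure, so no flatten/relist happens in the hot loop.

adam_init <- function(params) {
  zeros <- lapply(params, function(layer) lapply(layer, function(x) x * 0))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (layer in names(params)) {
    for (leaf in names(params[[layer]])) {
      g <- grads[[layer]][[leaf]]
      m <- beta1 * state$m[[layer]][[leaf]] + (1 - beta1) * g
      v <- beta2 * state$v[[layer]][[leaf]] + (1 - beta2) * g^2
      state$m[[layer]][[leaf]] <- m
      state$v[[layer]][[leaf]] <- v
      params[[layer]][[leaf]] <- params[[layer]][[leaf]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(params = params, state = state)
}
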