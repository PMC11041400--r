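#' Classifier architecture specification
#'
#' Two variants are supported. `simple` is a fixed-dimension CNN-LSTM:
#' stacked 1-D temporal convolution blocks over the fixed
#' (input_channels x window_len) input, a long short-term memory layer,
#' a dense layer and a softmax class output. `dana` is the
#' dimension-adaptive variant: the convolution blocks share their
#' filters across sensor channels and run on variable (C x T) input, a
#' dimension-adaptive pooling layer maps the feature map to a fixed
#' (channel-bins x time-bins) grid, and the same recurrent head follows.
#' The `dana` variant therefore accepts any sampling rate at or below
#' the native one and any non-empty sensor subset.
#'
#' @param variant `"simple"` or `"dana"`.
#' @param n_classes number of activity classes (default 6).
#' @param input_channels input channel count (fixed for `simple`,
#'   maximal for `dana`; default 6).
#' @param window_len fixed window length in samples for `simple`
#'   (default 128).
#' @param conv_blocks list of `c(filters, kernel_len)` pairs.
#' @param recurrent_units LSTM hidden units.
#' @param dense_units units of the dense layer after the LSTM.
#' @param dropout_rate dropout fraction applied after the recurrent
#'   layer during training.
#' @param dap a [dap_spec()]; required for (and only for) `dana`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(variant = c("simple", "dana"), n_classes = 6L,
                       input_channels = 6L, window_len = 128L,
                       conv_blocks = list(c(64L, 5L), c(64L, 5L)),
                       recurrent_units = 64L, dense_units = 64L,
                       dropout_rate = 0.25,
                       dap = if (variant == "dana") dap_spec() else NULL) {
  variant <- match.arg(variant)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (variant == "simple" && !is.null(dap)) {
    stop("the simple variant has no dimension-adaptive pooling layer",
         call. = FALSE)
  }
  if (variant == "dana" && is.null(dap)) {
    stop("the dana variant requires a dap_spec", call. = FALSE)
  }
  for (bl in conv_blocks) {
    if (length(bl) != 2 || any(bl < 1) || bl[2] %% 2 == 0) {
      stop("conv_blocks entries must be c(filters, odd kernel_len)",
           call. = FALSE)
    }
  }
  structure(list(variant = variant, n_classes = as.integer(n_classes),
                 input_channels = as.integer(input_channels),
                 window_len = as.integer(window_len),
                 conv_blocks = lapply(conv_blocks, as.integer),
                 recurrent_units = as.integer(recurrent_units),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 dap = dap),
            class = "model_spec")
}

#' Build an untrained classifier
#'
#' Parameter initialization is fully reproducible from `seed`.
#'
#' @param spec a [model_spec()].
#' @param seed integer RNG seed for weight initialization.
#' @return A `har_classifier` with untrained weights, no normalization
#'   statistics and the canonical class order.
#' @export
build_classifier <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- withr::with_seed(seed, init_params(spec))
  structure(list(spec = spec, params = params, stats = NULL,
                 class_order = activity_codes()[seq_len(spec$n_classes)],
                 history = NULL),
            class = "har_classifier")
}

#' @keywords internal
init_params <- function(spec) {
  cin <- if (spec$variant == "simple") spec$input_channels else 1L
  convs <- list()
  for (i in seq_along(spec$conv_blocks)) {
    bl <- spec$conv_blocks[[i]]
    convs[[i]] <- init_conv(bl[2], cin, bl[1])
    cin <- bl[1]
  }
  names(convs) <- paste0("conv", seq_along(convs))
  f_last <- spec$conv_blocks[[length(spec$conv_blocks)]][1]
  lstm_in <- if (spec$variant == "simple") f_last
             else f_last * spec$dap$out_channel_bins
  c(convs,
    list(lstm = init_lstm(lstm_in, spec$recurrent_units),
         dense = init_dense(spec$recurrent_units, spec$dense_units),
         out = init_dense(spec$dense_units, spec$n_classes)))
}

#' Total trainable parameter count
#' @param model a har_classifier (or a model_spec).
#' @export
param_count <- function(model) {
  params <- if (inherits(model, "har_classifier")) model$params
            else withr::with_seed(1L, init_params(model))
  length(params_flatten(params))
}

#' @export
print.har_classifier <- function(x, ...) {
  cat(sprintf("<har_classifier> %s variant, %d classes, %d parameters%s\n",
              x$spec$variant, x$spec$n_classes, param_count(x),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

# Convolution stack: fused conv -> relu -> maxpool(2) blocks (C++).
conv_stack_fwd <- function(params, spec, X) {
  caches <- list()
  for (i in seq_along(spec$conv_blocks)) {
    p <- params[[paste0("conv", i)]]
    r <- .cpp_conv_block_fwd(X, p$W, p$b)
    caches[[i]] <- list(X = X, relu_mask = r$relu_mask,
                        pool_mask = r$pool_mask %||% matrix(0L, 0, 0),
                        pooled = r$pooled)
    X <- r$out
  }
  list(out = X, caches = caches)
}

conv_stack_bwd <- function(params, spec, caches, dY) {
  grads <- list()
  for (i in rev(seq_along(spec$conv_blocks))) {
    cc <- caches[[i]]
    # the data gradient of the first block feeds nothing: skip it
    g <- .cpp_conv_block_bwd(cc$X, params[[paste0("conv", i)]]$W,
                             cc$relu_mask, cc$pool_mask, cc$pooled, dY,
                             i > 1L)
    grads[[paste0("conv", i)]] <- list(W = g$dW, b = as.numeric(g$db))
    dY <- g$dX
  }
  list(grads = grads, dX = dY)
}

# Head: (dropout) -> dense+relu -> linear -> logits
head_fwd <- function(params, h, train, dropout_rate) {
  if (train && dropout_rate > 0) {
    keep <- 1 - dropout_rate
    M <- matrix(stats::runif(length(h)) < keep, nrow(h), ncol(h)) / keep
    hd <- h * M
  } else {
    M <- NULL
    hd <- h
  }
  Z1 <- sweep(hd %*% params$dense$W, 2, params$dense$b, "+")
  A1 <- Z1 * (Z1 > 0)
  logits <- sweep(A1 %*% params$out$W, 2, params$out$b, "+")
  list(logits = logits, hd = hd, M = M, Z1 = Z1, A1 = A1)
}

head_bwd <- function(params, cache, dlogits) {
  dWo <- crossprod(cache$A1, dlogits)
  dbo <- colSums(dlogits)
  dA1 <- dlogits %*% t(params$out$W)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dWd <- crossprod(cache$hd, dZ1)
  dbd <- colSums(dZ1)
  dh <- dZ1 %*% t(params$dense$W)
  if (!is.null(cache$M)) dh <- dh * cache$M
  list(grads = list(dense = list(W = dWd, b = dbd),
                    out = list(W = dWo, b = dbo)),
       dh = dh)
}

# Full forward pass. X is [N, T, C]; for dana, C may be any subset size.
model_fwd <- function(params, spec, X, train = FALSE) {
  d <- dim(X); N <- d[1]; Tn <- d[2]; Cn <- d[3]
  if (spec$variant == "simple") {
    if (Cn != spec$input_channels || Tn != spec$window_len) {
      stop(sprintf(
        "shape error: simple variant requires fixed %d x %d input, got %d x %d",
        spec$input_channels, spec$window_len, Cn, Tn), call. = FALSE)
    }
    cs <- conv_stack_fwd(params, spec, X)
    lc <- lstm_fwd(cs$out, params$lstm$Wx, params$lstm$Wh, params$lstm$b)
    hc <- head_fwd(params, lc$h, train, spec$dropout_rate)
    list(logits = hc$logits, conv = cs, lstm = lc, head = hc, dims = d)
  } else {
    # shared filters across sensor channels: fold channels into the batch
    Xp <- aperm(X, c(1, 3, 2))            # [N, C, T]
    dim(Xp) <- c(N * Cn, Tn)
    Xc <- array(Xp, c(N * Cn, Tn, 1))
    cs <- conv_stack_fwd(params, spec, Xc)
    dp <- dap_fwd(cs$out, N, Cn, spec$dap)
    lc <- lstm_fwd(dp$out, params$lstm$Wx, params$lstm$Wh, params$lstm$b)
    hc <- head_fwd(params, lc$h, train, spec$dropout_rate)
    list(logits = hc$logits, conv = cs, dap = dp, lstm = lc, head = hc,
         dims = d)
  }
}

model_bwd <- function(params, spec, fw, dlogits) {
  hb <- head_bwd(params, fw$head, dlogits)
  lb <- lstm_bwd(fw$lstm, params$lstm$Wx, params$lstm$Wh, hb$dh)
  grads <- c(hb$grads,
             list(lstm = list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)))
  if (spec$variant == "simple") {
    cb <- conv_stack_bwd(params, spec, fw$conv$caches, lb$dX)
  } else {
    dmap <- dap_bwd(fw$dap, lb$dX)
    cb <- conv_stack_bwd(params, spec, fw$conv$caches, dmap)
  }
  grads <- c(grads, cb$grads)
  grads[names(params)]
}

# DAP over a batched feature map Y [N*C, Tp, F] -> LSTM input [N, Tb, Cb*F].
dap_fwd <- function(Y, N, Cn, dspec) {
  d <- dim(Y); Tp <- d[2]; Fn <- d[3]
  Cb <- dspec$out_channel_bins; Tb <- dspec$out_time_bins
  Rb <- dap_bin_matrix(Cn, Cb)
  Tm <- dap_bin_matrix(Tp, Tb)
  A <- array(Y, c(N, Cn, Tp, Fn))
  P1 <- aperm(A, c(2, 1, 3, 4)); dim(P1) <- c(Cn, N * Tp * Fn)
  M1 <- array(Rb %*% P1, c(Cb, N, Tp, Fn))
  P2 <- aperm(M1, c(3, 1, 2, 4)); dim(P2) <- c(Tp, Cb * N * Fn)
  M2 <- array(Tm %*% P2, c(Tb, Cb, N, Fn))
  L <- aperm(M2, c(3, 1, 2, 4))           # [N, Tb, Cb, F]
  dim(L) <- c(N, Tb, Cb * Fn)
  list(out = L, Rb = Rb, Tm = Tm, N = N, Cn = Cn, Tp = Tp, Fn = Fn,
       Cb = Cb, Tb = Tb)
}

dap_bwd <- function(cache, dL) {
  with(cache, {
    dim(dL) <- c(N, Tb, Cb, Fn)
    dM2 <- aperm(dL, c(2, 3, 1, 4))       # [Tb, Cb, N, F]
    dim(dM2) <- c(Tb, Cb * N * Fn)
    dP2 <- array(t(Tm) %*% dM2, c(Tp, Cb, N, Fn))
    dM1 <- aperm(dP2, c(2, 3, 1, 4))      # [Cb, N, Tp, F]
    dim(dM1) <- c(Cb, N * Tp * Fn)
    dP1 <- array(t(Rb) %*% dM1, c(Cn, N, Tp, Fn))
    dA <- aperm(dP1, c(2, 1, 3, 4))       # [N, C, Tp, F]
    dim(dA) <- c(N * Cn, Tp, Fn)
    dA
  })
}

# Loss and gradients for one batch (used by the training loop and by the
# finite-difference gradient checks in the test suite).
model_loss_grads <- function(params, spec, X, yidx, train = FALSE) {
  fw <- model_fwd(params, spec, X, train = train)
  sx <- softmax_xent(fw$logits, yidx)
  grads <- model_bwd(params, spec, fw, sx$dlogits)
  acc <- mean(max.col(sx$probs, ties.method = "first") == yidx)
  list(loss = sx$loss, grads = grads, probs = sx$probs, accuracy = acc)
}

# ---- prediction ------------------------------------------------------------

# Stack windows (all sharing one shape) into an [N, T, C] array.
windows_to_array <- function(windows) {
  Cn <- nrow(windows[[1]]$values); Tn <- ncol(windows[[1]]$values)
  X <- array(0, c(length(windows), Tn, Cn))
  for (i in seq_along(windows)) X[i, , ] <- t(windows[[i]]$values)
  X
}

#' Class-probability predictions for a list of windows
#'
#' Windows must already be preprocessed compatibly with the model
#' (normalized with the model's statistics; masked/resampled as the
#' variant requires). Windows of different shapes are grouped and
#' forwarded per shape group (only the `dana` variant accepts more than
#' one shape). Inference is deterministic: dropout is disabled.
#'
#' @param model a `har_classifier`.
#' @param windows list of `window` objects.
#' @param batch_size forward-pass batch size.
#' @return Numeric matrix (n_windows x n_classes); each row is a
#'   probability vector summing to 1. Columns follow `model$class_order`.
#' @export
predict_proba <- function(model, windows, batch_size = 256L) {
  stopifnot(inherits(model, "har_classifier"))
  n <- length(windows)
  out <- matrix(0, n, model$spec$n_classes,
                dimnames = list(NULL, model$class_order))
  if (n == 0) return(out)
  shapes <- vapply(windows, function(w) paste(dim(w$values), collapse = "x"),
                   character(1))
  for (sh in unique(shapes)) {
    idx <- which(shapes == sh)
    for (start in seq(1, length(idx), by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1, length(idx))]
      X <- windows_to_array(windows[bi])
      fw <- model_fwd(model$params, model$spec, X, train = FALSE)
      out[bi, ] <- softmax_rows(fw$logits)
    }
  }
  out
}

#' Hard class predictions
#'
#' Argmax of [predict_proba()] per window; exact ties are broken by class
#' order (the earlier class wins).
#'
#' @inheritParams predict_proba
#' @return Factor of predicted activity codes (levels in class order).
#' @export
classify <- function(model, windows, batch_size = 256L) {
  p <- predict_proba(model, windows, batch_size = batch_size)
  idx <- max.col(p, ties.method = "first")
  factor(model$class_order[idx], levels = model$class_order)
}

# ---- model bundle on disk --------------------------------------------------

#' Save / load a self-contained model bundle
#'
#' The bundle directory holds a machine-readable architecture spec
#' (`spec.json`), the trained weights (`weights.rds`), the normalization
#' sidecar (`norm_stats.json`) and, when present, the training history
#' (`history.json`). A loaded bundle reproduces evaluation metrics
#' exactly.
#'
#' @param model a `har_classifier`.
#' @param dir bundle directory (created if missing).
#' @return `dir` (save) or the restored `har_classifier` (load).
#' @export
save_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "har_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- model$spec
  spl <- list(variant = sp$variant, n_classes = sp$n_classes,
              input_channels = sp$input_channels,
              window_len = sp$window_len,
              conv_blocks = lapply(sp$conv_blocks, as.integer),
              recurrent_units = sp$recurrent_units,
              dense_units = sp$dense_units,
              dropout_rate = sp$dropout_rate,
              class_order = model$class_order,
              train_dataset = model$train_dataset_id %||% NA_character_)
  if (!is.null(sp$dap)) {
    spl$dap <- list(out_time_bins = sp$dap$out_time_bins,
                    out_channel_bins = sp$dap$out_channel_bins)
  }
  jsonlite::write_json(spl, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = I(17))
  saveRDS(model$params, file.path(dir, "weights.rds"))
  if (!is.null(model$stats)) {
    write_norm_stats(model$stats, file.path(dir, "norm_stats.json"))
  }
  if (!is.null(model$history)) {
    jsonlite::write_json(model$history, file.path(dir, "history.json"),
                         digits = I(17), dataframe = "columns")
  }
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  spl <- jsonlite::fromJSON(file.path(dir, "spec.json"))
  spec <- model_spec(
    variant = spl$variant, n_classes = spl$n_classes,
    input_channels = spl$input_channels, window_len = spl$window_len,
    conv_blocks = if (is.matrix(spl$conv_blocks)) {
      lapply(seq_len(nrow(spl$conv_blocks)), function(i) spl$conv_blocks[i, ])
    } else spl$conv_blocks,
    recurrent_units = spl$recurrent_units, dense_units = spl$dense_units,
    dropout_rate = spl$dropout_rate,
    dap = if (!is.null(spl$dap)) {
      dap_spec(spl$dap$out_time_bins, spl$dap$out_channel_bins)
    } else NULL)
  model <- structure(list(spec = spec,
                          params = readRDS(file.path(dir, "weights.rds")),
                          stats = NULL,
                          class_order = spl$class_order,
                          history = NULL),
                     class = "har_classifier")
  if (!is.null(spl$train_dataset) && !is.na(spl$train_dataset)) {
    model$train_dataset_id <- spl$train_dataset
  }
  nsp <- file.path(dir, "norm_stats.json")
  if (file.exists(nsp)) model$stats <- read_norm_stats(nsp)
  hp <- file.path(dir, "history.json")
  if (file.exists(hp)) {
    model$history <- as.data.frame(jsonlite::fromJSON(hp))
  }
  model
}
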