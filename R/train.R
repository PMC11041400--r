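#' Training configuration
#'
#' @param epochs number of passes over the training windows (default 100).
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed controlling shuffling, dropout and (when
#'   adaptive) dimension sampling; a fixed seed makes training fully
#'   reproducible.
#' @param dimension_adaptive when TRUE, every minibatch is transformed by
#'   a freshly sampled (rate, sensor-subset) configuration before the
#'   forward pass, so the model learns under varying input
#'   dimensionality. Requires the `dana` variant.
#' @param dimension_space list of [dimension_config()]s sampled from when
#'   adaptive (default [default_dimension_space()]).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         learning_rate = 1e-3, seed = 1L,
                         dimension_adaptive = FALSE,
                         dimension_space = default_dimension_space()) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (dimension_adaptive && length(dimension_space) == 0) {
    stop("dimension_adaptive training requires a non-empty dimension_space",
         call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 dimension_adaptive = isTRUE(dimension_adaptive),
                 dimension_space = dimension_space),
            class = "train_config")
}

#' Train a classifier
#'
#' Fits per-channel normalization statistics on the training windows,
#' stores them in the model, and minimizes categorical cross-entropy
#' with Adam. With `cfg$dimension_adaptive`, each minibatch is resampled
#' and sensor-masked (drop mode) under a configuration drawn uniformly
#' from `cfg$dimension_space`. The run is fully reproducible from
#' `cfg$seed`.
#'
#' @param model an untrained (or warm) `har_classifier`.
#' @param train_ds a non-empty `har_dataset` of raw (unnormalized)
#'   windows.
#' @param cfg a [train_config()].
#' @return The trained model, with `$history` holding one row per epoch
#'   (`epoch`, `loss`, `accuracy` over the training windows).
#' @export
train_classifier <- function(model, train_ds, cfg = train_config()) {
  stopifnot(inherits(model, "har_classifier"),
            inherits(train_ds, "har_dataset"),
            inherits(cfg, "train_config"))
  if (length(train_ds$windows) == 0) {
    stop("training dataset is empty", call. = FALSE)
  }
  if (cfg$dimension_adaptive && model$spec$variant == "simple") {
    stop("dimension-adaptive training requires the dana variant: the ",
         "simple model has a fixed input dimension", call. = FALSE)
  }
  stats <- fit_normalization(train_ds)
  nds <- normalize_dataset(train_ds, stats)
  yall <- match(vapply(nds$windows, function(w) w$label, character(1)),
                model$class_order)
  if (anyNA(yall)) stop("window label outside the model's class order",
                        call. = FALSE)
  n <- length(nds$windows)
  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- c(); accs <- c(); sizes <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        bi <- perm[start:min(start + cfg$batch_size - 1, n)]
        wins <- nds$windows[bi]
        if (cfg$dimension_adaptive) {
          dimcfg <- sample_dimension_config(cfg$dimension_space)
          wins <- lapply(wins, apply_dimension_config, cfg = dimcfg,
                         mode = "drop", channels = nds$channels)
        }
        X <- windows_to_array(wins)
        lg <- model_loss_grads(params, model$spec, X, yall[bi], train = TRUE)
        st <- adam_step(params, lg$grads, state, lr = cfg$learning_rate)
        params <- st$params
        state <- st$state
        losses <- c(losses, lg$loss)
        accs <- c(accs, lg$accuracy)
        sizes <- c(sizes, length(bi))
      }
      history <- rbind(history, data.frame(
        epoch = ep,
        loss = stats::weighted.mean(losses, sizes),
        accuracy = stats::weighted.mean(accs, sizes)))
    }
  })
  model$params <- params
  model$stats <- stats
  model$history <- history
  model$train_dataset_id <- train_ds$id
  model
}
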