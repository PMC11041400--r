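# Shared fixtures, all built in code at test time.

# A labeled recording with deterministic ramp values.
make_rec <- function(n = 300L, rate = 50, labels = "wlk",
                     participant = "p1") {
  mat <- matrix(seq_len(6 * n) / 7, 6, n)
  spans <- if (length(labels) == 1) {
    label_spans(0, n / rate, labels)
  } else {
    edges <- seq(0, n / rate, length.out = length(labels) + 1)
    label_spans(edges[-length(edges)], edges[-1], labels)
  }
  recording(mat, sampling_rate = rate, participant_id = participant,
            label_spans = spans)
}

# A dataset of hand-built windows (no synthesis), balanced over classes.
make_fake_dataset <- function(n_per_class = 2L, participants = c("p1", "p2"),
                              window_len = 16L, seed = 1L) {
  windows <- list()
  withr::with_seed(seed, {
    for (code in activity_codes()) {
      for (i in seq_len(n_per_class)) {
        w <- harpipe:::new_window(
          matrix(rnorm(6 * window_len), 6, window_len), code, 50,
          participants[1 + (i - 1) %% length(participants)], 0L)
        windows[[length(windows) + 1]] <- w
      }
    }
  })
  har_dataset(windows, id = "fake")
}

# Short 30 s course: fast to synthesize, still covers all six classes.
short_plan <- function() {
  data.frame(label = c("wlk", "jog", "sit", "ups", "std", "dws"),
             duration = rep(5, 6), stringsAsFactors = FALSE)
}

tiny_simple_spec <- function(window_len = 32L) {
  model_spec("simple", window_len = window_len,
             conv_blocks = list(c(8L, 3L), c(8L, 3L)),
             recurrent_units = 8L, dense_units = 8L, dropout_rate = 0.25)
}

tiny_dana_spec <- function() {
  model_spec("dana", conv_blocks = list(c(8L, 3L), c(8L, 3L)),
             recurrent_units = 8L, dense_units = 8L, dropout_rate = 0.25,
             dap = dap_spec(4L, 3L))
}

# A model whose every weight is zero: all logits equal, so every window
# ties and classify() falls back to the first class in class order.
zeroed_model <- function(spec = tiny_simple_spec()) {
  m <- build_classifier(spec, seed = 1)
  m$params <- lapply(m$params, function(layer) lapply(layer, function(x) x * 0))
  m
}

# Independent brute-force oracle for dimension-adaptive pooling: plain
# double loop over bin index sets with the same floor-boundary rule.
dap_brute <- function(M, Tb, Cb) {
  Cn <- nrow(M); Tn <- ncol(M)
  out <- matrix(0, Cb, Tb)
  for (i in seq_len(Cb)) {
    rs <- floor((i - 1) * Cn / Cb); re <- floor(i * Cn / Cb)
    if (re <= rs) re <- rs + 1
    for (j in seq_len(Tb)) {
      cs <- floor((j - 1) * Tn / Tb); ce <- floor(j * Tn / Tb)
      if (ce <= cs) ce <- cs + 1
      out[i, j] <- mean(M[(rs + 1):re, (cs + 1):ce])
    }
  }
  out
}
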