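#' Fit per-channel normalization statistics
#'
#' Computes the global per-channel mean and population standard deviation
#' over all samples of all training windows. Statistics must be fitted on
#' the training split only and are carried with a trained model so that
#' test (and cross-dataset) windows are always normalized with the
#' training domain's statistics.
#'
#' @param train a non-empty `har_dataset`.
#' @return A `norm_stats` object: list with `mean` and `sd` (named numeric
#'   vectors, one entry per channel; population convention, a constant
#'   channel has sd 0) and the channel names.
#' @export
fit_normalization <- function(train) {
  stopifnot(inherits(train, "har_dataset"))
  if (length(train$windows) == 0) stop("empty dataset", call. = FALSE)
  big <- do.call(cbind, lapply(train$windows, function(w) w$values))
  m <- rowMeans(big)
  sdv <- sqrt(rowMeans((big - m)^2))
  structure(list(mean = stats::setNames(m, train$channels$name),
                 sd = stats::setNames(sdv, train$channels$name),
                 channels = train$channels$name),
            class = "norm_stats")
}

#' Normalize a window with fitted statistics
#'
#' Maps each channel to `(x - mean) / sd`; channels with sd 0 map to 0.
#'
#' @param w a `window` whose channels match `stats`.
#' @param stats a `norm_stats` from [fit_normalization()].
#' @return The normalized window.
#' @export
normalize_window <- function(w, stats) {
  stopifnot(inherits(w, "window"), inherits(stats, "norm_stats"))
  if (nrow(w$values) != length(stats$mean)) {
    stop("channel mismatch: window has ", nrow(w$values),
         " channels, stats have ", length(stats$mean), call. = FALSE)
  }
  s <- stats$sd
  z <- (w$values - stats$mean) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  w$values <- z
  w
}

#' Normalize every window of a dataset
#' @param ds a har_dataset; stats a norm_stats.
#' @export
normalize_dataset <- function(ds, stats) {
  ds$windows <- lapply(ds$windows, normalize_window, stats = stats)
  ds
}

#' Undo normalization (exact inverse when all sds > 0)
#' @param w a normalized window; stats the norm_stats used.
#' @export
denormalize_window <- function(w, stats) {
  w$values <- w$values * stats$sd + stats$mean
  w
}

#' Save / load normalization statistics as a JSON sidecar
#' @param stats a norm_stats; path file path.
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(list(channels = stats$channels,
                            mean = unname(stats$mean),
                            sd = unname(stats$sd)),
                       path, digits = I(17))
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  doc <- jsonlite::fromJSON(path)
  structure(list(mean = stats::setNames(doc$mean, doc$channels),
                 sd = stats::setNames(doc$sd, doc$channels),
                 channels = doc$channels),
            class = "norm_stats")
}

#' Reduce a window's sampling rate
#'
#' Values are linearly interpolated onto a uniform grid at `target_rate`
#' spanning the same duration; the output length is
#' `max(1, round(window_len * target_rate / source_rate))`. For integer
#' decimation factors this equals taking every k-th sample (phase 0).
#' Upsampling is refused.
#'
#' @param w a `window`.
#' @param target_rate target rate in Hz, `0 < target_rate <= w$sampling_rate`.
#' @return The resampled window with `sampling_rate = target_rate`.
#' @export
resample_window <- function(w, target_rate) {
  stopifnot(inherits(w, "window"))
  if (target_rate <= 0) stop("target_rate must be positive", call. = FALSE)
  if (target_rate > w$sampling_rate) {
    stop("target_rate (", target_rate, " Hz) exceeds the source rate (",
         w$sampling_rate, " Hz): upsampling is not supported", call. = FALSE)
  }
  if (target_rate == w$sampling_rate) return(w)
  n <- ncol(w$values)
  out_len <- max(1L, as.integer(round(n * target_rate / w$sampling_rate)))
  t_src <- (seq_len(n) - 1) / w$sampling_rate
  t_out <- (seq_len(out_len) - 1) / target_rate
  vals <- t(apply(w$values, 1, function(y) {
    stats::approx(t_src, y, xout = t_out, method = "linear", rule = 2)$y
  }))
  if (out_len == 1L) vals <- matrix(vals, nrow = nrow(w$values))
  rownames(vals) <- rownames(w$values)
  w$values <- vals
  w$sampling_rate <- target_rate
  w
}

#' Sensor availability mask
#'
#' @param available character vector, subset of
#'   `c("accelerometer", "gyroscope", "magnetometer")`.
#' @return A `sensor_mask` object.
#' @export
#' @examples
#' sensor_mask(c("accelerometer", "gyroscope"))
sensor_mask <- function(available) {
  groups <- c("accelerometer", "gyroscope", "magnetometer")
  available <- unique(as.character(available))
  bad <- setdiff(available, groups)
  if (length(bad) > 0) {
    stop("unknown sensor group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(available = available), class = "sensor_mask")
}

#' Apply a sensor mask to a window
#'
#' `drop` mode removes the rows of unavailable sensor groups (channel
#' count shrinks -- input for the dimension-adaptive model); `zero_fill`
#' keeps the shape and sets unavailable rows to zero (input for the
#' fixed-dimension model, which requires a constant 6-channel shape).
#'
#' @param w a `window` with the default 6-channel layout.
#' @param mask a [sensor_mask()]; must be non-empty.
#' @param mode `"drop"` or `"zero_fill"`.
#' @param channels the window's channel set (default [default_channels()]).
#' @return The masked window.
#' @export
mask_sensors <- function(w, mask, mode = c("drop", "zero_fill"),
                         channels = default_channels()) {
  mode <- match.arg(mode)
  stopifnot(inherits(w, "window"), inherits(mask, "sensor_mask"))
  if (length(mask$available) == 0) {
    stop("no sensors available: mask is empty", call. = FALSE)
  }
  keep <- channels$sensor_group %in% mask$available
  if (mode == "drop") {
    w$values <- w$values[keep, , drop = FALSE]
  } else if (any(!keep)) {
    w$values[!keep, ] <- 0
  }
  w
}

#' A (sampling-rate, sensor-subset) input configuration
#'
#' Describes the input dimensionality presented to a model: a target
#' sampling rate (at or below the native rate of the data it is applied
#' to) and the subset of available sensors.
#'
#' @param rate target rate in Hz (> 0).
#' @param mask a [sensor_mask()] (or character vector of group names).
#' @return A `dimension_config` object.
#' @export
dimension_config <- function(rate, mask) {
  if (!inherits(mask, "sensor_mask")) mask <- sensor_mask(mask)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  structure(list(rate = as.numeric(rate), mask = mask),
            class = "dimension_config")
}

#' @export
format.dimension_config <- function(x, ...) {
  grp <- c(accelerometer = "acc", gyroscope = "gyr", magnetometer = "mag")
  sprintf("%gHz|%s", x$rate,
          paste(grp[x$mask$available], collapse = "+"))
}

#' @export
print.dimension_config <- function(x, ...) {
  cat("<dimension_config>", format(x), "\n")
  invisible(x)
}

#' Default dimension-configuration space
#'
#' Rates {50, 25, 10, 5} Hz crossed with sensor subsets {accelerometer},
#' {gyroscope}, {accelerometer + gyroscope}. The magnetometer is excluded
#' by default: the data this pipeline targets carry no magnetometer
#' channels.
#'
#' @return List of [dimension_config()] objects (12 entries).
#' @export
default_dimension_space <- function() {
  rates <- c(50, 25, 10, 5)
  masks <- list("accelerometer", "gyroscope",
                c("accelerometer", "gyroscope"))
  out <- list()
  for (r in rates) for (m in masks) {
    out[[length(out) + 1]] <- dimension_config(r, sensor_mask(m))
  }
  out
}

#' Draw one dimension configuration uniformly at random
#'
#' Uses R's global random number generator; seed via `set.seed()` for a
#' reproducible sequence (as the training loop does).
#'
#' @param space non-empty list of [dimension_config()] objects.
#' @return One element of `space`.
#' @export
sample_dimension_config <- function(space) {
  if (length(space) == 0) stop("dimension space is empty", call. = FALSE)
  space[[sample.int(length(space), 1L)]]
}

#' Apply a dimension configuration to a window
#'
#' Resamples to `cfg$rate` then masks sensors. Normalization (if any)
#' must happen before this transform, while the window still has the full
#' channel layout.
#'
#' @param w a window; cfg a dimension_config; mode passed to
#'   [mask_sensors()] (`drop` for the dimension-adaptive model,
#'   `zero_fill` for the fixed-dimension model).
#' @export
apply_dimension_config <- function(w, cfg, mode = c("drop", "zero_fill"),
                                   channels = default_channels()) {
  mode <- match.arg(mode)
  w <- resample_window(w, cfg$rate)
  mask_sensors(w, cfg$mask, mode = mode, channels = channels)
}

#' Variance-share channel screening
#'
#' Ranks channels by their share of total pooled variance across all
#' samples of all windows (population variance per channel, normalized to
#' sum to 1). This is a screening utility in the spirit of a principal
#' component analysis of channel informativeness, not a full PCA: it
#' reproduces the qualitative conclusion that the six acceleration and
#' rotation-rate channels carry the signal.
#'
#' @param ds a `har_dataset` with at least 2 windows.
#' @return data.frame with columns `channel` and `score`, sorted by
#'   descending score (ties broken by channel order); scores sum to 1.
#' @export
channel_relevance <- function(ds) {
  stopifnot(inherits(ds, "har_dataset"))
  if (length(ds$windows) < 2) {
    stop("need at least 2 windows to rank channels", call. = FALSE)
  }
  big <- do.call(cbind, lapply(ds$windows, function(w) w$values))
  v <- rowMeans((big - rowMeans(big))^2)
  tot <- sum(v)
  score <- if (tot > 0) v / tot else rep(0, length(v))
  ord <- order(-score, seq_along(score))
  data.frame(channel = ds$channels$name[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}
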