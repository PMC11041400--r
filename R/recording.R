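#' Construct a sensor recording
#'
#' A `recording` holds one participant's continuous multi-channel IMU
#' stream: a numeric matrix of shape (n_channels x n_samples), a sampling
#' rate in Hz, channel metadata, a start time `t0` (seconds, arbitrary
#' epoch) and optional label spans. Sample `i` (0-based) corresponds to
#' time `t0 + i / sampling_rate`.
#'
#' @param samples numeric matrix, n_channels x n_samples. Row names, if
#'   absent, are taken from `channels$name`.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param participant_id participant identifier.
#' @param channels a `channel_set` (default [default_channels()]).
#' @param t0 start time in seconds (default 0).
#' @param label_spans optional data.frame of label spans (see
#'   [label_spans()]); validated against the recording extent.
#' @return An object of class `recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(60), 6, 10), sampling_rate = 50,
#'                  participant_id = "p1")
#' rec
recording <- function(samples, sampling_rate, participant_id = "unknown",
                      channels = default_channels(), t0 = 0,
                      label_spans = NULL) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  validate_channel_set(channels)
  if (nrow(samples) != nrow(channels)) {
    stop("samples has ", nrow(samples), " rows but channel set has ",
         nrow(channels), " channels", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number", call. = FALSE)
  }
  rownames(samples) <- channels$name
  rec <- structure(
    list(participant_id = as.character(participant_id),
         sampling_rate = as.numeric(sampling_rate),
         channels = channels,
         samples = samples,
         t0 = as.numeric(t0),
         label_spans = NULL),
    class = "recording"
  )
  if (!is.null(label_spans)) rec <- apply_labels(rec, label_spans)
  rec
}

#' @export
print.recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$sampling_rate
  cat(sprintf("<recording> participant '%s': %d channels x %d samples (%.1f s at %g Hz)\n",
              x$participant_id, nrow(x$samples), ncol(x$samples), dur,
              x$sampling_rate))
  if (!is.null(x$label_spans)) {
    cat(sprintf("  %d label span(s): %s\n", nrow(x$label_spans),
                paste(unique(x$label_spans$label), collapse = ", ")))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a recording.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate

#' Build a label-span table
#'
#' Label spans map half-open time intervals `[start, end)` (seconds, same
#' epoch as the recording's `t0`) to activity codes. Spans within one
#' recording must not overlap.
#'
#' @param start,end numeric vectors of interval bounds (start inclusive,
#'   end exclusive).
#' @param label character vector of activity codes.
#' @return A `label_spans` data.frame sorted by `start`.
#' @export
#' @examples
#' label_spans(c(0, 60), c(60, 120), c("wlk", "jog"))
label_spans <- function(start, end, label) {
  stopifnot(length(start) == length(end), length(start) == length(label))
  sp <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   label = as_activity_code(label), stringsAsFactors = FALSE)
  if (any(!is.finite(sp$start)) || any(!is.finite(sp$end))) {
    stop("span bounds must be finite", call. = FALSE)
  }
  if (any(sp$start >= sp$end)) {
    bad <- which(sp$start >= sp$end)[1]
    stop(sprintf("span %d has start >= end (%g >= %g)", bad, sp$start[bad],
                 sp$end[bad]), call. = FALSE)
  }
  sp <- sp[order(sp$start), , drop = FALSE]
  rownames(sp) <- NULL
  ov <- which(sp$start[-1] < sp$end[-nrow(sp)])
  if (length(ov) > 0) {
    i <- ov[1]
    stop(sprintf(
      "overlapping spans: [%g, %g) '%s' and [%g, %g) '%s'",
      sp$start[i], sp$end[i], sp$label[i],
      sp$start[i + 1], sp$end[i + 1], sp$label[i + 1]), call. = FALSE)
  }
  class(sp) <- c("label_spans", "data.frame")
  sp
}

#' Attach label spans to a recording
#'
#' Samples outside every span are considered unlabeled and are excluded
#' from window emission by [segment_windows()].
#'
#' @param rec a recording.
#' @param spans a data.frame with columns `start`, `end`, `label`
#'   (seconds, same epoch as `rec$t0`), e.g. from [label_spans()].
#' @return The recording with validated, sorted `label_spans` attached.
#' @export
apply_labels <- function(rec, spans) {
  stopifnot(inherits(rec, "recording"))
  if (!inherits(spans, "label_spans")) {
    spans <- label_spans(spans$start, spans$end, spans$label)
  }
  lo <- rec$t0
  hi <- rec$t0 + ncol(rec$samples) / rec$sampling_rate
  # tolerate float rounding from timestamp reconstruction (< 1e-6 sample)
  tol <- 1e-6 / rec$sampling_rate
  spans$start[abs(spans$start - lo) < tol] <- lo
  spans$end[spans$end > hi & spans$end - hi < tol] <- hi
  out <- which(spans$start < lo | spans$end > hi)
  if (length(out) > 0) {
    i <- out[1]
    stop(sprintf(
      "span [%g, %g) '%s' lies outside the recording extent [%g, %g]",
      spans$start[i], spans$end[i], spans$label[i], lo, hi), call. = FALSE)
  }
  rec$label_spans <- spans
  rec
}

#' Per-sample label codes for a recording
#'
#' @param rec a labeled recording.
#' @return Character vector of length n_samples; `NA` where unlabeled.
#' @export
sample_labels <- function(rec) {
  n <- ncol(rec$samples)
  lab <- rep(NA_character_, n)
  if (is.null(rec$label_spans) || n == 0) return(lab)
  t <- rec$t0 + (seq_len(n) - 1) / rec$sampling_rate
  for (i in seq_len(nrow(rec$label_spans))) {
    sel <- t >= rec$label_spans$start[i] & t < rec$label_spans$end[i]
    lab[sel] <- rec$label_spans$label[i]
  }
  lab
}
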