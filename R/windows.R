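#' Slice a labeled recording into fixed-length windows
#'
#' Windows start at sample offsets 0, `step`, `2*step`, ... (0-based) and
#' cover `window_len` consecutive samples. Under the `pure` policy a
#' window is emitted only if every one of its samples is labeled with one
#' and the same activity; under `majority` it is emitted if strictly more
#' than 50% of its samples share one label. For a fully labeled,
#' single-label recording of length `L` the number of emitted windows is
#' `floor((L - window_len) / step) + 1` when `L >= window_len`, else 0.
#'
#' @param rec a labeled [recording()].
#' @param window_len window length in samples (default 128, i.e. 2.56 s
#'   at 50 Hz).
#' @param step hop between window starts in samples (default 64, 50%
#'   overlap); must satisfy `1 <= step <= window_len`.
#' @param label_policy `"pure"` or `"majority"`.
#' @return List of `window` objects; each holds `values`
#'   (n_channels x window_len matrix), `label`, `sampling_rate`,
#'   `source_participant` and 0-based `source_offset`.
#' @export
segment_windows <- function(rec, window_len = 128L, step = 64L,
                            label_policy = c("pure", "majority")) {
  label_policy <- match.arg(label_policy)
  stopifnot(inherits(rec, "recording"))
  window_len <- as.integer(window_len)
  step <- as.integer(step)
  if (window_len < 1) stop("window_len must be >= 1", call. = FALSE)
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  if (step > window_len) stop("step must be <= window_len", call. = FALSE)
  L <- ncol(rec$samples)
  if (L < window_len) return(list())
  offsets <- seq.int(0L, L - window_len, by = step)

  lab <- sample_labels(rec)
  code <- match(lab, activity_codes())          # NA for unlabeled
  code0 <- ifelse(is.na(code), 0L, code)
  # run-change counter: pure windows have no label change inside
  chg <- cumsum(c(0L, diff(code0) != 0L))

  out <- vector("list", length(offsets))
  k <- 0L
  for (o in offsets) {
    i1 <- o + 1L
    i2 <- o + window_len
    win_label <- NA_character_
    if (label_policy == "pure") {
      if (code0[i1] != 0L && chg[i2] == chg[i1]) {
        win_label <- activity_codes()[code0[i1]]
      }
    } else {
      tab <- tabulate(code[i1:i2], nbins = 6L)
      j <- which.max(tab)
      if (tab[j] * 2L > window_len) win_label <- activity_codes()[j]
    }
    if (!is.na(win_label)) {
      k <- k + 1L
      out[[k]] <- new_window(rec$samples[, i1:i2, drop = FALSE], win_label,
                             rec$sampling_rate, rec$participant_id, o)
    }
  }
  out[seq_len(k)]
}

#' @keywords internal
new_window <- function(values, label, sampling_rate, participant, offset) {
  structure(list(values = values, label = label,
                 sampling_rate = sampling_rate,
                 source_participant = participant,
                 source_offset = as.integer(offset)),
            class = "window")
}

#' @export
print.window <- function(x, ...) {
  cat(sprintf("<window> '%s' %d x %d @ %g Hz (participant %s, offset %d)\n",
              x$label, nrow(x$values), ncol(x$values), x$sampling_rate,
              x$source_participant, x$source_offset))
  invisible(x)
}

#' Bundle windows into a dataset
#'
#' All windows must share the channel set and window length. Class counts
#' over the six activities are derived and stored.
#'
#' @param windows list of `window` objects.
#' @param channels the shared `channel_set`.
#' @param id optional dataset identifier (used in evaluation metadata).
#' @return An object of class `har_dataset`.
#' @export
har_dataset <- function(windows, channels = default_channels(),
                        id = "dataset") {
  if (length(windows) > 0) {
    nc <- vapply(windows, function(w) nrow(w$values), integer(1))
    nl <- vapply(windows, function(w) ncol(w$values), integer(1))
    if (length(unique(nc)) != 1 || length(unique(nl)) != 1) {
      stop("all windows must share channel count and window length",
           call. = FALSE)
    }
    if (nc[1] != nrow(channels)) {
      stop("window channel count does not match the channel set", call. = FALSE)
    }
  }
  labs <- vapply(windows, function(w) w$label, character(1))
  counts <- table(activity_factor(labs))
  structure(list(windows = windows, channels = channels, id = id,
                 class_counts = counts),
            class = "har_dataset")
}

#' @export
print.har_dataset <- function(x, ...) {
  cat(sprintf("<har_dataset> '%s': %d windows, %d participants\n", x$id,
              length(x$windows), length(dataset_participants(x))))
  print(x$class_counts)
  invisible(x)
}

#' @export
length.har_dataset <- function(x) length(x$windows)

#' Participants contributing to a dataset
#' @param ds a har_dataset.
#' @export
dataset_participants <- function(ds) {
  unique(vapply(ds$windows, function(w) w$source_participant, character(1)))
}

#' Window labels of a dataset as a factor in canonical class order
#' @param ds a har_dataset.
#' @export
dataset_labels <- function(ds) {
  activity_factor(vapply(ds$windows, function(w) w$label, character(1)))
}

#' Per-class and per-participant window counts
#'
#' @param ds a `har_dataset`.
#' @return List with `by_class` (named integer vector over all 6 classes,
#'   zeros allowed), `by_participant` (named integer vector) and `total`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "har_dataset"))
  labs <- vapply(ds$windows, function(w) w$label, character(1))
  parts <- vapply(ds$windows, function(w) w$source_participant, character(1))
  by_class <- table(activity_factor(labs))
  by_participant <- if (length(parts)) table(parts) else table(character(0))
  list(by_class = c(by_class),
       by_participant = c(by_participant),
       total = length(ds$windows))
}

#' Subset a dataset by window index
#' @param ds a har_dataset; idx integer indices.
#' @keywords internal
dataset_subset <- function(ds, idx, id = ds$id) {
  har_dataset(ds$windows[idx], channels = ds$channels, id = id)
}
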