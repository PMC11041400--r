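#' Default CSV column dialect
#'
#' Maps the pipeline's standard column roles to the column names found in
#' a file. The default export dialect is
#' `timestamp,acc_x,acc_y,acc_z,rot_roll,rot_pitch,rot_yaw[,label]` with
#' timestamps in seconds.
#'
#' @return Named character vector: role -> file column name.
#' @export
default_csv_dialect <- function() {
  ch <- default_channels()$name
  stats::setNames(c("timestamp", ch, "label"), c("timestamp", ch, "label"))
}

#' Read a sensor recording from CSV
#'
#' Expects tabular text with a header row containing a timestamp column
#' (seconds) and the six sensor channels. Rows must be in strictly
#' increasing timestamp order. The sampling rate is estimated as the
#' reciprocal of the median timestamp increment unless supplied; a
#' warning is issued when timestamp jitter exceeds 1% of the median
#' increment. An optional `label` column of activity codes (empty =
#' unlabeled) is converted to label spans.
#'
#' @param path path to a CSV file (or a character vector of lines).
#' @param dialect named character vector mapping roles to file columns,
#'   see [default_csv_dialect()].
#' @param participant_id participant identifier to record.
#' @param sampling_rate optional known rate in Hz; skips estimation.
#' @return A [recording()].
#' @export
read_recording_csv <- function(path, dialect = default_csv_dialect(),
                               participant_id = "unknown",
                               sampling_rate = NULL) {
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = TRUE, showProgress = FALSE)
  ch <- default_channels()
  need <- unname(dialect[c("timestamp", ch$name)])
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dt) < 2) {
    stop("fewer than 2 samples: sampling rate is inestimable", call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(v) & !(dt[[col]] %in% c("", "NA")))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                   dt[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    }
    v
  }
  ts <- num(dialect[["timestamp"]])
  if (any(diff(ts) <= 0)) {
    stop("non-monotonic timestamps at row ", which(diff(ts) <= 0)[1] + 1,
         call. = FALSE)
  }
  if (is.null(sampling_rate)) {
    dts <- diff(ts)
    med <- stats::median(dts)
    if (max(abs(dts - med)) > 0.01 * med) {
      warning("timestamp jitter exceeds 1% of the median increment; ",
              "estimated sampling rate may be unreliable", call. = FALSE)
    }
    sampling_rate <- 1 / med
  }
  mat <- t(vapply(ch$name, function(nm) num(dialect[[nm]]), numeric(nrow(dt))))
  spans <- NULL
  labcol <- dialect[["label"]]
  if (!is.na(labcol) && labcol %in% names(dt)) {
    lab <- dt[[labcol]]
    lab[lab == ""] <- NA_character_
    if (!all(is.na(lab))) spans <- labels_to_spans(lab, ts)
  }
  recording(mat, sampling_rate = sampling_rate,
            participant_id = participant_id, channels = ch, t0 = ts[1],
            label_spans = spans)
}

#' Runs of per-sample labels -> label spans
#' @param lab character vector (NA = unlabeled), ts sample times.
#' @keywords internal
labels_to_spans <- function(lab, ts) {
  n <- length(lab)
  dt <- stats::median(diff(ts))
  key <- ifelse(is.na(lab), "", lab)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != ""
  if (!any(keep)) return(NULL)
  # boundaries at timestamp midpoints: abutting runs share the exact
  # same boundary value, and float jitter in the printed timestamps can
  # never shift a sample across a span boundary
  lo_b <- function(i) if (i == 1) ts[1] else (ts[i - 1] + ts[i]) / 2
  hi_b <- function(i) if (i == n) ts[n] + dt else (ts[i] + ts[i + 1]) / 2
  label_spans(start = vapply(starts[keep], lo_b, numeric(1)),
              end = vapply(ends[keep], hi_b, numeric(1)),
              label = r$values[keep])
}

#' Write a recording to CSV
#'
#' Emits the default dialect, with timestamps reconstructed as
#' `t0 + i / sampling_rate` and values printed at full double precision
#' so that read/write round-trips preserve sample values exactly.
#'
#' @param rec a recording.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  n <- ncol(rec$samples)
  ts <- rec$t0 + (seq_len(n) - 1) / rec$sampling_rate
  lab <- sample_labels(rec)
  lab[is.na(lab)] <- ""
  cols <- c(list(sprintf("%.17g", ts)),
            lapply(seq_len(nrow(rec$samples)),
                   function(i) sprintf("%.17g", rec$samples[i, ])),
            list(lab))
  header <- paste(c("timestamp", rec$channels$name, "label"), collapse = ",")
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a sensor recording from JSON
#'
#' Accepts two dialects: an array-per-channel document
#' (`data` object holding one numeric array per channel, plus
#' `sampling_rate`) and a record-per-sample document (`samples` array of
#' objects each holding `timestamp` plus the channel values). Content
#' that is equivalent to a CSV export parses to an identical recording.
#'
#' @param path path to a JSON file.
#' @return A [recording()].
#' @export
read_recording_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ch <- default_channels()
  if (!is.null(doc$data)) {
    lens <- vapply(ch$name, function(nm) length(doc$data[[nm]]), integer(1))
    miss <- ch$name[lens == 0]
    if (length(miss) > 0 && all(!ch$name %in% names(doc$data))) {
      stop("unknown JSON shape: 'data' object has no channel arrays",
           call. = FALSE)
    }
    if (length(unique(lens)) != 1) {
      stop("unequal channel lengths: ",
           paste(sprintf("%s=%d", ch$name, lens), collapse = ", "),
           call. = FALSE)
    }
    if (is.null(doc$sampling_rate)) {
      stop("array-per-channel document must carry a 'sampling_rate' field",
           call. = FALSE)
    }
    mat <- do.call(rbind, lapply(ch$name, function(nm) as.numeric(doc$data[[nm]])))
    spans <- NULL
    if (!is.null(doc$label_spans) && NROW(doc$label_spans) > 0) {
      spans <- label_spans(doc$label_spans$start, doc$label_spans$end,
                           doc$label_spans$label)
    }
    recording(mat, sampling_rate = doc$sampling_rate,
              participant_id = doc$participant_id %||% "unknown",
              channels = ch, t0 = doc$t0 %||% 0, label_spans = spans)
  } else if (!is.null(doc$samples)) {
    df <- doc$samples
    miss <- setdiff(c("timestamp", ch$name), names(df))
    if (length(miss) > 0) {
      stop("record-per-sample document missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (nrow(df) < 2) {
      stop("fewer than 2 samples: sampling rate is inestimable", call. = FALSE)
    }
    ts <- as.numeric(df$timestamp)
    if (any(diff(ts) <= 0)) stop("non-monotonic timestamps", call. = FALSE)
    rate <- doc$sampling_rate %||% (1 / stats::median(diff(ts)))
    mat <- unname(t(as.matrix(df[, ch$name])))
    spans <- NULL
    if ("label" %in% names(df) && !all(is.na(df$label))) {
      spans <- labels_to_spans(as.character(df$label), ts)
    }
    recording(mat, sampling_rate = rate,
              participant_id = doc$participant_id %||% "unknown",
              channels = ch, t0 = ts[1], label_spans = spans)
  } else {
    stop("unknown JSON shape: expected a 'data' object (array-per-channel) ",
         "or a 'samples' array (record-per-sample)", call. = FALSE)
  }
}

#' Write a recording to JSON (array-per-channel dialect)
#'
#' @param rec a recording.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_json <- function(rec, path) {
  data <- lapply(seq_len(nrow(rec$samples)), function(i) rec$samples[i, ])
  names(data) <- rec$channels$name
  doc <- list(participant_id = rec$participant_id,
              sampling_rate = rec$sampling_rate,
              t0 = rec$t0,
              data = data)
  if (!is.null(rec$label_spans)) {
    doc$label_spans <- as.data.frame(rec$label_spans)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
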