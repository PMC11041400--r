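#' Confusion matrix in canonical class order
#'
#' Rows are true classes, columns predicted classes, both in the fixed
#' canonical class order. `trace(cm) / sum(cm)` is the accuracy.
#'
#' @param truth,pred factors (or codes) of true and predicted classes.
#' @param class_order character vector fixing the axis order.
#' @return Integer matrix (k x k) of counts.
#' @export
confusion_matrix <- function(truth, pred, class_order = activity_codes()) {
  truth <- factor(as.character(truth), levels = class_order)
  pred <- factor(as.character(pred), levels = class_order)
  unclass(table(truth = truth, predicted = pred))
}

#' Row-normalized confusion matrix
#' @param cm a counts matrix; rows with no observations become NA.
#' @export
confusion_rates <- function(cm) {
  rs <- rowSums(cm)
  out <- cm / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- NA_real_
  out
}

#' Macro-averaged F1 score
#' @param cm a confusion counts matrix.
#' @keywords internal
macro_f1 <- function(cm) {
  f1 <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

#' Evaluate a classifier on a dataset
#'
#' Test windows are normalized with the model's own (training-domain)
#' statistics, optionally transformed by a [dimension_config()]
#' (resample + sensor mask: `drop` mode for the `dana` variant,
#' `zero_fill` for `simple`), classified, and tallied into a confusion
#' matrix. Accuracy is plain window-level accuracy,
#' `trace(cm) / sum(cm)`; macro-F1 is reported alongside but never gated
#' on.
#'
#' @param model a trained `har_classifier`.
#' @param test_ds a non-empty `har_dataset` of raw windows.
#' @param dim optional [dimension_config()] applied to the test windows.
#' @return A `har_evaluation`: list with `accuracy`, `macro_f1`,
#'   `confusion` (counts), `n`, `metadata`.
#' @export
evaluate <- function(model, test_ds, dim = NULL) {
  stopifnot(inherits(model, "har_classifier"),
            inherits(test_ds, "har_dataset"))
  if (length(test_ds$windows) == 0) stop("test dataset is empty", call. = FALSE)
  wins <- test_ds$windows
  if (!is.null(model$stats)) {
    wins <- lapply(wins, normalize_window, stats = model$stats)
  }
  if (!is.null(dim)) {
    mode <- if (model$spec$variant == "dana") "drop" else "zero_fill"
    wins <- lapply(wins, apply_dimension_config, cfg = dim, mode = mode,
                   channels = test_ds$channels)
  }
  pred <- classify(model, wins)
  truth <- vapply(test_ds$windows, function(w) w$label, character(1))
  cm <- confusion_matrix(truth, pred, class_order = model$class_order)
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 macro_f1 = macro_f1(cm),
                 confusion = cm,
                 n = length(wins),
                 metadata = list(
                   train_dataset = model$train_dataset_id %||% NA_character_,
                   test_dataset = test_ds$id,
                   dim = if (is.null(dim)) NA_character_ else format(dim))),
            class = "har_evaluation")
}

#' @export
print.har_evaluation <- function(x, ...) {
  cat(sprintf("<har_evaluation> %s -> %s%s: accuracy %.3f (n = %d)\n",
              x$metadata$train_dataset, x$metadata$test_dataset,
              if (is.na(x$metadata$dim)) "" else paste0(" @ ", x$metadata$dim),
              x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Cross-dataset evaluation
#'
#' Evaluates a model trained on dataset A against another dataset B. B's
#' windows are normalized with A's statistics (the training-domain
#' statistics travel with the model -- a deployment assumption). The
#' ordered (train, test) dataset pair is recorded in the metadata.
#'
#' @inheritParams evaluate
#' @param other_ds the held-out dataset from the other domain.
#' @return A `har_evaluation` (see [evaluate()]).
#' @export
cross_evaluate <- function(model, other_ds, dim = NULL) {
  ev <- evaluate(model, other_ds, dim = dim)
  ev$metadata$cross <- TRUE
  ev
}

#' Sampling-rate x sensor-subset robustness grid
#'
#' Probes one trained model under every (rate, mask) combination (no
#' per-cell retraining): each cell is [evaluate()] under that
#' [dimension_config()]. The (native rate, full mask) cell equals plain
#' `evaluate()` exactly.
#'
#' @param model a trained `har_classifier`.
#' @param test_ds a non-empty `har_dataset`.
#' @param rates numeric vector of target rates (Hz), all at or below the
#'   native rate.
#' @param masks list of [sensor_mask()]s (or character vectors).
#' @return An `evaluation_grid`: `cells` (named accuracy vector,
#'   "rateHz|mask"), `evaluations` (per-cell `har_evaluation`s),
#'   `metadata`.
#' @export
dimension_grid_evaluate <- function(model, test_ds,
                                    rates = c(50, 25, 10, 5),
                                    masks = list(
                                      c("accelerometer", "gyroscope"),
                                      "accelerometer", "gyroscope")) {
  if (length(rates) == 0 || length(masks) == 0) {
    stop("rates and masks must be non-empty", call. = FALSE)
  }
  cells <- numeric(0)
  evals <- list()
  for (r in rates) for (m in masks) {
    cfg <- dimension_config(r, if (inherits(m, "sensor_mask")) m else sensor_mask(m))
    ev <- evaluate(model, test_ds, dim = cfg)
    key <- format(cfg)
    cells[key] <- ev$accuracy
    evals[[key]] <- ev
  }
  structure(list(cells = cells, evaluations = evals,
                 metadata = list(
                   train_dataset = model$train_dataset_id %||% NA_character_,
                   test_dataset = test_ds$id)),
            class = "evaluation_grid")
}

#' @export
print.evaluation_grid <- function(x, ...) {
  cat(sprintf("<evaluation_grid> %s -> %s\n", x$metadata$train_dataset,
              x$metadata$test_dataset))
  print(round(x$cells, 3))
  invisible(x)
}

# ---- structured results summary -------------------------------------------

eval_to_record <- function(ev) {
  list(model = ev$metadata$train_dataset,
       dataset = ev$metadata$test_dataset,
       dim = ev$metadata$dim,
       accuracy = ev$accuracy,
       macro_f1 = ev$macro_f1,
       n = ev$n,
       confusion = as.integer(t(ev$confusion)))  # row-major, true-class rows
}

#' Write an evaluation summary file
#'
#' Serializes a non-empty set of evaluation results (single evaluations
#' and/or grids) to one machine-readable JSON file, one record per
#' evaluation: model id, dataset pair, dimension configuration, accuracy,
#' macro-F1 and the 36 confusion counts (row-major). Numbers round-trip
#' exactly through [read_summary()]; re-writing a parsed summary
#' reproduces the file byte for byte.
#'
#' @param results a named or unnamed list of `har_evaluation` and/or
#'   `evaluation_grid` objects (a bare single object is accepted).
#' @param path output file path.
#' @param verbose print rendered tables to the console.
#' @return `path`, invisibly.
#' @export
report <- function(results, path, verbose = FALSE) {
  if (inherits(results, "har_evaluation") ||
      inherits(results, "evaluation_grid")) {
    results <- list(results)
  }
  if (length(results) == 0) stop("no results to report", call. = FALSE)
  records <- list()
  for (res in results) {
    if (inherits(res, "har_evaluation")) {
      records[[length(records) + 1]] <- eval_to_record(res)
    } else if (inherits(res, "evaluation_grid")) {
      for (ev in res$evaluations) {
        records[[length(records) + 1]] <- eval_to_record(ev)
      }
    } else if (is.list(res) && !is.null(res$accuracy) &&
               !is.null(res$confusion)) {
      # a parsed record from read_summary(): re-rendering is idempotent
      chr <- function(x) if (is.null(x) || is.na(x)) NA_character_ else x
      records[[length(records) + 1]] <-
        list(model = chr(res$model), dataset = chr(res$dataset),
             dim = chr(res$dim), accuracy = res$accuracy,
             macro_f1 = res$macro_f1, n = res$n,
             confusion = as.integer(t(res$confusion)))
    } else {
      stop("unsupported result object of class ", class(res)[1], call. = FALSE)
    }
    if (verbose) print(res)
  }
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname report
#' @return `read_summary()`: list of records, each with the fields above
#'   and `confusion` as a 6 x 6 integer matrix.
#' @export
read_summary <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    k <- as.integer(sqrt(length(r$confusion)))
    r$confusion <- matrix(as.integer(unlist(r$confusion)), k, k, byrow = TRUE,
                          dimnames = list(truth = activity_codes()[seq_len(k)],
                                          predicted = activity_codes()[seq_len(k)]))
    r$dim <- r$dim %||% NA_character_
    r
  })
}
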