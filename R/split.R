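#' Subject-wise train/test split
#'
#' Partitions at the participant level, never at the window level, so no
#' participant contributes windows to both sides; this prevents identity
#' leakage between highly overlapping windows of one person. The number
#' of test participants is `max(1, round(n_participants * test_fraction))`
#' (at least one participant stays on each side). Reproducible from
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param ds a `har_dataset` with at least 2 participants.
#' @param test_fraction fraction of participants assigned to the test
#'   side, strictly between 0 and 1 (default 0.2).
#' @param seed integer seed.
#' @return List with `train` and `test` datasets (ids suffixed
#'   `/train`, `/test`) and the participant assignment.
#' @export
split_by_participant <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "har_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  parts <- sort(dataset_participants(ds))
  if (length(parts) < 2) {
    stop("subject-wise split needs at least 2 participants; with a single ",
         "participant, split at the window level explicitly instead",
         call. = FALSE)
  }
  n_test <- max(1L, min(length(parts) - 1L,
                        as.integer(round(length(parts) * test_fraction))))
  test_parts <- withr::with_seed(seed, sample(parts, n_test))
  wp <- vapply(ds$windows, function(w) w$source_participant, character(1))
  is_test <- wp %in% test_parts
  list(train = dataset_subset(ds, which(!is_test),
                              id = paste0(ds$id, "/train")),
       test = dataset_subset(ds, which(is_test),
                             id = paste0(ds$id, "/test")),
       test_participants = sort(test_parts),
       train_participants = setdiff(parts, test_parts))
}
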