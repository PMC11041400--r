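test_that("split_by_participant partitions subjects cleanly", {
  ds <- make_fake_dataset(10, participants = sprintf("p%02d", 1:10))
  sp <- split_by_participant(ds, 0.2, seed = 4)
  expect_length(sp$test_participants, 2)
  expect_length(sp$train_participants, 8)
  expect_length(intersect(dataset_participants(sp$train),
                          dataset_participants(sp$test)), 0)
  expect_equal(length(sp$train) + length(sp$test), length(ds))
  # union preserves the windows
  labs <- sort(c(vapply(sp$train$windows, function(w) w$source_offset, 0L),
                 vapply(sp$test$windows, function(w) w$source_offset, 0L)))
  expect_equal(length(labs), length(ds))

  sp2 <- split_by_participant(ds, 0.2, seed = 4)
  expect_identical(sp$test_participants, sp2$test_participants)

  one <- make_fake_dataset(2, participants = "p1")
  expect_error(split_by_participant(one, 0.2, 1), "at least 2 participants")
  expect_error(split_by_participant(ds, 1.2, 1), "strictly between")
})

test_that("training tracks history, reduces loss and is reproducible", {
  # linearly separable toy set: class fully determined by a channel offset
  mkwin <- function(code, i) {
    v <- matrix(rnorm(6 * 32, sd = 0.1), 6, 32)
    v[match(code, activity_codes()), ] <-
      v[match(code, activity_codes()), ] + 3
    harpipe:::new_window(v, code, 50, sprintf("p%d", i %% 3 + 1), 0L)
  }
  wins <- withr::with_seed(31, unlist(lapply(activity_codes(), function(cd) {
    lapply(1:8, function(i) mkwin(cd, i))
  }), recursive = FALSE))
  ds <- har_dataset(wins, id = "toy")

  cfg <- train_config(epochs = 60, batch_size = 12, learning_rate = 2e-3,
                      seed = 6)
  m <- train_classifier(build_classifier(tiny_simple_spec(32L), 1), ds, cfg)
  expect_equal(nrow(m$history), 60)
  expect_equal(m$history$epoch, 1:60)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  expect_equal(m$train_dataset_id, "toy")

  # same seed, same data => bit-identical weights and metrics
  m2 <- train_classifier(build_classifier(tiny_simple_spec(32L), 1), ds, cfg)
  expect_identical(m2$params, m$params)
  expect_identical(m2$history, m$history)

  ev <- evaluate(m, ds)
  expect_gt(ev$accuracy, 0.9)                # separable by construction

  expect_error(train_classifier(build_classifier(tiny_simple_spec(32L), 1),
                                har_dataset(list()), cfg), "empty")
  expect_error(
    train_classifier(build_classifier(tiny_simple_spec(32L), 1), ds,
                     train_config(epochs = 1, dimension_adaptive = TRUE)),
    "dana")
})

test_that("dimension-adaptive training runs and keeps output well-formed", {
  ds <- make_fake_dataset(4, window_len = 64L)
  cfg <- train_config(epochs = 2, batch_size = 12, seed = 2,
                      dimension_adaptive = TRUE)
  m <- train_classifier(build_classifier(tiny_dana_spec(), 1), ds, cfg)
  expect_equal(nrow(m$history), 2)
  # the trained dana model still yields probabilities for every config
  for (dc in default_dimension_space()) {
    w <- normalize_window(ds$windows[[1]], m$stats)
    wt <- apply_dimension_config(w, dc, mode = "drop")
    p <- predict_proba(m, list(wt))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("evaluate produces a consistent confusion matrix", {
  # zero-weight model ties everywhere -> predicts dws for every window
  mz <- zeroed_model(tiny_simple_spec(32L))
  mz$train_dataset_id <- "zero"
  dws_only <- har_dataset(lapply(1:10, function(i) {
    harpipe:::new_window(matrix(rnorm(6 * 32), 6, 32), "dws", 50, "p1", 0L)
  }), id = "dwsset")
  ev <- evaluate(mz, dws_only)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(unname(ev$confusion["dws", "dws"]), 10L)
  expect_equal(sum(ev$confusion), 10L)

  # balanced set: constant predictor scores exactly chance (1/6)
  bal <- make_fake_dataset(4, window_len = 32L)
  evb <- evaluate(mz, bal)
  expect_equal(evb$accuracy, 1 / 6)

  # accuracy from the matrix equals windowwise mean correctness (two-path)
  m <- build_classifier(tiny_simple_spec(32L), seed = 13)
  m$stats <- fit_normalization(bal)
  evm <- evaluate(m, bal)
  pred <- classify(m, lapply(bal$windows, normalize_window, stats = m$stats))
  truth <- vapply(bal$windows, function(w) w$label, "")
  expect_equal(evm$accuracy, mean(as.character(pred) == truth))
  expect_equal(sum(evm$confusion), length(bal))
  # row-normalized rows sum to 1 where populated
  rr <- confusion_rates(evm$confusion)
  expect_equal(unname(rowSums(rr)), rep(1, 6))

  expect_error(evaluate(m, har_dataset(list())), "empty")
})

test_that("cross_evaluate degenerates to evaluate and records the pair", {
  ds <- make_fake_dataset(3, window_len = 32L)
  m <- train_classifier(build_classifier(tiny_simple_spec(32L), 1), ds,
                        train_config(epochs = 1, batch_size = 12, seed = 1))
  ev <- evaluate(m, ds)
  cv <- cross_evaluate(m, ds)
  expect_equal(cv$accuracy, ev$accuracy)
  expect_equal(cv$confusion, ev$confusion)
  expect_true(cv$metadata$cross)
  expect_equal(cv$metadata$train_dataset, "fake")
  expect_equal(cv$metadata$test_dataset, "fake")
})

test_that("dimension grid evaluates every cell and matches plain evaluate", {
  ds <- make_fake_dataset(3, window_len = 64L)
  m <- train_classifier(build_classifier(tiny_dana_spec(), 1), ds,
                        train_config(epochs = 1, batch_size = 12, seed = 1))
  g <- dimension_grid_evaluate(m, ds, rates = c(50, 25),
                               masks = list(c("accelerometer", "gyroscope"),
                                            "accelerometer"))
  expect_length(g$cells, 4)
  expect_true(all(g$cells >= 0 & g$cells <= 1))
  expect_equal(unname(g$cells["50Hz|acc+gyr"]), evaluate(m, ds)$accuracy)
  expect_error(dimension_grid_evaluate(m, ds, rates = numeric(0)),
               "non-empty")
})

test_that("report writes a summary that round-trips idempotently", {
  ds <- make_fake_dataset(2, window_len = 32L)
  m <- train_classifier(build_classifier(tiny_simple_spec(32L), 1), ds,
                        train_config(epochs = 1, batch_size = 8, seed = 1))
  ev <- evaluate(m, ds)
  f1 <- withr::local_tempfile(fileext = ".json")
  report(ev, f1)
  recs <- read_summary(f1)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$accuracy, ev$accuracy)
  expect_equal(recs[[1]]$confusion, unclass(ev$confusion),
               ignore_attr = TRUE)
  expect_equal(sum(recs[[1]]$confusion), ev$n)

  # parse -> re-render is byte-identical
  f2 <- withr::local_tempfile(fileext = ".json")
  report(recs, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(report(list(), f1), "no results")
})
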