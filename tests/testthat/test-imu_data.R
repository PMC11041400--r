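test_that("CSV reader estimates the rate from timestamps and validates input", {
  f <- withr::local_tempfile(fileext = ".csv")
  header <- "timestamp,acc_x,acc_y,acc_z,rot_roll,rot_pitch,rot_yaw"
  rows <- sprintf("%.2f,%g,%g,%g,%g,%g,%g", c(0, 0.02, 0.04, 0.06),
                  1:4, 5:8, 9:12, 0.1 * (1:4), 0.2 * (1:4), 0.3 * (1:4))
  writeLines(c(header, rows), f)
  rec <- read_recording_csv(f)
  expect_equal(rec$sampling_rate, 50)          # 1 / median(0.02)
  expect_equal(ncol(rec$samples), 4L)
  expect_equal(unname(rec$samples["acc_x", ]), c(1, 2, 3, 4))
  expect_equal(rec$t0, 0)

  writeLines(header, f)
  expect_error(read_recording_csv(f), "fewer than 2 samples")

  rows_bad <- rows
  rows_bad[3] <- sub("^0.04,3", "0.04,NaNtext", rows_bad[3])
  writeLines(c(header, rows_bad), f)
  expect_error(read_recording_csv(f), "row 3")

  writeLines(c("timestamp,acc_x,acc_y", "0,1,2", "0.02,1,2"), f)
  expect_error(read_recording_csv(f), "acc_z")

  writeLines(c(header, rows[c(2, 1, 3, 4)]), f)
  expect_error(read_recording_csv(f), "non-monotonic")
})

test_that("JSON reader accepts both dialects and rejects malformed shapes", {
  f <- withr::local_tempfile(fileext = ".json")
  ch <- default_channels()$name
  data <- setNames(lapply(1:6, function(i) i * (1:100)), ch)
  jsonlite::write_json(list(participant_id = "p7", sampling_rate = 50,
                            t0 = 0, data = data),
                       f, auto_unbox = TRUE, digits = NA)
  rec <- read_recording_json(f)
  expect_equal(ncol(rec$samples), 100L)
  expect_equal(rec$sampling_rate, 50)
  expect_equal(rec$participant_id, "p7")

  data$rot_yaw <- data$rot_yaw[1:99]
  jsonlite::write_json(list(sampling_rate = 50, data = data), f,
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_recording_json(f), "unequal channel lengths")

  jsonlite::write_json(list(unexpected = 1), f, auto_unbox = TRUE)
  expect_error(read_recording_json(f), "unknown JSON shape")

  # record-per-sample dialect parses to the same recording
  df <- data.frame(timestamp = (0:99) / 50)
  for (i in seq_along(ch)) df[[ch[i]]] <- i * (1:100)
  jsonlite::write_json(list(participant_id = "p7", samples = df), f,
                       digits = NA)
  rec2 <- read_recording_json(f)
  expect_equal(rec2$samples, rec$samples)
  expect_equal(rec2$sampling_rate, 50)
})

test_that("CSV and JSON round-trips preserve values exactly", {
  rec <- synth_recording(short_plan(), default_domain_params(),
                         participant_id = "p3", seed = 42)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, fc)
  back <- read_recording_csv(fc, participant_id = "p3")
  expect_identical(unname(back$samples), unname(rec$samples))
  expect_equal(back$sampling_rate, rec$sampling_rate, tolerance = 1e-12)
  expect_identical(sample_labels(back), sample_labels(rec))

  fj <- withr::local_tempfile(fileext = ".json")
  write_recording_json(rec, fj)
  backj <- read_recording_json(fj)
  expect_identical(unname(backj$samples), unname(rec$samples))
  expect_identical(backj$sampling_rate, rec$sampling_rate)
  expect_equal(as.data.frame(backj$label_spans),
               as.data.frame(rec$label_spans))
  expect_identical(backj$participant_id, rec$participant_id)

  # CSV -> recording -> JSON -> recording keeps content
  backj2 <- read_recording_json(write_recording_json(back, fj))
  expect_identical(unname(backj2$samples), unname(rec$samples))
})

test_that("label spans validate overlap and extent", {
  rec <- make_rec(300, labels = c("wlk", "jog"))
  expect_error(label_spans(c(0, 5), c(10, 15), c("wlk", "jog")),
               "overlapping spans.*\\[0, 10\\).*\\[5, 15\\)")
  expect_error(apply_labels(rec, data.frame(start = 310, end = 320,
                                            label = "sit")),
               "outside the recording")
  expect_error(label_spans(0, 10, "run"), "unknown activity code")
  # full cover labels every sample
  expect_false(anyNA(sample_labels(rec)))
})

test_that("segment_windows matches the closed-form count and slices exactly", {
  rec <- make_rec(15000)
  wins <- segment_windows(rec, 128, 64)
  expect_length(wins, floor((15000 - 128) / 64) + 1)   # 233
  expect_length(segment_windows(make_rec(100), 128, 64), 0)
  expect_error(segment_windows(rec, 128, 0), "step")
  expect_error(segment_windows(rec, 128, 200), "step")

  # emitted values are exact slices of the parent recording (index oracle)
  w <- wins[[5]]
  o <- w$source_offset
  expect_identical(w$values, rec$samples[, (o + 1):(o + 128)])
  expect_equal(w$source_offset, 4L * 64L)

  # exhaustive small grid for the count formula
  for (L in c(1:12, 40)) {
    recL <- make_rec(L)
    for (W in seq_len(L)) {
      for (S in seq_len(W)) {
        expect_length(segment_windows(recL, W, S),
                      floor((L - W) / S) + 1)
      }
    }
  }
  # sampled large cases up to L = 2000
  withr::with_seed(99, for (i in 1:40) {
    L <- sample(500:2000, 1)
    W <- sample(seq_len(L), 1)
    S <- sample(seq_len(W), 1)
    expect_length(segment_windows(make_rec(L), W, S),
                  floor((L - W) / S) + 1)
  })
})

test_that("label policies handle boundary windows as specified", {
  # 200 samples at 50 Hz: wlk on [0, 2), jog on [2, 4)
  rec <- make_rec(200, labels = c("wlk", "jog"))
  # pure policy: windows straddling the boundary are dropped
  pure <- segment_windows(rec, 80, 20, label_policy = "pure")
  expect_true(all(vapply(pure, function(w) w$label, "") %in% c("wlk", "jog")))
  offs <- vapply(pure, function(w) w$source_offset, 0L)
  expect_false(any(offs < 100 & offs + 80 > 100))
  # majority policy keeps a 75% wlk window and labels it wlk
  maj <- segment_windows(rec, 80, 20, label_policy = "majority")
  moffs <- vapply(maj, function(w) w$source_offset, 0L)
  mlabs <- vapply(maj, function(w) w$label, "")
  expect_equal(mlabs[moffs == 40], "wlk")    # 60 of 80 samples are wlk
  expect_equal(mlabs[moffs == 80], "jog")    # 60 of 80 samples are jog
  # an exact 50/50 window has no strict majority and is dropped
  expect_false(60 %in% moffs)
})

test_that("summarize_dataset tallies all classes and ignores window order", {
  expect_equal(sum(summarize_dataset(har_dataset(list()))$by_class), 0)
  ds <- make_fake_dataset(3)
  s <- summarize_dataset(ds)
  expect_equal(s$total, 18)
  expect_equal(unname(s$by_class), rep(3L, 6))
  expect_named(s$by_class, activity_codes())
  shuf <- har_dataset(ds$windows[withr::with_seed(1, sample(18))])
  expect_equal(summarize_dataset(shuf)$by_class, s$by_class)
  expect_equal(sum(s$by_participant), s$total)
})

test_that("dataset construction enforces shared window geometry", {
  w1 <- harpipe:::new_window(matrix(0, 6, 16), "wlk", 50, "p1", 0L)
  w2 <- harpipe:::new_window(matrix(0, 6, 8), "jog", 50, "p1", 0L)
  expect_error(har_dataset(list(w1, w2)), "share")
  w3 <- harpipe:::new_window(matrix(0, 3, 16), "jog", 50, "p1", 0L)
  expect_error(har_dataset(list(w1, w3)), "share")
})
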