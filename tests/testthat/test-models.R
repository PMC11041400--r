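test_that("dap_pool matches its worked examples and conserves means", {
  expect_equal(dap_pool(matrix(1:7, 1, 7), out_time_bins = 2,
                        out_channel_bins = 1),
               matrix(c(2, 5.5), 1, 2))
  # identity when the input is already on the output grid
  M <- matrix(rnorm(12), 3, 4)
  expect_equal(dap_pool(M, 4, 3), M)
  # constants are preserved at any shape
  expect_true(all(dap_pool(matrix(3.5, 5, 17), 4, 2) == 3.5))
  # single bin recovers the grand mean
  expect_equal(dap_pool(M, 1, 1)[1, 1], mean(M))
  # replication when bins exceed the input size
  expect_equal(dap_pool(matrix(1:3, 1, 3), 5, 1),
               matrix(c(1, 1, 2, 2, 3), 1, 5))
  expect_error(dap_pool(matrix(0, 0, 3), 2, 1), "at least 1 x 1")
  expect_error(dap_spec(0, 2), ">= 1")
})

test_that("dap_pool equals the brute-force oracle on a dense grid", {
  withr::with_seed(5, {
    for (Cn in 1:6) {
      for (Tn in c(1:8, 13, 20)) {
        M <- matrix(rnorm(Cn * Tn), Cn, Tn)
        for (Cb in seq_len(Cn)) {
          for (Tb in seq_len(Tn)) {
            expect_equal(dap_pool(M, Tb, Cb), dap_brute(M, Tb, Cb),
                         tolerance = 1e-12)
          }
        }
      }
    }
  })
})

test_that("model_spec validates variants and build is seed-deterministic", {
  expect_error(model_spec("simple", dap = dap_spec()), "no dimension")
  expect_error(model_spec("dana", dap = NULL), "requires a dap_spec")
  expect_error(model_spec("simple", n_classes = 1), "n_classes")
  expect_error(model_spec("simple", conv_blocks = list(c(8, 4))), "odd")

  a <- build_classifier(tiny_simple_spec(), seed = 11)
  b <- build_classifier(tiny_simple_spec(), seed = 11)
  expect_identical(a$params, b$params)
  c <- build_classifier(tiny_simple_spec(), seed = 12)
  expect_false(identical(a$params, c$params))
  expect_equal(a$class_order, activity_codes())
})

test_that("parameter count is a pure function of the spec", {
  # hand-computed for the default simple architecture:
  # conv1 5*6*64+64, conv2 5*64*64+64, lstm 4*64*(64+64)+4*64,
  # dense 64*64+64, out 64*6+6
  expect_equal(param_count(model_spec("simple")), 60102L)
  expect_equal(param_count(build_classifier(model_spec("simple"), 3)), 60102L)
})

test_that("compiled kernels agree with the pure-R reference forwards", {
  ns <- asNamespace("harpipe")
  withr::with_seed(21, {
    for (rep in 1:5) {
      N <- sample(1:5, 1); Tn <- sample(1:30, 1); Cin <- sample(1:5, 1)
      Fo <- sample(1:6, 1); k <- sample(c(1, 3, 5), 1)
      X <- array(rnorm(N * Tn * Cin), c(N, Tn, Cin))
      W <- matrix(rnorm(k * Cin * Fo), k * Cin, Fo)
      b <- rnorm(Fo)
      expect_equal(ns$conv1d_fwd(X, W, b)$out, ns$conv1d_fwd_ref(X, W, b),
                   tolerance = 1e-12)
      expect_equal(ns$pool2_fwd(X)$out, ns$pool2_fwd_ref(X),
                   tolerance = 1e-12)
      H <- sample(2:5, 1)
      Wx <- matrix(rnorm(Cin * 4 * H), Cin, 4 * H)
      Wh <- matrix(rnorm(H * 4 * H, sd = 0.3), H, 4 * H)
      bl <- rnorm(4 * H)
      expect_equal(ns$lstm_fwd(X, Wx, Wh, bl)$h,
                   ns$lstm_fwd_ref(X, Wx, Wh, bl), tolerance = 1e-10)
    }
  })
})

test_that("analytic gradients match finite differences (both variants)", {
  ns <- asNamespace("harpipe")
  check_grads <- function(spec, X, n_coord = 40) {
    m <- build_classifier(spec, seed = 7)
    y <- withr::with_seed(1, sample.int(6, dim(X)[1], replace = TRUE))
    lg <- ns$model_loss_grads(m$params, spec, X, y)
    flat <- ns$params_flatten(m$params)
    gflat <- ns$params_flatten(lg$grads)
    idx <- withr::with_seed(2, sort(sample(length(flat), n_coord)))
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      p1 <- flat; p1[i] <- p1[i] + eps
      p2 <- flat; p2[i] <- p2[i] - eps
      l1 <- ns$model_loss_grads(ns$params_unflatten(p1, m$params), spec, X, y)$loss
      l2 <- ns$model_loss_grads(ns$params_unflatten(p2, m$params), spec, X, y)$loss
      (l1 - l2) / (2 * eps)
    }, numeric(1))
    max(abs(num - gflat[idx]))
  }
  Xs <- withr::with_seed(3, array(rnorm(5 * 32 * 6), c(5, 32, 6)))
  expect_lt(check_grads(tiny_simple_spec(32L), Xs), 1e-6)
  Xd <- withr::with_seed(4, array(rnorm(4 * 20 * 4), c(4, 20, 4)))
  expect_lt(check_grads(tiny_dana_spec(), Xd), 1e-6)
})

test_that("dana accepts varying input shapes; simple refuses them", {
  md <- build_classifier(tiny_dana_spec(), seed = 2)
  mkwin <- function(C, T) {
    harpipe:::new_window(matrix(rnorm(C * T), C, T), "wlk", 50, "p", 0L)
  }
  withr::with_seed(6, {
    p1 <- predict_proba(md, list(mkwin(3, 64)))
    p2 <- predict_proba(md, list(mkwin(6, 128)))
  })
  expect_equal(rowSums(p1), 1, tolerance = 1e-6)
  expect_equal(rowSums(p2), 1, tolerance = 1e-6)
  expect_equal(ncol(p1), 6)

  ms <- build_classifier(tiny_simple_spec(32L), seed = 2)
  expect_error(predict_proba(ms, list(mkwin(3, 32))), "shape error")
  expect_error(predict_proba(ms, list(mkwin(6, 16))), "shape error")
})

test_that("predict_proba returns well-formed, deterministic probabilities", {
  m <- build_classifier(tiny_simple_spec(32L), seed = 9)
  expect_equal(dim(predict_proba(m, list())), c(0L, 6L))
  w <- withr::with_seed(8, harpipe:::new_window(
    matrix(rnorm(6 * 32), 6, 32), "jog", 50, "p", 0L))
  p <- predict_proba(m, list(w, w, w))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(p[1, ], p[2, ])           # duplicated input, same row
  expect_identical(p, predict_proba(m, list(w, w, w)))  # inference is pure
})

test_that("classify is the argmax of predict_proba with first-class ties", {
  m <- build_classifier(tiny_simple_spec(32L), seed = 10)
  wins <- withr::with_seed(12, lapply(1:50, function(i) {
    harpipe:::new_window(matrix(rnorm(6 * 32), 6, 32), "wlk", 50, "p", 0L)
  }))
  p <- predict_proba(m, wins)
  expect_identical(as.character(classify(m, wins)),
                   m$class_order[max.col(p, ties.method = "first")])
  # all-zero weights give exactly tied probabilities -> first class wins
  mz <- zeroed_model(tiny_simple_spec(32L))
  expect_equal(as.character(classify(mz, wins[1:4])), rep("dws", 4))
})

test_that("model bundles save and load losslessly", {
  ds <- make_fake_dataset(2, window_len = 32L)
  m <- build_classifier(tiny_simple_spec(32L), seed = 5)
  m <- train_classifier(m, ds, train_config(epochs = 1, seed = 3,
                                            batch_size = 8))
  dir <- withr::local_tempdir()
  save_model_bundle(m, dir)
  expect_true(all(file.exists(file.path(dir, c("spec.json", "weights.rds",
                                               "norm_stats.json",
                                               "history.json")))))
  m2 <- load_model_bundle(dir)
  expect_identical(m2$params, m$params)
  expect_equal(m2$spec, m$spec)
  expect_equal(m2$stats$mean, m$stats$mean)
  p <- predict_proba(m, lapply(ds$windows[1:3], normalize_window,
                               stats = m$stats))
  p2 <- predict_proba(m2, lapply(ds$windows[1:3], normalize_window,
                                 stats = m2$stats))
  expect_identical(p, p2)
})
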