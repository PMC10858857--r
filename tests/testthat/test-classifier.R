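test_that("LReLU scales negatives by exactly the configured slope", {
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(lrelu(x, 0.1), c(-0.2, -0.05, 0, 0.5, 2))
  expect_equal(lrelu(x, 0.3)[1], -0.6)
  m <- matrix(c(-1, 1, -4, 4), 2)
  expect_equal(lrelu(m, 0.1), matrix(c(-0.1, 1, -0.4, 4), 2))
})

test_that("LSTM cell reproduces the hand-computed two-unit fixture", {
  fx <- lstm_fixture()
  st <- lstm_cell_step(fx$x, fx$h_prev, fx$C_prev, fx$wts)
  expect_equal(st$C, fx$expected_C, tolerance = 1e-10)
  expect_equal(st$h, fx$expected_h, tolerance = 1e-10)
})

test_that("LSTM cell limits: zero weights and saturated forget gate", {
  Hn <- 3
  zw <- list(Wxi = matrix(0, Hn, 2), Whi = matrix(0, Hn, Hn),
             wci = rep(0, Hn), bi = rep(0, Hn),
             Wxf = matrix(0, Hn, 2), Whf = matrix(0, Hn, Hn),
             wcf = rep(0, Hn), bf = rep(0, Hn),
             Wxo = matrix(0, Hn, 2), Who = matrix(0, Hn, Hn),
             wco = rep(0, Hn), bo = rep(0, Hn),
             Wxc = matrix(0, Hn, 2), Whc = matrix(0, Hn, Hn),
             bc = rep(0, Hn))
  C_prev <- c(0.4, -0.8, 0)
  st <- lstm_cell_step(c(1, -1), rep(0, Hn), C_prev, zw)
  # sigma(0) = 0.5, tanh(0) = 0: C halves, h = 0.5 * tanh(C)
  expect_equal(st$C, 0.5 * C_prev)
  expect_equal(st$h, 0.5 * tanh(0.5 * C_prev))
  # forget bias -> +inf: memory fully preserved plus the gated candidate
  zw$bf <- rep(1e3, Hn)
  st2 <- lstm_cell_step(c(1, -1), rep(0, Hn), C_prev, zw)
  expect_equal(st2$C, C_prev + 0.5 * 0)
})

test_that("sequence kernel agrees with composed single cell steps", {
  set.seed(6)
  D <- 3; Hn <- 4; Tn <- 6
  Wx <- matrix(rnorm(4 * Hn * D), 4 * Hn, D)
  Wh <- matrix(rnorm(4 * Hn * Hn) * 0.3, 4 * Hn, Hn)
  b <- rnorm(4 * Hn); wci <- rnorm(Hn); wcf <- rnorm(Hn); wco <- rnorm(Hn)
  X <- array(rnorm(D * 2 * Tn), c(D, 2, Tn))
  lf <- mfccsleep:::nn_lstm_fw(X, Wx, Wh, b, wci, wcf, wco)
  sl <- function(g) (g * Hn + 1):((g + 1) * Hn)
  wts <- list(Wxi = Wx[sl(0), ], Wxf = Wx[sl(1), ], Wxo = Wx[sl(2), ],
              Wxc = Wx[sl(3), ], Whi = Wh[sl(0), ], Whf = Wh[sl(1), ],
              Who = Wh[sl(2), ], Whc = Wh[sl(3), ],
              wci = wci, wcf = wcf, wco = wco,
              bi = b[sl(0)], bf = b[sl(1)], bo = b[sl(2)], bc = b[sl(3)])
  for (batch in 1:2) {
    h <- rep(0, Hn); C <- rep(0, Hn)
    for (t in 1:Tn) {
      st <- lstm_cell_step(X[, batch, t], h, C, wts)
      h <- st$h; C <- st$C
    }
    expect_equal(lf$h_last[, batch], h, tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation on a tiny model", {
  set.seed(7)
  cfg <- model_config(conv_filters = c(2, 2, 2, 3), lstm_units = 4, seed = 3)
  H <- 12; W <- 30
  model <- build_model(cfg, c(H, W))
  X <- matrix(rnorm(H * W * 3), ncol = 3)
  y <- c(1L, 3L, 5L)
  fw <- mfccsleep:::model_forward(model, X, keep_cache = TRUE)
  gr <- mfccsleep:::model_backward(model, fw$cache, y)
  loss_fn <- function(m) {
    pr <- mfccsleep:::model_forward(m, X)$probs
    mean(-log(pr[cbind(y, seq_along(y))]))
  }
  eps <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + eps
      m3 <- model; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      rel <- abs(num - gr[[nm]][i]) / max(1e-6, abs(num) + abs(gr[[nm]][i]))
      expect_lt(rel, 1e-3)
    }
  }
})

test_that("model construction is seeded, counted, and shape-checked", {
  cfg <- model_config(seed = 42)
  m1 <- build_model(cfg, c(39, 357))
  m2 <- build_model(cfg, c(39, 357))
  expect_identical(m1$params, m2$params)
  # parameter count strictly increases with LSTM width
  counts <- vapply(c(16, 32, 64, 128), function(u) {
    build_model(model_config(lstm_units = u), c(39, 357))$n_params
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
  # too-small input names the failing layer
  expect_error(build_model(cfg, c(3, 8)), "pool")
})

test_that("softmax outputs stay on the simplex for random inputs", {
  set.seed(11)
  model <- build_model(model_config(conv_filters = c(2, 2, 2, 3),
                                    lstm_units = 6, seed = 2), c(13, 36))
  X <- matrix(rnorm(13 * 36 * 20, sd = 5), ncol = 20)
  pr <- mfccsleep:::model_forward(model, X)$probs
  expect_true(all(pr >= 0))
  expect_equal(unname(colSums(pr)), rep(1, 20), tolerance = 1e-6)
})

test_that("prediction is deterministic and batch-order independent", {
  set.seed(13)
  model <- build_model(model_config(conv_filters = c(2, 2, 2, 3),
                                    lstm_units = 6, seed = 5), c(13, 36))
  mk <- function(i) {
    structure(list(tensor = matrix(rnorm(13 * 36), 13), label = "W",
                   subject_id = "a", epoch_index = i),
              class = "feature_stream")
  }
  set.seed(99)
  streams <- lapply(1:7, mk)
  p1 <- predict_stages(model, streams)
  p2 <- predict_stages(model, streams)
  expect_identical(p1$probs, p2$probs)
  # same stream twice -> identical prediction rows, in input order
  p3 <- predict_stages(model, streams[c(3, 1, 3)])
  expect_equal(p3$probs[1, ], p1$probs[3, ], tolerance = 1e-12)
  expect_equal(p3$probs[3, ], p1$probs[3, ], tolerance = 1e-12)
  expect_equal(nrow(p3$probs), 3)
  # shape mismatch is caught
  bad <- structure(list(tensor = matrix(0, 10, 10), label = "W",
                        subject_id = "a", epoch_index = 1),
                   class = "feature_stream")
  expect_error(predict_stages(model, list(bad)), "does not match")
})

test_that("training refuses degenerate inputs and freezes at zero learning rate", {
  mk <- function(lab, id, i, mu) {
    structure(list(tensor = matrix(rnorm(13 * 36, mean = mu), 13),
                   label = lab, subject_id = id, epoch_index = i),
              class = "feature_stream")
  }
  set.seed(21)
  single <- lapply(1:12, function(i) mk("S2", "a", i, 0))
  val <- lapply(1:4, function(i) mk(sample(stages(), 1), "b", i, 0))
  cfg <- model_config(conv_filters = c(2, 2, 2, 3), lstm_units = 6,
                      batch_size = 4, max_epochs = 1, seed = 1)
  model <- build_model(cfg, c(13, 36))
  expect_error(train_model(model, single, val), "single class")
  # lr = 0: parameters unchanged, history flat
  mixed <- lapply(1:12, function(i) mk(stages()[(i %% 5) + 1], "a", i, 0))
  cfg0 <- model_config(conv_filters = c(2, 2, 2, 3), lstm_units = 6,
                       batch_size = 4, learning_rate = 0, max_epochs = 2,
                       patience = 5, seed = 1)
  m0 <- build_model(cfg0, c(13, 36))
  t0 <- train_model(m0, mixed, val)
  expect_equal(t0$params, m0$params)
  expect_equal(t0$history$train_loss[1], t0$history$train_loss[2],
               tolerance = 1e-9)
})

test_that("first-epoch loss starts near the uniform-softmax baseline", {
  mk <- function(lab, id, i) {
    structure(list(tensor = matrix(rnorm(13 * 36), 13),
                   label = lab, subject_id = id, epoch_index = i),
              class = "feature_stream")
  }
  set.seed(31)
  train <- lapply(1:40, function(i) mk(stages()[(i %% 5) + 1], "a", i))
  val <- lapply(1:10, function(i) mk(stages()[(i %% 5) + 1], "b", i))
  cfg <- model_config(conv_filters = c(2, 2, 2, 3), lstm_units = 6,
                      batch_size = 40, learning_rate = 0, max_epochs = 1,
                      seed = 2)
  model <- train_model(build_model(cfg, c(13, 36)), train, val)
  expect_equal(model$history$train_loss[1], log(5), tolerance = 0.15)
})

test_that("the network learns strongly separable synthetic streams", {
  # class-dependent mean patterns, light noise: trainable in a few epochs
  mk <- function(lab, id, i) {
    base <- outer(sin(seq(0, pi, length.out = 13) * match(lab, stages())),
                  cos(seq(0, 2 * pi, length.out = 36)))
    structure(list(tensor = 2 * base + matrix(rnorm(13 * 36, sd = 0.3), 13),
                   label = lab, subject_id = id, epoch_index = i),
              class = "feature_stream")
  }
  set.seed(17)
  train <- lapply(1:200, function(i) mk(stages()[(i %% 5) + 1], "a", i))
  val <- lapply(1:50, function(i) mk(stages()[(i %% 5) + 1], "b", i))
  cfg <- model_config(conv_filters = c(4, 4, 4, 8), lstm_units = 16,
                      batch_size = 50, max_epochs = 30, patience = 30,
                      seed = 3)
  model <- train_model(build_model(cfg, c(13, 36)), train, val)
  expect_gt(utils::tail(model$history$train_acc, 1), 0.95)
  # history bookkeeping
  expect_true(all(c("epoch", "train_loss", "train_acc", "val_loss",
                    "val_acc") %in% names(model$history)))
  expect_true(model$trained)
})

test_that("checkpoints round-trip through disk", {
  model <- build_model(model_config(conv_filters = c(2, 2, 2, 3),
                                    lstm_units = 4, seed = 9), c(13, 36))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  expect_identical(load_checkpoint(f)$params, model$params)
})
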