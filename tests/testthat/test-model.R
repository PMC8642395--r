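test_that("losses match their closed forms and reject length mismatch", {
  eps <- 1e-9
  expect_equal(bce_loss(c(1, 0), c(1 - eps, eps)), 0, tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(0.5, 0.5), log(2))   # fractional label
  expect_error(bce_loss(c(1, 0), 0.5), "length")
  expect_gte(bce_loss(runif(10), runif(10)), 0)

  expect_equal(mse_monitor(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(mse_monitor(c(1, 0), c(0.5, 0.5)), 0.25)
  set.seed(2)
  y <- runif(50); yh <- runif(50)
  brute <- 0
  for (i in seq_along(y)) brute <- brute + (y[i] - yh[i])^2
  expect_equal(mse_monitor(y, yh), brute / 50)
  expect_error(mse_monitor(1, c(0.5, 0.5)), "length")
  expect_lte(mse_monitor(runif(20), runif(20)), 1)
})

test_that("the network maps a 50 x 1024 stack to a probability in (0, 1)", {
  m <- build_model(width_scale = 0.0625, seed = 1)
  p0 <- predict_beats(m, matrix(0, 50, 1024))
  expect_length(p0, 1)
  expect_gt(p0, 0); expect_lt(p0, 1)
  X <- array(rnorm(50 * 1024 * 3), c(50, 1024, 3))
  p3 <- predict_beats(m, X)
  expect_length(p3, 3)
  expect_true(all(p3 > 0 & p3 < 1))
  expect_error(predict_beats(m, matrix(0, 40, 1024)), "geometry")
})

test_that("parameter count at full width matches the architecture arithmetic", {
  m <- build_model(width_scale = 1, seed = 1)
  # independent count: 7x7 stem conv, four stages of two basic blocks
  # (3x3 convs + batch-norm affine pairs, 1x1 downsample at stage entry),
  # and the single-output head, for 1 input channel
  w <- c(64, 128, 256, 512)
  expected <- 7 * 7 * 1 * 64 + 2 * 64         # stem + bn
  cin <- 64
  for (i in 1:4) for (j in 1:2) {
    expected <- expected + 9 * cin * w[i] + 2 * w[i] +   # conv_a + bn
                           9 * w[i] * w[i] + 2 * w[i]    # conv_b + bn
    if (j == 1 && i > 1)
      expected <- expected + cin * w[i] + 2 * w[i]       # downsample + bn
    cin <- w[i]
  }
  expected <- expected + 512 + 1                          # head
  expect_equal(n_parameters(m), expected)
  # canonical 18-layer residual net adapted to 1 input channel / 1 output
  expect_lt(abs(n_parameters(m) - 11170753) / 11170753, 0.05)
})

test_that("training reduces the loss and returns the best checkpoint", {
  ds <- fixture_stack_dataset()
  cfg <- train_config(learning_rate = 1e-3, batch_size = 32,
                      patience_epochs = 10, max_epochs = 5, seed = 21)
  m <- ks_train(ds, cfg, width_scale = 0.0625)
  h <- m$history
  expect_lt(h$train_bce[nrow(h)], h$train_bce[1])
  expect_equal(m$val_mse, min(h$val_mse))
  expect_equal(m$best_epoch, which.min(h$val_mse))
  # the returned parameters really are the checkpoint, not the last state
  vp <- predict_beats(m, ds$x_val)
  expect_equal(mse_monitor(ds$y_val, vp), m$val_mse, tolerance = 1e-10)
})

test_that("early stopping triggers after patience epochs without improvement", {
  ds <- fixture_stack_dataset()
  # zero learning rate freezes the parameters: no epoch can improve
  sub <- list(x_train = ds$x_train[1:16], y_train = ds$y_train[1:16],
              x_val = ds$x_val[1:8], y_val = ds$y_val[1:8])
  cfg <- train_config(learning_rate = 1e-12, batch_size = 16,
                      patience_epochs = 3, max_epochs = 50, seed = 5)
  m <- ks_train(sub, cfg, width_scale = 0.0625, augment = FALSE)
  expect_equal(nrow(m$history), 1 + 3)   # first epoch sets best, then wait
  expect_equal(m$best_epoch, 1L)
})

test_that("training is deterministic under a fixed seed", {
  ds <- fixture_stack_dataset()
  sub <- list(x_train = ds$x_train[1:24], y_train = ds$y_train[1:24],
              x_val = ds$x_val[1:8], y_val = ds$y_val[1:8])
  cfg <- train_config(learning_rate = 1e-3, batch_size = 12,
                      patience_epochs = 5, max_epochs = 3, seed = 77)
  m1 <- ks_train(sub, cfg, width_scale = 0.0625)
  m2 <- ks_train(sub, cfg, width_scale = 0.0625)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_error(ks_train(list(x_train = list(), y_train = numeric(0),
                             x_val = sub$x_val, y_val = sub$y_val), cfg),
               "non-empty")
})

test_that("a model trained on synthetic data separates audible from silent beats", {
  ds <- fixture_stack_dataset()
  cfg <- train_config(learning_rate = 1e-3, batch_size = 32,
                      patience_epochs = 10, max_epochs = 5, seed = 21)
  m <- ks_train(ds, cfg, width_scale = 0.0625)
  vp <- predict_beats(m, ds$x_val)
  expect_gt(mean(vp[ds$y_val >= 0.98]), mean(vp[ds$y_val <= 0.02]))
})

test_that("random search draws from the stated ranges and returns the argmin", {
  ds <- fixture_stack_dataset()
  sub <- list(x_train = ds$x_train[1:24], y_train = ds$y_train[1:24],
              x_val = ds$x_val[1:8], y_val = ds$y_val[1:8])
  base <- train_config(patience_epochs = 2, max_epochs = 2)
  best <- random_search(3, sub, seed = 3, base_cfg = base,
                        width_scale = 0.0625)
  tab <- best$search
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$learning_rate >= 1e-5 & tab$learning_rate <= 1e-2))
  expect_true(all(tab$weight_decay >= 1e-6 & tab$weight_decay <= 1e-3))
  expect_true(all(tab$batch_size %in% c(16, 32, 64, 128)))
  expect_equal(best$val_mse, min(tab$val_mse))
  # reproducible selection
  best2 <- random_search(3, sub, seed = 3, base_cfg = base,
                         width_scale = 0.0625)
  expect_identical(best$search, best2$search)
})
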