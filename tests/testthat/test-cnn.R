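test_that("the default configuration counts 17 layers and validates", {
  cfg <- model_config()
  expect_equal(hotspotEEG:::n_layers(cfg), 17)  # 10 conv + 4 pool + 3 dense
  expect_error(model_config(dense_sizes = c(256, 64, 2)), "width 3")
  expect_error(model_config(lr = -1))
})

test_that("the architecture report reproduces the reference layer table", {
  m <- build_model(model_config(), c(63, 200))
  rep_ <- m$layer_report
  convs <- rep_[grepl("^Conv", rep_$name), ]
  expect_equal(nrow(convs), 10)
  expect_equal(convs$n_filters, c(16, 16, 32, 32, 64, 64, 64, 128, 128, 128))
  expect_true(all(convs$kernel == "7x7"))
  expect_true(all(convs$stride == 1))
  pools <- rep_[grepl("^Max-pooling", rep_$name), ]
  expect_equal(nrow(pools), 4)
  expect_true(all(pools$kernel == "2x2"))
  expect_true(all(pools$stride == 2))
  expect_equal(pools$n_filters, c(16, 32, 64, 128))
  denses <- rep_[grepl("^Dense", rep_$name), ]
  expect_equal(nrow(denses), 3)
  expect_equal(denses$output_shape[3], "3")
  # spatial size after 4 ceil-pools of (63, 200): (4, 13)
  expect_equal(pools$output_shape[4], "4x13x128")
  expect_equal(rep_$output_shape[rep_$name == "Flatten"],
               as.character(4 * 13 * 128))

  m2 <- build_model(model_config(), c(9, 200))
  p2 <- m2$layer_report[grepl("^Max-pooling", m2$layer_report$name), ]
  expect_equal(p2$output_shape,
               c("5x100x16", "3x50x32", "2x25x64", "1x13x128"))

  expect_error(build_model(model_config(), c(4, 200)), "minimum")
})

test_that("standardization uses training statistics only", {
  set.seed(1)
  train <- array(rnorm(10 * 3 * 8, mean = 5, sd = 2), c(10, 3, 8))
  test <- array(rnorm(4 * 3 * 8, mean = 9, sd = 2), c(4, 3, 8))
  std <- standardize_inputs(train, test)
  for (ch in 1:3) {
    expect_equal(mean(std$train[, ch, ]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(as.vector(std$train[, ch, ])), 1, tolerance = 1e-2)
  }
  # the shifted test set is not self-normalized under train statistics
  expect_gt(mean(std$applied[[1]]), 1)

  const <- train; const[, 2, ] <- 7
  expect_warning(stdc <- standardize_inputs(const), "zero-variance")
  expect_true(all(stdc$train[, 2, ] == 0))
})

test_that("training fits a constant target and is seed-reproducible", {
  set.seed(5)
  one <- array(rnorm(6 * 40), c(1, 6, 40))
  x <- array(one[rep(1, 20), , ], c(20, 6, 40))
  target <- c(10, -20, 30)
  cfg <- tiny_config(max_epochs = 300, patience = 300, seed = 42)
  fit <- hotspot_cnn(x, target, config = cfg)
  p <- predict(fit, x, type = "subject")
  expect_lt(euclidean_error(p, target), 2)
  expect_lt(utils::tail(fit$history$train_mse, 1),
            fit$history$train_mse[1])

  fit2 <- hotspot_cnn(x, target, config = cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)

  # residuals/fitted accessors are consistent
  expect_equal(residuals(fit), fit$y_train - fit$fitted)
})

test_that("early stopping respects patience and restores the best epoch", {
  set.seed(6)
  # pure-noise targets: validation loss cannot keep improving
  x <- array(rnorm(20 * 6 * 40), c(20, 6, 40))
  y <- matrix(rnorm(20 * 3, sd = 30), 20, 3)
  cfg <- tiny_config(max_epochs = 400, patience = 7, seed = 3)
  fit <- hotspot_cnn(x[1:15, , ], y[1:15, ], val_x = x[16:20, , ],
                     val_y = y[16:20, ], config = cfg)
  expect_lte(fit$stopped_epoch, 400)
  if (fit$stopped_epoch < 400)
    expect_equal(fit$stopped_epoch - fit$best_epoch, 7)
  expect_equal(fit$best_val_mse, min(fit$history$val_mse))
  expect_lte(fit$best_epoch, fit$stopped_epoch)
})

test_that("prediction is trial-permutation invariant and checks shapes", {
  set.seed(7)
  x <- array(rnorm(12 * 6 * 40), c(12, 6, 40))
  fit <- hotspot_cnn(x, c(0, 10, 20), config = tiny_config(seed = 2))
  p <- predict(fit, x)
  expect_equal(dim(p), c(12, 3))
  perm <- sample(12)
  expect_equal(colMeans(p[perm, ]), predict(fit, x[perm, , ], type = "subject"))
  # duplicated trial set gives the identical subject-level mean
  xdup <- x[c(1:12, 1:12), , ]
  expect_equal(predict(fit, xdup, type = "subject"),
               predict(fit, x, type = "subject"))
  expect_error(predict(fit, array(0, c(2, 5, 40))), "shape mismatch")
  h <- predict_hotspot(fit, x)
  expect_s3_class(h, "hotspot_location")
  expect_equal(h$source, "predicted")
})

test_that("the model learns a linearly decodable synthetic mapping", {
  # targets are a linear readout of per-channel offsets; the trained
  # network must beat the predict-the-mean baseline in every seeded run
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  wins <- 0
  n_runs <- 8
  for (run in seq_len(n_runs)) {
    set.seed(100 + run)
    n <- 120
    offs <- matrix(runif(n * 6, -5, 5), n, 6)
    x <- array(rnorm(n * 6 * 40, sd = 0.3), c(n, 6, 40)) +
      array(rep(offs, 40), c(n, 6, 40))
    y <- 10 * offs[, 1:3] + matrix(rnorm(n * 3, sd = 0.5), n, 3)
    tr <- 1:100; te <- 101:120
    fit <- hotspot_cnn(x[tr, , ], y[tr, ],
                       config = tiny_config(max_epochs = 300, patience = 300,
                                            seed = run,
                                            conv_blocks = list(c(1, 8)),
                                            dense_sizes = c(16, 3)))
    pred <- predict(fit, x[te, , ])
    base <- matrix(colMeans(y[tr, ]), length(te), 3, byrow = TRUE)
    if (rmse(pred, y[te, ]) < rmse(base, y[te, ])) wins <- wins + 1
  }
  expect_gte(wins / n_runs, 0.95)
})
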