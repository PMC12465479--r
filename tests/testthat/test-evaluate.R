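test_that("the error distance is the 3D Euclidean metric", {
  expect_equal(euclidean_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_error(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_equal(euclidean_error(c(1, 1, 1), c(1, 1, 1)), 0)
  h1 <- hotspot_location(-40, 10, 50, "tms_ground_truth")
  h2 <- hotspot_location(-43, 14, 50, "predicted")
  expect_equal(euclidean_error(h1, h2), 5)

  set.seed(1)
  for (i in 1:50) {
    a <- rnorm(3, sd = 20); b <- rnorm(3, sd = 20); c_ <- rnorm(3, sd = 20)
    expect_equal(euclidean_error(a, b), euclidean_error(b, a))
    expect_gte(euclidean_error(a, b), 0)
    expect_lte(euclidean_error(a, c_),
               euclidean_error(a, b) + euclidean_error(b, c_) + 1e-12)
  }
})

test_that("fold plans partition trials with a 4:1 inner split", {
  plan <- cv_fold_plan(30, k_outer = 5, n_repeats = 5, seed = 3)
  expect_length(plan, 5)
  for (rep_ in plan) {
    tests <- lapply(rep_$folds, `[[`, "test")
    expect_true(all(lengths(tests) == 6))
    expect_equal(sort(unlist(tests)), 1:30)  # disjoint and exhaustive
    for (f in rep_$folds) {
      expect_length(f$train, 19)
      expect_length(f$val, 5)
      expect_equal(sort(c(f$test, f$train, f$val)), 1:30)
    }
  }
  expect_equal(sum(lengths(lapply(plan, `[[`, "folds"))), 25)

  # exact replay
  expect_identical(plan, cv_fold_plan(30, 5, 5, seed = 3))
  expect_false(identical(plan, cv_fold_plan(30, 5, 5, seed = 4)))

  # uneven splits differ by at most one trial
  p28 <- cv_fold_plan(28, 5, 1, seed = 1)
  expect_true(all(lengths(lapply(p28[[1]]$folds, `[[`, "test")) %in% 5:6))
  # minimum size: every outer fold non-empty
  p5 <- cv_fold_plan(5, 5, 1, seed = 1)
  expect_true(all(lengths(lapply(p5[[1]]$folds, `[[`, "test")) == 1))
  expect_true(all(lengths(lapply(p5[[1]]$folds, `[[`, "val")) == 1))
  expect_error(cv_fold_plan(4, 5, 1, 1), "at least")
})

test_that("nested CV accounts for folds without leakage", {
  set.seed(11)
  x <- array(rnorm(10 * 6 * 40), c(10, 6, 40))
  cv <- nested_cv(x, c(-40, 10, 50), tiny_config(max_epochs = 2, seed = 1),
                  k_outer = 5, n_repeats = 2, seed = 9,
                  subject_id = "sX", hand = "right")
  expect_equal(cv$n_outer_evals, 10)
  expect_true(all(cv$folds$error_mm >= 0))
  for (r in unique(cv$folds$repetition)) {
    tests <- cv$folds$test_idx[cv$folds$repetition == r]
    expect_equal(sort(unlist(tests)), 1:10)
    # no test trial appears in its fold's train or val set
    for (k in seq_along(tests)) {
      f <- cv$plan[[r]]$folds[[k]]
      expect_length(intersect(f$test, c(f$train, f$val)), 0)
    }
  }
  expect_equal(cv$mean_error_mm, mean(cv$folds$error_mm))
  expect_equal(cv$subject_id, "sX")

  # restriction to a subset of outer folds
  cv1 <- nested_cv(x, c(-40, 10, 50), tiny_config(max_epochs = 2, seed = 1),
                   n_repeats = 1, outer_folds = 1, seed = 9)
  expect_equal(cv1$n_outer_evals, 1)
})

test_that("a constant-output model recovers its target exactly", {
  # degenerate check of the fold bookkeeping: if the model always predicts
  # the truth, every fold error is 0
  set.seed(12)
  x <- array(rnorm(10 * 6 * 40), c(10, 6, 40))
  truth <- c(5, -5, 10)
  plan <- cv_fold_plan(10, 5, 1, seed = 2)
  errs <- vapply(plan[[1]]$folds, function(f) {
    pred <- colMeans(matrix(truth, length(f$test), 3, byrow = TRUE))
    euclidean_error(pred, truth)
  }, numeric(1))
  expect_true(all(errs == 0))
})

test_that("the mean predictor is the chance-level baseline", {
  b1 <- baseline_mean_predictor(matrix(c(1, 2, 3), 1))
  expect_equal(unname(predict(b1)[1, ]), c(1, 2, 3))
  tr <- rbind(c(10, 0, 5), c(-10, 0, -5))
  b2 <- baseline_mean_predictor(tr)
  expect_equal(unname(predict(b2)[1, ]), c(0, 0, 0))
  expect_equal(nrow(predict(b2, 7)), 7)
  hs <- list(hotspot_location(-40, 10, 50, "tms_ground_truth"),
             hotspot_location(-44, 14, 54, "tms_ground_truth"))
  expect_equal(unname(predict(baseline_mean_predictor(hs))[1, ]),
               c(-42, 12, 52))
  # Monte-Carlo: baseline error approximates the spread of the hotspot prior
  m <- load_montage("healthy63")
  cfg <- synth_config("healthy")
  set.seed(13)
  pts <- t(vapply(1:60, function(i)
    hotspotEEG:::as_coord(sample_hotspot(m, "right", cfg)), numeric(3)))
  base <- baseline_mean_predictor(pts)
  errs <- apply(pts, 1, function(p) euclidean_error(predict(base)[1, ], p))
  spread <- mean(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  expect_equal(mean(errs), spread, tolerance = 1e-9)
  expect_gt(mean(errs), 3)  # jitter makes chance level several mm
})

test_that("the condition grid ablates trials with nested subsets", {
  s <- small_subject(n_trials = 6, seed = 31, cohort = "stroke")
  grid <- run_condition_grid(
    list(s), levels = 1, channel_sets = "Set3", trial_counts = c(6, 4, 3),
    config = tiny_config(max_epochs = 2, seed = 1), seed = 5,
    hands = "right", k_outer = 3, n_repeats = 1, outer_folds = 1)
  expect_equal(nrow(grid$summaries), 3)
  expect_equal(grid$summaries$n, rep(1, 3))
  subsets <- lapply(grid$results, `[[`, "trial_subset")
  expect_true(all(subsets[[3]] %in% subsets[[2]]))
  expect_true(all(subsets[[2]] %in% subsets[[1]]))
  expect_equal(lengths(subsets), c(6, 4, 3))
  expect_equal(grid$results[[2]]$channel_set, "Set3")
  expect_error(run_condition_grid(
    list(s), 1, "Set3", trial_counts = 50,
    config = tiny_config(), seed = 1, hands = "right"), "exceeds")
})
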