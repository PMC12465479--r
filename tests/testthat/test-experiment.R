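mini_config <- function(dir, n_subjects = 2, n_trials = 5) {
  list(
    cohort = "stroke", seed = 7, output_dir = dir,
    synthetic = list(n_subjects = n_subjects, n_trials = n_trials),
    evaluation = list(levels = 1, channel_sets = "Set3",
                      trial_counts = n_trials, hands = "right",
                      k_outer = 2, n_repeats = 1, outer_folds = 1),
    model = list(conv_blocks = list(c(1, 4)), dense_sizes = c(8, 3),
                 max_epochs = 2, patience = 2)
  )
}

test_that("a minimal experiment produces a complete artifact directory", {
  dir <- withr::local_tempdir()
  res <- run_experiment(mini_config(dir))
  expect_true(file.exists(file.path(dir, "config_resolved.json")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "cohort", "hotspots.csv")))
  expect_length(list.files(file.path(dir, "cohort"), pattern = "\\.edf$"), 2)
  sum_ <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(sum_), 1)
  expect_equal(sum_$n, 2)
  expect_true(sum_$mean_error_mm >= 0)
  expect_equal(res$summaries$condition, "Input_1|Set3|5 trials")
})

test_that("re-running the same configuration reproduces summary.csv", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_experiment(mini_config(d1))
  run_experiment(mini_config(d2))
  expect_identical(readBin(file.path(d1, "summary.csv"), raw(), 1e5),
                   readBin(file.path(d2, "summary.csv"), raw(), 1e5))
})

test_that("configuration validation names the offending field", {
  dir <- withr::local_tempdir()
  bad <- mini_config(dir)
  bad$evaluation$trial_counts <- 50
  expect_error(run_experiment(bad), "evaluation.trial_counts", fixed = TRUE)
  bad2 <- mini_config(dir)
  bad2$synthetic$snr_wrong <- 3
  expect_error(run_experiment(bad2), "synthetic.snr_wrong", fixed = TRUE)
  bad3 <- mini_config(dir)
  bad3$cohort <- "mice"
  expect_error(run_experiment(bad3), "cohort")
  bad4 <- mini_config(dir)
  bad4$evaluation$levels <- 3  # stroke analyses are raw-data only
  expect_error(run_experiment(bad4), "raw data")
  bad5 <- mini_config(dir)
  bad5$output_dir <- NULL
  expect_error(run_experiment(bad5), "output_dir")
})

test_that("a YAML config drives the experiment and the CLI entry point", {
  dir <- withr::local_tempdir()
  cfgfile <- file.path(dir, "cfg.yaml")
  cfg <- mini_config(file.path(dir, "out"))
  yaml::write_yaml(cfg, cfgfile)
  res <- run_experiment(cfgfile)
  expect_true(file.exists(file.path(dir, "out", "summary.csv")))

  cli <- system.file("cli", "hotspoteeg.R", package = "hotspotEEG")
  expect_true(nzchar(cli))
  out <- suppressWarnings(system2("Rscript",
    c(cli, "simulate", "--cohort", "stroke", "--n-subjects", "1",
      "--n-trials", "2", "--seed", "3", "--out", file.path(dir, "sim")),
    stdout = TRUE, stderr = TRUE))
  if (is.null(attr(out, "status")))
    expect_true(file.exists(file.path(dir, "sim", "hotspots.csv")))
})
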