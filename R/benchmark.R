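#' Hotspot-recovery benchmark on the healthy synthetic preset
#'
#' End-to-end parameter recovery at desk scale: simulates `n_subjects`
#' healthy subjects (right hand), builds the raw channel x time input
#' (`Input_1`) over the 9-channel motor-area set (`Set5`), trains the full
#' CNN per subject inside one outer cross-validation fold (80/20 split with
#' a 4:1 inner train/validation split and early stopping, epoch cap
#' `max_epochs`), and scores the held-out-trial predictions against the
#' planted ground truth. The chance-level reference is the leave-one-out
#' mean predictor over the cohort's true hotspot coordinates - the best any
#' EEG-blind method could do.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Base seed for simulation, folds and weights.
#' @param snr Simulator burst SNR.
#' @param channel_set Channel set id (default `"Set5"`, 9 channels).
#' @param max_epochs Epoch cap for training.
#' @param outer_folds Outer folds evaluated per subject (default 1).
#' @param config Optional `cnn_config` overriding the full architecture.
#' @return List with `errors_mm` (per subject), `mean_error_mm`,
#'   `baseline_error_mm`, `ratio`, and `truths`.
#' @export
recovery_benchmark <- function(n_subjects = 10, seed = 1, snr = 5,
                               channel_set = "Set5", max_epochs = 100,
                               outer_folds = 1, config = NULL) {
  montage <- load_montage("healthy63")
  scfg <- synth_config("healthy", n_subjects = n_subjects, snr = snr,
                       seed = seed)
  mcfg <- config %||% model_config(max_epochs = max_epochs)
  errors <- numeric(n_subjects)
  truths <- matrix(NA_real_, n_subjects, 3)
  for (i in seq_len(n_subjects)) {
    set.seed((seed %% 100000L) * 100L + i)
    s <- generate_subject(montage, scfg, sprintf("s%02d", i), hands = "right")
    cs <- select_channel_set(montage, channel_set, "right")
    rec <- s$recording_right
    # Input_1 involves no cross-channel stage, so restrict channels early
    rec$signal <- rec$signal[cs$labels, , drop = FALSE]
    rec$labels <- cs$labels
    inp <- build_input(rec, 1)
    cv <- nested_cv(inp, s$truth_right, mcfg, n_repeats = 1,
                    outer_folds = outer_folds, seed = seed + i,
                    subject_id = rec$subject_id, hand = "right",
                    channel_set = channel_set)
    errors[i] <- cv$mean_error_mm
    truths[i, ] <- as_coord(s$truth_right)
  }
  base_errors <- vapply(seq_len(n_subjects), function(i) {
    b <- baseline_mean_predictor(truths[-i, , drop = FALSE])
    euclidean_error(predict(b)[1, ], truths[i, ])
  }, numeric(1))
  list(errors_mm = errors, mean_error_mm = mean(errors),
       baseline_error_mm = mean(base_errors),
       ratio = mean(errors) / mean(base_errors), truths = truths)
}

#' Trial-count ablation trend on the healthy synthetic preset
#'
#' Repeats, over independent seeds, a small cohort evaluation at several
#' trial counts (subsampled without replacement, nested subsets per
#' subject) with a reduced CNN profile trained for a fixed number of
#' epochs, and reports the mean error distance per trial count. Mirrors
#' the study's observation that fewer trials degrade localization.
#'
#' @param n_seeds Number of independent replications.
#' @param n_subjects Subjects per replication.
#' @param trial_counts Trial counts to compare.
#' @param seed Base seed.
#' @param outer_folds Outer folds evaluated per dataset.
#' @param config Reduced `cnn_config` (default: 2 conv blocks of 8/16
#'   filters, dense 32-16-3, 40 epochs fixed).
#' @return List with `mean_errors_mm` (named by trial count) and the full
#'   per-seed, per-subject `errors` data.frame.
#' @export
trial_trend_benchmark <- function(n_seeds = 10, n_subjects = 3,
                                  trial_counts = c(30, 10, 5), seed = 1,
                                  outer_folds = 1:2, config = NULL) {
  montage <- load_montage("healthy63")
  cfg <- config %||% model_config(
    conv_blocks = list(c(1, 8), c(1, 16)), dense_sizes = c(32, 16, 3),
    max_epochs = 40, patience = 40)
  cs <- select_channel_set(montage, "Set5", "right")
  rows <- list()
  for (rep_ in seq_len(n_seeds)) {
    scfg <- synth_config("healthy", n_subjects = n_subjects,
                         seed = seed + rep_)
    for (i in seq_len(n_subjects)) {
      set.seed((seed %% 100000L) * 200L + rep_ * 50L + i)
      s <- generate_subject(montage, scfg, sprintf("s%02d", i),
                            hands = "right")
      rec <- s$recording_right
      rec$signal <- rec$signal[cs$labels, , drop = FALSE]
      rec$labels <- cs$labels
      inp <- build_input(rec, 1)
      n_tr <- dim(inp$tensor)[1]
      set.seed((seed %% 100000L) * 200L + rep_ * 50L + i)
      perm <- sample(n_tr)
      for (tc in trial_counts) {
        keep <- sort(perm[seq_len(tc)])
        cv <- nested_cv(inp$tensor[keep, , , drop = FALSE], s$truth_right,
                        cfg, n_repeats = 1, outer_folds = outer_folds,
                        seed = seed + rep_ * 100 + i,
                        subject_id = rec$subject_id, hand = "right")
        rows[[length(rows) + 1]] <- data.frame(
          replication = rep_, subject = i, n_trials = tc,
          error_mm = cv$mean_error_mm)
      }
    }
  }
  errors <- do.call(rbind, rows)
  means <- tapply(errors$error_mm, errors$n_trials, mean)
  means <- means[as.character(sort(as.numeric(names(means)), decreasing = TRUE))]
  list(mean_errors_mm = means, errors = errors)
}
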