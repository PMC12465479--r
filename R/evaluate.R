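#' Euclidean error distance between two hotspot locations
#'
#' @param pred,truth `hotspot_location`s or 3-vectors (mm, same head frame).
#' @return Distance in mm.
#' @examples
#' euclidean_error(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclidean_error <- function(pred, truth) {
  sqrt(sum((as_coord(pred) - as_coord(truth))^2))
}

#' Fold plan for trial-wise nested cross-validation
#'
#' For each of `n_repeats` repetitions, trials are randomly partitioned
#' into `k_outer` outer test folds (sizes differing by at most one). The
#' remaining trials of each fold are split into training and validation
#' sets at a 4:1 ratio (validation size `max(1, round(n_rest / 5))`, e.g.
#' 19 train / 5 validation from 24 trials) for
#' early stopping. Fold assignment is seeded per repetition, so plans are
#' exactly replayable.
#'
#' @param n_trials Number of trials.
#' @param k_outer Outer folds per repetition.
#' @param n_repeats Repetitions.
#' @param seed Base seed; repetition `r` uses `seed + r`.
#' @return List of repetitions; each has `folds`, a list of
#'   `list(test, train, val)` index vectors.
#' @export
cv_fold_plan <- function(n_trials, k_outer = 5, n_repeats = 5, seed = 1) {
  if (n_trials < k_outer)
    stop("need at least k_outer = ", k_outer, " trials (got ", n_trials, ")")
  lapply(seq_len(n_repeats), function(r) {
    set.seed(seed + r)
    perm <- sample(n_trials)
    fold_of <- integer(n_trials)
    fold_of[perm] <- rep(seq_len(k_outer), length.out = n_trials)
    folds <- lapply(seq_len(k_outer), function(k) {
      test <- which(fold_of == k)
      rest <- setdiff(seq_len(n_trials), test)
      if (length(rest) < 2)
        stop("need at least 2 non-test trials per outer fold ",
             "(train + validation); got ", length(rest))
      n_val <- max(1L, round(length(rest) / 5))
      val <- sample(rest, n_val)
      list(test = sort(test), train = sort(setdiff(rest, val)),
           val = sort(val))
    })
    list(repetition = r, seed = seed + r, folds = folds)
  })
}

#' Trial-wise nested cross-validation of the hotspot CNN
#'
#' The full protocol evaluates one subject-and-hand dataset with 5
#' repetitions of 5-fold outer cross-validation (25 outer evaluations):
#' each outer fold holds out 20% of trials for testing, the remaining 80%
#' are split 4:1 into training and validation for early stopping, a model
#' is trained from scratch per fold, the subject-level prediction is the
#' mean over outer-test trial predictions, and the fold error is its
#' Euclidean distance to the ground truth. `outer_folds` restricts each
#' repetition to a subset of folds for cheap runs.
#'
#' @param x trials x channels x width array or `model_input`.
#' @param truth Ground-truth `hotspot_location` or 3-vector (mm).
#' @param config A `cnn_config`.
#' @param k_outer,n_repeats CV protocol (5 x 5 by default).
#' @param seed Seed for fold assignment and per-fold model seeds.
#' @param outer_folds Optional integer vector of outer folds to evaluate
#'   per repetition (default: all).
#' @param subject_id,hand,level,channel_set Provenance strings stored in
#'   the result.
#' @return An object of class `hotspot_cv`: `folds` data.frame (repetition,
#'   fold, error_mm, predicted coordinates, test indices), `mean_error_mm`,
#'   `n_outer_evals`, provenance and the fold plan.
#' @export
nested_cv <- function(x, truth, config = model_config(), k_outer = 5,
                      n_repeats = 5, seed = 1, outer_folds = NULL,
                      subject_id = "s00", hand = "right", level = NA,
                      channel_set = NA) {
  if (inherits(x, "model_input")) {
    if (is.na(level)) level <- x$level
    x <- x$tensor
  }
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]
  tr <- as_coord(truth)
  plan <- cv_fold_plan(n, k_outer, n_repeats, seed)
  outer_folds <- outer_folds %||% seq_len(k_outer)

  rows <- list()
  for (rep_ in plan) {
    for (k in outer_folds) {
      f <- rep_$folds[[k]]
      stopifnot(length(intersect(f$test, c(f$train, f$val))) == 0,
                length(intersect(f$train, f$val)) == 0)
      cfg <- config
      cfg$seed <- (seed %% 100000L) * 1000L + rep_$repetition * 10L + k
      fit <- hotspot_cnn(x[f$train, , , drop = FALSE], tr,
                         val_x = x[f$val, , , drop = FALSE], val_y = tr,
                         config = cfg)
      p <- predict(fit, x[f$test, , , drop = FALSE], type = "subject")
      rows[[length(rows) + 1]] <- data.frame(
        repetition = rep_$repetition, fold = k,
        pred_x = p[1], pred_y = p[2], pred_z = p[3],
        error_mm = euclidean_error(p, tr),
        n_test = length(f$test),
        test_idx = I(list(f$test)),
        best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch)
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds, mean_error_mm = mean(folds$error_mm),
                 n_outer_evals = nrow(folds), truth = tr,
                 n_trials_used = n, subject_id = subject_id, hand = hand,
                 level = level, channel_set = channel_set, seed = seed,
                 plan = plan),
            class = "hotspot_cv")
}

#' @export
print.hotspot_cv <- function(x, ...) {
  cat(sprintf(
    "<hotspot_cv> %s/%s: mean error %.2f mm over %d outer evaluations (%d trials)\n",
    x$subject_id, x$hand, x$mean_error_mm, x$n_outer_evals, x$n_trials_used))
  invisible(x)
}

#' @export
summary.hotspot_cv <- function(object, ...) {
  print(object)
  cat(sprintf("  error range [%.2f, %.2f] mm, SD %.2f mm\n",
              min(object$folds$error_mm), max(object$folds$error_mm),
              stats::sd(object$folds$error_mm)))
  invisible(object$folds)
}

#' @export
plot.hotspot_cv <- function(x, ...) {
  graphics::boxplot(error_mm ~ repetition, data = x$folds,
                    xlab = "repetition", ylab = "error distance (mm)", ...)
  graphics::abline(h = x$mean_error_mm, lty = 3)
  invisible(x)
}

#' Mean-coordinate baseline predictor
#'
#' Predicts the mean training-truth coordinate for every input - the
#' chance-level reference a model that ignores the EEG entirely would
#' achieve. Train it on the ground-truth hotspots of a reference cohort
#' and evaluate its error against each held-out subject's truth.
#'
#' @param train_truths n x 3 matrix of truths (mm), or a list of
#'   `hotspot_location`s.
#' @return An object of class `baseline_predictor`; its `predict()` method
#'   returns the stored mean for any number of rows.
#' @export
baseline_mean_predictor <- function(train_truths) {
  if (is.list(train_truths) && !is.data.frame(train_truths))
    train_truths <- do.call(rbind, lapply(train_truths, as_coord))
  train_truths <- as.matrix(train_truths)
  if (ncol(train_truths) != 3 || nrow(train_truths) < 1)
    stop("need at least one 3D training truth")
  structure(list(center = colMeans(train_truths), n = nrow(train_truths)),
            class = "baseline_predictor")
}

#' @export
predict.baseline_predictor <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) 1L
  else if (is.numeric(newdata) && length(newdata) == 1) as.integer(newdata)
  else if (!is.null(dim(newdata))) dim(newdata)[1]
  else 1L
  out <- matrix(object$center, n, 3, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
print.baseline_predictor <- function(x, ...) {
  cat(sprintf("<baseline_predictor> center (%.1f, %.1f, %.1f) mm from %d truths\n",
              x$center[1], x$center[2], x$center[3], x$n))
  invisible(x)
}

#' Run a grid of evaluation conditions (input levels, channel sets, trials)
#'
#' Evaluates subject-and-hand datasets under combinations of preprocessing
#' level, channel set, and trial count. Trial-count ablation subsamples
#' without replacement using a seeded permutation per dataset, taking the
#' first `k` entries, so smaller trial sets are nested within larger ones.
#'
#' @param subjects List of `synthetic_subject`s (or of lists with
#'   `recording_*` / `truth_*` entries).
#' @param levels Input levels (integers 1-5).
#' @param channel_sets Character vector of set ids.
#' @param trial_counts Trial counts to evaluate.
#' @param config A `cnn_config`.
#' @param seed Base seed.
#' @param hands Hands to include as independent datasets.
#' @param montage The `electrode_montage` (defaults to the cohort's).
#' @param k_outer,n_repeats,outer_folds CV protocol forwarded to
#'   [nested_cv()].
#' @return List with `results` (all `hotspot_cv` objects) and `summaries`
#'   (a `condition_summary` data.frame: one row per condition with mean,
#'   SE and n over datasets).
#' @export
run_condition_grid <- function(subjects, levels = 1, channel_sets = "Set1",
                               trial_counts = NULL, config = model_config(),
                               seed = 1, hands = c("left", "right"),
                               montage = NULL, k_outer = 5, n_repeats = 5,
                               outer_folds = NULL) {
  cohort <- subjects[[1]]$config$cohort
  montage <- montage %||% load_montage(default_montage_name(cohort))
  results <- list()
  summaries <- list()
  datasets <- list()
  for (s in subjects) for (h in hands) {
    rec <- s[[paste0("recording_", h)]]
    if (is.null(rec)) next
    datasets[[length(datasets) + 1]] <-
      list(rec = rec, truth = s[[paste0("truth_", h)]], hand = h)
  }
  n_avail <- min(vapply(datasets, function(d) nrow(d$rec$events), numeric(1)))
  trial_counts <- trial_counts %||% n_avail
  if (any(trial_counts > n_avail))
    stop("requested trial count exceeds available trials (", n_avail, ")")

  for (lv in levels) for (cs in channel_sets) for (tc in trial_counts) {
    cond <- sprintf("Input_%d|%s|%d trials", lv, cs, tc)
    errs <- numeric(0)
    for (di in seq_along(datasets)) {
      d <- datasets[[di]]
      chset <- select_channel_set(montage, cs, d$hand)
      inp <- build_input(d$rec, lv, chset, cohort)
      n_tr <- dim(inp$tensor)[1]
      set.seed(seed * 100 + di)
      perm <- sample(n_tr)
      keep <- sort(perm[seq_len(tc)])
      xt <- inp$tensor[keep, , , drop = FALSE]
      cv <- nested_cv(xt, d$truth, config, k_outer = k_outer,
                      n_repeats = n_repeats, seed = seed + di,
                      outer_folds = outer_folds,
                      subject_id = d$rec$subject_id, hand = d$hand,
                      level = paste0("Input_", lv), channel_set = cs)
      cv$trial_subset <- keep
      results[[length(results) + 1]] <- cv
      errs <- c(errs, cv$mean_error_mm)
    }
    summaries[[length(summaries) + 1]] <- data.frame(
      condition = cond, level = paste0("Input_", lv), channel_set = cs,
      n_trials = tc, mean_error_mm = mean(errs),
      se_error_mm = stats::sd(errs) / sqrt(length(errs)), n = length(errs))
  }
  summaries <- do.call(rbind, summaries)
  class(summaries) <- c("condition_summary", class(summaries))
  list(results = results, summaries = summaries)
}
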