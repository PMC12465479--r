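#' Run a full simulate -> preprocess -> evaluate experiment from a config
#'
#' Drives the whole pipeline from a YAML (or list) configuration: generates
#' a seeded synthetic cohort, evaluates the requested condition grid with
#' nested cross-validation, and writes all artifacts to an output
#' directory: `config_resolved.json` (the validated configuration
#' snapshot), the cohort's EDF recordings and `hotspots.csv`,
#' `summary.csv` (one row per condition with mean +/- SE error), and
#' `stats.json` (condition comparison when 2+ conditions ran). Runs are
#' pure functions of the resolved configuration: the same config and seed
#' reproduce `summary.csv` byte for byte.
#'
#' Configuration fields (dot paths): `cohort` ("healthy"/"stroke"),
#' `seed`, `output_dir`, `synthetic` (n_subjects, n_trials, snr, ...;
#' see [synth_config()]), `evaluation` (levels, channel_sets,
#' trial_counts, hands, k_outer, n_repeats, outer_folds), `model`
#' (conv_blocks, dense_sizes, lr, batch_size, max_epochs, patience).
#'
#' @param config Path to a YAML file or a list.
#' @param seed Optional override of `config$seed`.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with `summaries`, `results`, `stats` and
#'   `output_dir`.
#' @export
run_experiment <- function(config, seed = NULL, force = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_run_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  dir <- cfg$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sc_args <- cfg$synthetic
  sc_args$cohort <- cfg$cohort
  sc_args$seed <- cfg$seed
  sc <- do.call(synth_config, sc_args)

  jsonlite::write_json(cfg, file.path(dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  hands <- cfg$evaluation$hands
  cohort_dir <- file.path(dir, "cohort")
  subjects <- generate_cohort(sc, dir = cohort_dir, overwrite = force,
                              hands = hands)

  mcfg_args <- cfg$model
  if (!is.null(mcfg_args$conv_blocks))
    mcfg_args$conv_blocks <- lapply(mcfg_args$conv_blocks, unlist)
  mcfg <- do.call(model_config, mcfg_args)

  grid <- run_condition_grid(
    subjects,
    levels = cfg$evaluation$levels,
    channel_sets = cfg$evaluation$channel_sets,
    trial_counts = cfg$evaluation$trial_counts,
    config = mcfg, seed = cfg$seed, hands = hands,
    k_outer = cfg$evaluation$k_outer,
    n_repeats = cfg$evaluation$n_repeats,
    outer_folds = cfg$evaluation$outer_folds)

  out_sum <- grid$summaries
  out_sum$mean_error_mm <- round(out_sum$mean_error_mm, 6)
  out_sum$se_error_mm <- round(out_sum$se_error_mm, 6)
  utils::write.csv(out_sum, file.path(dir, "summary.csv"), row.names = FALSE,
                   quote = FALSE)

  stats_rep <- NULL
  if (nrow(grid$summaries) >= 2) {
    em <- vapply(split(grid$results,
                       rep(seq_len(nrow(grid$summaries)),
                           each = length(grid$results) / nrow(grid$summaries))),
                 function(g) vapply(g, `[[`, numeric(1), "mean_error_mm"),
                 numeric(length(grid$results) / nrow(grid$summaries)))
    colnames(em) <- grid$summaries$condition
    stats_rep <- compare_conditions(em, "paired")
    jsonlite::write_json(
      list(omnibus = stats_rep$omnibus, pairwise = stats_rep$pairwise),
      file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(list(summaries = grid$summaries, results = grid$results,
                 stats = stats_rep, output_dir = dir))
}

# Schema-style validation with field paths; defaults are filled in.
validate_run_config <- function(cfg) {
  fail <- function(path, msg) stop("config field '", path, "': ", msg,
                                   call. = FALSE)
  if (!is.list(cfg)) fail("(root)", "must be a mapping")
  cfg$cohort <- cfg$cohort %||% "healthy"
  if (!cfg$cohort %in% c("healthy", "stroke"))
    fail("cohort", "must be 'healthy' or 'stroke'")
  cfg$seed <- cfg$seed %||% 1L
  if (!is.numeric(cfg$seed)) fail("seed", "must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) fail("output_dir", "is required")

  cfg$synthetic <- cfg$synthetic %||% list()
  syn_fields <- c("n_subjects", "n_trials", "fs", "snr", "spatial_sigma",
                  "hotspot_offset_mean", "hotspot_jitter_sd",
                  "artifact_rate")
  bad <- setdiff(names(cfg$synthetic), syn_fields)
  if (length(bad)) fail(paste0("synthetic.", bad[1]), "unknown field")
  for (f in intersect(names(cfg$synthetic), syn_fields))
    if (!is.numeric(cfg$synthetic[[f]]))
      fail(paste0("synthetic.", f), "must be numeric")

  ev <- cfg$evaluation %||% list()
  ev$levels <- ev$levels %||% 1
  if (!all(ev$levels %in% 1:5)) fail("evaluation.levels", "must be in 1..5")
  if (cfg$cohort == "stroke" && !all(ev$levels == 1))
    fail("evaluation.levels",
         "stroke analyses use raw data (level 1) only")
  ev$channel_sets <- ev$channel_sets %||% "Set1"
  valid_sets <- names(channel_set_table(default_montage_name(cfg$cohort)))
  if (!all(ev$channel_sets %in% valid_sets))
    fail("evaluation.channel_sets",
         paste("must be among", paste(valid_sets, collapse = ", ")))
  n_trials <- cfg$synthetic$n_trials %||% 30
  ev$trial_counts <- ev$trial_counts %||% n_trials
  if (any(ev$trial_counts > n_trials))
    fail("evaluation.trial_counts",
         paste0("cannot exceed synthetic.n_trials (", n_trials, ")"))
  ev$hands <- ev$hands %||% c("left", "right")
  if (!all(ev$hands %in% c("left", "right")))
    fail("evaluation.hands", "must be 'left' and/or 'right'")
  ev$k_outer <- ev$k_outer %||% 5
  ev$n_repeats <- ev$n_repeats %||% 5
  cfg$evaluation <- ev

  cfg$model <- cfg$model %||% list()
  known <- c("conv_blocks", "kernel", "dense_sizes", "lr", "batch_size",
             "max_epochs", "patience", "seed")
  bad <- setdiff(names(cfg$model), known)
  if (length(bad)) fail(paste0("model.", bad[1]), "unknown field")
  cfg
}
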