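# File-based pipeline commands wiring the modules into reproducible runs.
# Each command writes its outputs plus a manifest (config echo, seed, input
# hashes) so a run can be audited and reproduced byte-identically.

write_manifest <- function(out_dir, command, config, inputs = character(0),
                           outputs = character(0), seed = NULL) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("neuroqwerty")),
    seed = seed,
    config = config,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Pipeline commands
#'
#' Thin, file-based wrappers over the package's functions, suitable for
#' scripted runs (and the `nqi` command-line script shipped under
#' `inst/scripts/`). Every command is deterministic given its inputs and
#' seed and writes a JSON manifest next to its outputs.
#'
#' * `run_simulate()` writes `events.csv` and `meta.csv` for a synthetic
#'   cohort.
#' * `run_featurize()` reads an event log and writes the per-window feature
#'   table.
#' * `run_train()` trains the ensemble on a feature table plus metadata and
#'   writes the serialized model.
#' * `run_score()` scores a feature table with a saved model and writes
#'   `subject_id,n_windows,nqi`.
#' * `run_evaluate()` runs the two-cohort cross-dataset validation
#'   (subject- and window-level), the DeLong-backed ROC summaries, the
#'   cost-weighted cutoff table and the covariate-adjusted logistic model,
#'   and writes a JSON report plus the combined ROC curve points.
#'
#' @param cfg A [sim_config()] (`run_simulate`), [window_config()]
#'   (`run_featurize`) or [nqi_config()] (`run_train`, `run_evaluate`).
#' @param out_dir Output directory, created if needed.
#' @param events_path,meta_path,features_path,model_path Input file paths.
#' @param events_a,meta_a,events_b,meta_b Event/metadata CSV paths of the
#'   two cohorts to cross-validate.
#' @param window_cfg A [window_config()] used to featurize both cohorts.
#' @param cost_pairs Misclassification-cost pairs for the cutoff table.
#' @return The main output path(s), invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(cfg = sim_config(), out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(cfg)
  events_path <- file.path(out_dir, "events.csv")
  meta_path <- file.path(out_dir, "meta.csv")
  write_key_events(sim$events, events_path)
  write_subject_meta(sim$meta, meta_path)
  write_manifest(out_dir, "simulate", unclass(cfg),
                 outputs = c(events_path, meta_path), seed = cfg$seed)
  invisible(c(events = events_path, meta = meta_path))
}

#' @rdname pipeline
#' @export
run_featurize <- function(events_path, out_dir = ".",
                          cfg = window_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  events <- read_key_events(events_path)
  features <- featurize(events, cfg)
  out <- file.path(out_dir, "features.csv")
  write_feature_table(features, out)
  write_manifest(out_dir, "featurize", unclass(cfg), inputs = events_path,
                 outputs = out)
  invisible(out)
}

#' @rdname pipeline
#' @export
run_train <- function(features_path, meta_path, out_dir = ".",
                      cfg = nqi_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  features <- read_feature_table(features_path)
  meta <- read_subject_meta(meta_path)
  model <- train_nqi(features, meta, cfg)
  out <- file.path(out_dir, "model.json")
  write_nqi_model(model, out)
  write_manifest(out_dir, "train", unclass(cfg),
                 inputs = c(features_path, meta_path), outputs = out,
                 seed = cfg$seed)
  invisible(out)
}

#' @rdname pipeline
#' @export
run_score <- function(model_path, features_path, out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- read_nqi_model(model_path)
  features <- read_feature_table(features_path)
  scores <- score_subjects(model, features)
  out <- file.path(out_dir, "scores.csv")
  readr::write_csv(scores, out)
  write_manifest(out_dir, "score", list(model = model_path),
                 inputs = c(model_path, features_path), outputs = out,
                 seed = model$cfg$seed)
  invisible(out)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(events_a, meta_a, events_b, meta_b, out_dir = ".",
                         cfg = nqi_config(), window_cfg = window_config(),
                         cost_pairs = list(c(1, 1), c(2, 1), c(1, 2))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- featurize(read_key_events(events_a), window_cfg)
  fb <- featurize(read_key_events(events_b), window_cfg)
  ma <- read_subject_meta(meta_a)
  mb <- read_subject_meta(meta_b)
  cv <- cross_dataset_validate(fa, ma, fb, mb, cfg)
  pw <- per_window_auc(fa, ma, fb, mb, cfg)
  cuts <- cutoff_table(cv$scores$nqi, cv$scores$group,
                       cost_pairs = cost_pairs)
  meta_all <- dplyr::bind_rows(ma, mb)
  adj <- NULL
  covs <- c("age", "sex", "education_years", "typing_speed")
  if (all(covs %in% names(meta_all))) {
    dat <- dplyr::inner_join(cv$scores, meta_all[, c("subject_id", covs)],
                             by = "subject_id")
    adj <- adjusted_logistic(dat)
  }
  report <- list(
    auc = list(
      fold_a = glance(cv$roc_a),
      fold_b = glance(cv$roc_b),
      combined = glance(cv$roc_combined),
      per_window = glance(pw$roc)
    ),
    cutoffs = cuts,
    adjusted_logistic = if (!is.null(adj)) {
      list(coefficients = adj$coefficients, separation = adj$separation)
    },
    n_subjects = nrow(cv$scores),
    n_windows = nrow(pw$window_scores)
  )
  report_path <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  scores_path <- file.path(out_dir, "cv_scores.csv")
  readr::write_csv(cv$scores, scores_path)
  curve_path <- file.path(out_dir, "roc_combined.csv")
  readr::write_csv(cv$roc_combined$curve, curve_path)
  write_manifest(out_dir, "evaluate", unclass(cfg),
                 inputs = c(events_a, meta_a, events_b, meta_b),
                 outputs = c(report_path, scores_path, curve_path),
                 seed = cfg$seed)
  invisible(report_path)
}
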