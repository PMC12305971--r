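#' Pipeline configuration
#'
#' One validated configuration object drives the whole run: simulate (or
#' load) a cohort, extract stride-pair features, split and weight, select
#' features per subscore, grid-search the model families, evaluate at
#' patient level, and explain the fitted models. One master seed is
#' fanned out deterministically to the stages (simulation uses the seed
#' itself; the split uses seed + 1; per-target cross-validation uses
#' seed + 10 * target index; explanation shuffles use seed + 97).
#'
#' @param sim a [sim_config()] for the synthetic cohort.
#' @param test_fraction patient-level test share (default 0.30).
#' @param alpha Alexander-Govern retention threshold (default 0.05).
#' @param families model families to train, subset of `c("dt", "mlp")`.
#' @param targets subscores to model (default all six).
#' @param cv_folds cross-validation folds (default 10).
#' @param mlp_epochs,mlp_batch_size MLP training budget per fit.
#' @param perm_reps permutation-importance repetitions (default 500).
#' @param explain compute importance reports (default TRUE).
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            test_fraction = 0.30,
                            alpha = 0.05,
                            families = c("dt", "mlp"),
                            targets = sms_subscores(),
                            cv_folds = 10L,
                            mlp_epochs = 60L,
                            mlp_batch_size = 32L,
                            perm_reps = 500L,
                            explain = TRUE,
                            seed = 1L) {
  families <- match.arg(families, c("dt", "mlp"), several.ok = TRUE)
  bad <- setdiff(targets, sms_subscores())
  if (length(bad))
    stop("unknown target(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  structure(
    list(sim = sim, test_fraction = test_fraction, alpha = alpha,
         families = families, targets = targets,
         cv_folds = as.integer(cv_folds),
         mlp_control = list(epochs = as.integer(mlp_epochs),
                            batch_size = as.integer(mlp_batch_size)),
         perm_reps = as.integer(perm_reps), explain = explain,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full reconstruction pipeline
#'
#' Executes every stage in order — simulate, extract, split + weight,
#' select, train, evaluate, explain — and returns all artifacts plus a
#' manifest recording the seeds and active design-decision values. The
#' same configuration always reproduces the identical run.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `sms_cohort` (skips simulation).
#' @param out_dir optional directory; when given, the feature table,
#'   selected-feature lists, Alexander-Govern reports, tree exports,
#'   evaluation report, scatter data, and manifest are written there.
#' @return object of class `sms_run`: list with `cohort`, `dataset`,
#'   `selection` (per target), `models` (per family and target),
#'   `evaluation`, `importance` (per model), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$sim)

  features <- extract_features(cohort)
  dataset <- assemble_dataset(features, config$test_fraction,
                              seed = config$seed + 1L)
  train <- dataset[dataset$split == "train", ]

  selection <- list()
  models <- list()
  importance <- list()
  for (ti in seq_along(config$targets)) {
    target <- config$targets[ti]
    sel <- select_features(dataset, target, alpha = config$alpha)
    if (!length(sel$selected)) {
      warning("no feature retained for ", target,
              "; falling back to the step-1 mask", call. = FALSE)
      sel$selected <- sel$mask
    }
    selection[[target]] <- sel
    for (family in config$families) {
      model <- grid_search(train, target, family,
                           selected = sel$selected,
                           rep_ids = sel$representatives,
                           k = config$cv_folds,
                           seed = config$seed + 10L * ti,
                           mlp_control = config$mlp_control)
      key <- paste(family, target, sep = "_")
      models[[key]] <- model
      if (config$explain) {
        test <- dataset[dataset$split == "test", ]
        pi <- permutation_importance(model, test, reps = config$perm_reps,
                                     seed = config$seed + 97L)
        importance[[key]] <- list(
          permutation = pi,
          split_gain = if (family == "dt") dt_importance(model$fit))
      }
    }
  }

  evaluation <- evaluate_models(models, dataset, raters = cohort$raters)

  manifest <- list(
    package_version = as.character(utils::packageVersion("strideboard")),
    seed = config$seed,
    stage_seeds = list(simulation = config$sim$seed,
                       split = config$seed + 1L,
                       cv = config$seed + 10L * seq_along(config$targets),
                       explanation = config$seed + 97L),
    n_patients = nrow(cohort$patients),
    n_pairs = nrow(dataset),
    n_train_pairs = sum(dataset$split == "train"),
    n_test_pairs = sum(dataset$split == "test"),
    targets = config$targets,
    families = config$families,
    alpha = config$alpha,
    test_fraction = config$test_fraction,
    cv_folds = config$cv_folds,
    mlp_control = config$mlp_control,
    design_decisions = list(
      nav_scheme = "central differences, one-sided endpoints",
      window_boundary = "foot-off sample in both stance and swing",
      limp_index = "own stance time / opposite stance time",
      pairing = "contralateral stride starting within the ipsilateral one",
      representative_pair = "min Euclidean distance to patient median, z-space",
      stratum_rounding = "largest remainder; singleton strata to training",
      max_features_set = "sqrt(n), n, log2(n)",
      cv_stratification = "by label at stride-pair level",
      mlp_standardization = "z-score by training statistics",
      permutation_level = "test set, stride-pair level, global shuffling"
    )
  )

  run <- structure(
    list(cohort = cohort, dataset = dataset, selection = selection,
         models = models, evaluation = evaluation,
         importance = importance, manifest = manifest, config = config),
    class = "sms_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write a pipeline run's artifacts
#'
#' @param run an `sms_run`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$dataset, file.path(out_dir, "features.csv"),
                   progress = FALSE)
  for (target in names(run$selection)) {
    sel <- run$selection[[target]]
    writeLines(sel$selected,
               file.path(out_dir, paste0("selected_", target, ".txt")))
    if (nrow(sel$report))
      readr::write_csv(sel$report,
                       file.path(out_dir, paste0("ag_report_", target, ".csv")),
                       progress = FALSE)
  }
  for (key in names(run$models)) {
    model <- run$models[[key]]
    if (inherits(model$fit, "sms_dt"))
      export_tree(model$fit,
                  json_path = file.path(out_dir, paste0("tree_", key, ".json")),
                  dot_path = file.path(out_dir, paste0("tree_", key, ".dot")))
  }
  jsonlite::write_json(
    list(metrics = run$evaluation$metrics),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  readr::write_csv(run$evaluation$scatter,
                   file.path(out_dir, "scatter.csv"), progress = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sms_run <- function(x, ...) {
  cat("<sms_run> ", x$manifest$n_patients, " patients, ",
      x$manifest$n_pairs, " pairs (", x$manifest$n_train_pairs, " train / ",
      x$manifest$n_test_pairs, " test), families: ",
      paste(x$manifest$families, collapse = ", "), "\n", sep = "")
  print(x$evaluation$metrics)
  invisible(x)
}
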