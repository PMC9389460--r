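#' End-to-end run configuration
#'
#' Bundles everything a reproducible run needs: the synthesis config (or
#' a cohort directory), the SVM stage config, the feature-count grids and
#' repetition count of the selection search, the decision threshold and
#' the global seed. The config is serialised into every output directory
#' as an audit copy.
#'
#' @param synthesis A [synthesis_config()] for simulated cohorts.
#' @param svm An [svm_stage_config()] (its seed is overridden by the
#'   global seed).
#' @param k_via_grid,k_vili_grid Candidate feature counts per modality;
#'   the defaults include the (5, 5) operating point.
#' @param repetitions Repeated cross-validation runs in the grid search.
#' @param grid_search If `FALSE`, skip the search and train at the first
#'   grid entry of each modality.
#' @param threshold Decision threshold on the H posterior.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(synthesis = synthesis_config(),
                       svm = svm_stage_config(),
                       k_via_grid = c(3, 5, 8),
                       k_vili_grid = c(3, 5, 8),
                       repetitions = 5,
                       grid_search = TRUE,
                       threshold = 0.5,
                       seed = 1L) {
  structure(list(synthesis = synthesis, svm = svm,
                 k_via_grid = k_via_grid, k_vili_grid = k_vili_grid,
                 repetitions = repetitions, grid_search = grid_search,
                 threshold = threshold, seed = as.integer(seed)),
            class = "run_config")
}

write_config_audit <- function(config, dir) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Train the diagnosis model on a cohort's training split
#'
#' Runs the training stages in order: t-test feature ranking per
#' modality, (optionally) the grid search over feature-count
#' combinations, selection of the winning top-k lists, and the two-stage
#' model fit. When `out_dir` is given, the ranking reports, score grid,
#' model artifact and a config audit copy are written there.
#'
#' @param train_features Training-split feature table from
#'   [extract_cohort_features()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List with `model`, `rank_via`, `rank_vili`, `selection`
#'   (grid-search result or fixed counts) and `selected_features`.
#' @export
run_train <- function(train_features, config = run_config(),
                      out_dir = NULL) {
  svm_cfg <- config$svm
  svm_cfg$seed <- config$seed
  rank_via <- rank_features_ttest(train_features, modality = "VIA")
  rank_vili <- rank_features_ttest(train_features, modality = "VILI")
  if (isTRUE(config$grid_search) &&
        (length(config$k_via_grid) > 1 || length(config$k_vili_grid) > 1)) {
    selection <- grid_search_combination(
      train_features, config$k_via_grid, config$k_vili_grid,
      repetitions = config$repetitions, seed = config$seed,
      svm_config = svm_cfg)
  } else {
    selection <- list(best_k_via = config$k_via_grid[1],
                      best_k_vili = config$k_vili_grid[1],
                      score_grid = NULL)
  }
  selected <- c(select_top_k(rank_via, selection$best_k_via),
                select_top_k(rank_vili, selection$best_k_vili))
  model <- train_pipeline(train_features, selected_features = selected,
                          svm_config = svm_cfg,
                          threshold = config$threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config_audit(config, out_dir)
    write_ranking_report(rank_via, selected,
                         file.path(out_dir, "ranking_VIA.csv"))
    write_ranking_report(rank_vili, selected,
                         file.path(out_dir, "ranking_VILI.csv"))
    if (!is.null(selection$score_grid)) {
      utils::write.csv(as.data.frame(selection$score_grid),
                       file.path(out_dir, "score_grid.csv"))
    }
    save_model(model, file.path(out_dir, "model"))
  }
  list(model = model, rank_via = rank_via, rank_vili = rank_vili,
       selection = selection, selected_features = selected)
}

#' Evaluate a trained model on a held-out test split
#'
#' Refuses to score patients that were part of the model's training split
#' (id overlap is an error), predicts the test cases, and reports the
#' model-only, physician-only and OR-combined metrics. When `out_dir` is
#' given, the predictions and the evaluation report are written there.
#'
#' @param model A `colpo_model`.
#' @param test_features Test-split feature table.
#' @param config A [run_config()] (bootstrap seed).
#' @param out_dir Optional output directory.
#' @return List with `predictions` and `evaluation`.
#' @export
run_evaluate <- function(model, test_features, config = run_config(),
                         out_dir = NULL) {
  overlap <- intersect(model$train_ids, test_features$patient_id)
  if (length(overlap)) {
    stop("run_evaluate: test set overlaps the training split: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  predictions <- predict_pipeline(model, test_features)
  evaluation <- evaluate_predictions(
    predictions, test_features$label,
    physician_calls = test_features$physician_call,
    seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config_audit(config, out_dir)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    write_evaluation_report(evaluation, file.path(out_dir, "evaluation"))
  }
  list(predictions = predictions, evaluation = evaluation)
}

#' Simulate, train and evaluate in one call
#'
#' Generates a synthetic cohort, applies the exclusion filters and the
#' temporal train/test split, extracts the feature table, trains the
#' two-stage model and evaluates it on the held-out month-4 patients.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (artifacts and reports).
#' @return List with `cohort`, `features`, `split`, `training` (see
#'   [run_train()]) and `evaluation` (see [run_evaluate()]).
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  cohort <- generate_cohort(config$synthesis, seed = config$seed)
  filtered <- apply_exclusion_filters(cohort$clinical)
  cohort$clinical <- filtered$retained
  features <- extract_cohort_features(cohort)
  split <- temporal_split(features)
  training <- run_train(split$train, config, out_dir = out_dir)
  evaluation <- run_evaluate(training$model, split$test, config,
                             out_dir = out_dir)
  list(cohort = cohort, features = features, split = split,
       training = training, evaluation = evaluation)
}
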