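#' Rank image features by Welch t-tests between the H and LN groups
#'
#' For each feature of one modality, computes a Welch (unequal-variance)
#' two-sample t-test between the high-grade and low-grade/normal training
#' patients, adjusts the p-values by Benjamini-Hochberg, and sorts
#' ascending by adjusted p-value (ties broken by raw p-value, then
#' feature name). A feature that is constant in both groups cannot
#' discriminate and is assigned `p = 1` by convention, ranking last.
#'
#' @param features Per-patient feature table (as from
#'   [extract_cohort_features()]) of the training split.
#' @param labels Factor/character H/LN labels aligned with the rows
#'   (defaults to `features$label`).
#' @param modality `"VIA"` or `"VILI"`: which prefixed columns to rank.
#' @return Data frame of class `ranked_features` with columns `feature`,
#'   `modality`, `mean_H`, `mean_LN`, `sd_H`, `sd_LN`, `p_raw`, `p_adj`,
#'   `rank`, plus attributes `n_H`/`n_LN`.
#' @export
rank_features_ttest <- function(features, labels = features$label,
                                modality = c("VIA", "VILI")) {
  modality <- match.arg(modality)
  labels <- factor(as.character(labels), levels = c("LN", "H"))
  for (cl in c("LN", "H")) {
    if (sum(labels == cl) < 2) {
      stop("rank_features_ttest: class ", cl, " has fewer than 2 patients")
    }
  }
  cols <- feature_columns(features, modality)
  is_h <- labels == "H"
  stats_one <- function(col) {
    x <- features[[col]][is_h]; y <- features[[col]][!is_h]
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      1  # constant feature: no evidence by convention
    } else {
      tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
               error = function(e) 1)
    }
    c(mean_H = mean(x), mean_LN = mean(y),
      sd_H = stats::sd(x), sd_LN = stats::sd(y), p_raw = p)
  }
  m <- t(vapply(cols, stats_one, numeric(5)))
  out <- data.frame(feature = cols, modality = modality, m,
                    row.names = NULL)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out <- out[order(out$p_adj, out$p_raw, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_H") <- sum(is_h)
  attr(out, "n_LN") <- sum(!is_h)
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Select the top-k ranked features
#'
#' @param ranked A `ranked_features` table from [rank_features_ttest()].
#' @param k Number of features, `1 <= k <= nrow(ranked)`.
#' @return Character vector of the first `k` feature names in rank order.
#' @export
select_top_k <- function(ranked, k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > nrow(ranked)) {
    stop("select_top_k: k must be in 1..", nrow(ranked))
  }
  ranked$feature[seq_len(k)]
}

#' Write a feature-ranking report
#'
#' CSV with one row per feature: group means and SDs, raw and adjusted
#' p-values, rank, and whether the feature was selected.
#'
#' @param ranked A `ranked_features` table.
#' @param selected Character vector of selected feature names.
#' @param path Output CSV path.
#' @export
write_ranking_report <- function(ranked, selected, path) {
  ranked$selected <- ranked$feature %in% selected
  utils::write.csv(as.data.frame(ranked), path, row.names = FALSE)
  invisible(path)
}

# Stratified fold assignment: within each class, cycle fold ids over a
# random permutation of the cases.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(factor(labels))) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                  length(idx))
  }
  fold
}

#' Grid search over the (k_VIA, k_VILI) feature-count combination
#'
#' Scores every pair of candidate counts by running the full downstream
#' pipeline — t-test ranking, SMOTE rebalancing, RBF-SVM, naive Bayes
#' fusion — under stratified cross-validation on the training split,
#' repeated with independent child seeds, and averaging the macro F1
#' score of the held-out folds. Ranking and model fitting are redone
#' inside each fold, so no validation information leaks into the
#' selection. The pair with the highest mean score wins; ties go to the
#' pair with fewer total features.
#'
#' @param train Training feature table (from [extract_cohort_features()]).
#' @param k_via_grid,k_vili_grid Candidate feature counts per modality.
#' @param repetitions Number of repeated cross-validation runs (>= 5).
#' @param seed Integer seed driving fold assignment and the stochastic
#'   pipeline stages.
#' @param n_folds Folds of the stratified cross-validation (default 5).
#' @param svm_config An [svm_stage_config()].
#' @return List with `best_k_via`, `best_k_vili` and the mean-score
#'   matrix `score_grid` (rows = k_VIA, columns = k_VILI).
#' @export
grid_search_combination <- function(train, k_via_grid, k_vili_grid,
                                    repetitions = 5, seed = 1,
                                    n_folds = 5,
                                    svm_config = svm_stage_config()) {
  if (length(k_via_grid) == 0 || length(k_vili_grid) == 0) {
    stop("grid_search_combination: empty grid")
  }
  if (repetitions < 5) {
    stop("grid_search_combination: repetitions must be at least 5")
  }
  labels <- factor(as.character(train$label), levels = c("LN", "H"))
  acc <- array(0, dim = c(length(k_via_grid), length(k_vili_grid)))
  cnt <- 0
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    fold <- stratified_folds(labels, n_folds)
    fold_seeds <- sample.int(.Machine$integer.max - 1L, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- train[fold != f, , drop = FALSE]
      va <- train[fold == f, , drop = FALSE]
      if (length(unique(tr$label)) < 2 || length(unique(va$label)) < 2) next
      rank_via <- rank_features_ttest(tr, modality = "VIA")
      rank_vili <- rank_features_ttest(tr, modality = "VILI")
      cfg <- svm_config; cfg$seed <- fold_seeds[f]
      for (a in seq_along(k_via_grid)) for (b in seq_along(k_vili_grid)) {
        sel <- c(select_top_k(rank_via, k_via_grid[a]),
                 select_top_k(rank_vili, k_vili_grid[b]))
        model <- train_pipeline(tr, selected_features = sel,
                                svm_config = cfg)
        pred <- predict_pipeline(model, va)
        acc[a, b] <- acc[a, b] + macro_f1_binary(pred$call, va$label)
      }
      cnt <- cnt + 1
    }
  }
  score_grid <- acc / cnt
  dimnames(score_grid) <- list(k_via = k_via_grid, k_vili = k_vili_grid)
  # argmax; ties broken toward fewer total features
  total <- outer(k_via_grid, k_vili_grid, "+")
  best <- which(score_grid == max(score_grid), arr.ind = TRUE)
  best <- best[order(total[best]), , drop = FALSE][1, ]
  list(best_k_via = k_via_grid[best[1]], best_k_vili = k_vili_grid[best[2]],
       score_grid = score_grid)
}
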