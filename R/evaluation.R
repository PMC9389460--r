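#' Confusion matrix and rate metrics for binary H/LN calls
#'
#' Counts true/false positives and negatives with H as the positive
#' class, and derives sensitivity `tp / (tp + fn)`, specificity
#' `tn / (tn + fp)` and accuracy `(tp + tn) / total`. A rate whose
#' denominator is zero (e.g. sensitivity with no true H case) is reported
#' as `NA` with a warning.
#'
#' @param calls Predicted H/LN labels.
#' @param truths Ground-truth H/LN labels, aligned with `calls`.
#' @return A `colpo_metrics` list: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `f1_macro`.
#' @export
confusion_and_rates <- function(calls, truths) {
  calls <- as.character(calls); truths <- as.character(truths)
  if (length(calls) != length(truths)) {
    stop("confusion_and_rates: length mismatch")
  }
  bad <- setdiff(unique(c(calls, truths)), c("H", "LN"))
  if (length(bad)) {
    stop("confusion_and_rates: labels must be H or LN, got: ",
         paste(bad, collapse = ", "))
  }
  tp <- sum(calls == "H" & truths == "H")
  fp <- sum(calls == "H" & truths == "LN")
  tn <- sum(calls == "LN" & truths == "LN")
  fn <- sum(calls == "LN" & truths == "H")
  rate <- function(num, den, what) {
    if (den == 0) {
      warning("confusion_and_rates: ", what, " undefined (empty denominator)")
      return(NA_real_)
    }
    num / den
  }
  sen <- rate(tp, tp + fn, "sensitivity")
  spe <- rate(tn, tn + fp, "specificity")
  acc <- rate(tp + tn, tp + fp + tn + fn, "accuracy")
  f1 <- if (is.na(sen) || is.na(spe)) NA_real_ else {
    macro_f1(c(sen, spe), c(spe, sen))
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sen, specificity = spe, accuracy = acc,
                 f1_macro = f1),
            class = "colpo_metrics")
}

#' @export
print.colpo_metrics <- function(x, ...) {
  cat(sprintf("          truth H  truth LN\n  call H  %7d  %8d\n  call LN %7d  %8d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f  macro-F1 %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$f1_macro))
  invisible(x)
}

#' Macro-averaged F1 from per-class sensitivity and specificity
#'
#' Computes `mean_i( 2 * Sen_i * Spec_i / (Sen_i + Spec_i) )`: the
#' arithmetic mean over classes of the harmonic mean of each class's
#' sensitivity and specificity. Note this deliberately pairs sensitivity
#' with specificity (not precision with recall as the conventional F1
#' does); it is the score used to tune and report the diagnosis model. A
#' per-class `0/0` term is defined as 0.
#'
#' @param per_class_sen,per_class_spec Equal-length vectors of per-class
#'   sensitivity and specificity in `[0, 1]`.
#' @return Value in `[0, 1]`.
#' @export
macro_f1 <- function(per_class_sen, per_class_spec) {
  if (length(per_class_sen) != length(per_class_spec)) {
    stop("macro_f1: length mismatch")
  }
  term <- ifelse(per_class_sen + per_class_spec == 0, 0,
                 2 * per_class_sen * per_class_spec /
                   (per_class_sen + per_class_spec))
  mean(term)
}

# Binary convenience wrapper: per-class (H, LN) sensitivity/specificity
# from hard calls, then the macro F1. For two classes the sensitivity of
# one class is the specificity of the other.
macro_f1_binary <- function(calls, truths) {
  calls <- as.character(calls); truths <- as.character(truths)
  sen_h <- if (sum(truths == "H") == 0) 0 else {
    sum(calls == "H" & truths == "H") / sum(truths == "H")
  }
  sen_ln <- if (sum(truths == "LN") == 0) 0 else {
    sum(calls == "LN" & truths == "LN") / sum(truths == "LN")
  }
  macro_f1(c(sen_h, sen_ln), c(sen_ln, sen_h))
}

#' Area under the precision-recall curve
#'
#' Step-wise construction over the unique score thresholds in descending
#' order (H is the positive class): at each threshold the recall and
#' precision of calling every case scoring at or above it are taken as
#' one PR point, and the area is the sum of `(R_t - R_{t-1}) * P_t`. Tied
#' scores enter as a single threshold. A constant score vector therefore
#' yields a single point with recall 1 and precision equal to prevalence,
#' giving an area equal to the prevalence.
#'
#' @param scores Numeric scores (higher means more likely H).
#' @param truths H/LN ground-truth labels.
#' @return Area in `[0, 1]`.
#' @export
auprc <- function(scores, truths) {
  truths <- as.character(truths)
  stopifnot(length(scores) == length(truths))
  pos <- truths == "H"
  if (!any(pos)) stop("auprc: no positive (H) case in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p)
  n_called <- seq_along(p)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[keep]; n_called <- n_called[keep]
  recall <- tp / sum(pos)
  precision <- tp / n_called
  sum(diff(c(0, recall)) * precision)
}

#' Bootstrap uncertainty of the AUPRC
#'
#' Mean and standard deviation of the AUPRC over seeded case resamples
#' (resamples without a positive case are redrawn).
#'
#' @inheritParams auprc
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List with `auprc` (point estimate), `boot_mean` and `boot_sd`.
#' @export
auprc_bootstrap <- function(scores, truths, n_boot = 1000, seed = 1) {
  point <- auprc(scores, truths)
  set.seed(seed)
  n <- length(scores)
  vals <- vapply(seq_len(n_boot), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(truths[idx] == "H")) break
    }
    auprc(scores[idx], truths[idx])
  }, numeric(1))
  list(auprc = point, boot_mean = mean(vals), boot_sd = stats::sd(vals))
}

#' Combine model and physician diagnoses with the OR rule
#'
#' A patient is classified high-grade if the model or the physician calls
#' them high-grade. This trades specificity for sensitivity: the combined
#' sensitivity is at least each input's, the combined specificity at most
#' each input's.
#'
#' @param model_call,physician_call H/LN vectors of equal length; a
#'   missing physician call is an error.
#' @return Factor of combined H/LN calls.
#' @export
combine_with_physician <- function(model_call, physician_call) {
  model_call <- as.character(model_call)
  physician_call <- as.character(physician_call)
  if (length(model_call) != length(physician_call) ||
        any(is.na(physician_call))) {
    stop("combine_with_physician: physician call missing")
  }
  stopifnot(all(model_call %in% c("H", "LN")),
            all(physician_call %in% c("H", "LN")))
  factor(ifelse(model_call == "H" | physician_call == "H", "H", "LN"),
         levels = c("LN", "H"))
}

#' Evaluate model, physician and combined diagnoses
#'
#' Builds the three-way evaluation report: confusion matrix and rates for
#' the model alone, for the physician alone, and for the OR-rule
#' combination, plus the model's AUPRC with bootstrap SD.
#'
#' @param predictions Prediction table from [predict_pipeline()].
#' @param truths H/LN ground-truth labels aligned with the predictions.
#' @param physician_calls Optional H/LN physician diagnoses.
#' @param n_boot,seed Bootstrap settings for the AUPRC uncertainty.
#' @return A `colpo_evaluation` list with elements `model`, `physician`,
#'   `combined` (each `colpo_metrics` or `NULL`) and `auprc`.
#' @export
evaluate_predictions <- function(predictions, truths,
                                 physician_calls = NULL,
                                 n_boot = 1000, seed = 1) {
  truths <- as.character(truths)
  model_m <- confusion_and_rates(predictions$call, truths)
  pr <- auprc_bootstrap(predictions$posterior_H, truths,
                        n_boot = n_boot, seed = seed)
  physician_m <- NULL; combined_m <- NULL
  if (!is.null(physician_calls)) {
    physician_m <- confusion_and_rates(physician_calls, truths)
    combined_m <- confusion_and_rates(
      combine_with_physician(predictions$call, physician_calls), truths)
  }
  structure(list(model = model_m, physician = physician_m,
                 combined = combined_m, auprc = pr),
            class = "colpo_evaluation")
}

#' @export
print.colpo_evaluation <- function(x, ...) {
  cat("== model ==\n"); print(x$model)
  cat(sprintf("  AUPRC %.3f +/- %.3f (bootstrap SD)\n",
              x$auprc$auprc, x$auprc$boot_sd))
  if (!is.null(x$physician)) {
    cat("== physician ==\n"); print(x$physician)
    cat("== model OR physician ==\n"); print(x$combined)
  }
  invisible(x)
}

#' Write an evaluation report (CSV + text)
#'
#' `<path>.csv` holds one row per diagnosis source with counts and rates;
#' `<path>.txt` holds the human-readable three-matrix report.
#'
#' @param evaluation A `colpo_evaluation`.
#' @param path Output path stem (without extension).
#' @export
write_evaluation_report <- function(evaluation, path) {
  rows <- list()
  for (src in c("model", "physician", "combined")) {
    m <- evaluation[[src]]
    if (is.null(m)) next
    rows[[src]] <- data.frame(source = src, tp = m$tp, fp = m$fp,
                              tn = m$tn, fn = m$fn,
                              sensitivity = m$sensitivity,
                              specificity = m$specificity,
                              accuracy = m$accuracy,
                              f1_macro = m$f1_macro,
                              auprc = if (src == "model")
                                evaluation$auprc$auprc else NA,
                              auprc_sd = if (src == "model")
                                evaluation$auprc$boot_sd else NA)
  }
  utils::write.csv(do.call(rbind, rows), paste0(path, ".csv"),
                   row.names = FALSE)
  sink(paste0(path, ".txt")); on.exit(sink())
  print(evaluation)
  invisible(path)
}
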