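test_that("confusion counts and rates follow their definitions", {
  all_right <- confusion_and_rates(c("H", "H", "LN"), c("H", "H", "LN"))
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  expect_equal(all_right$accuracy, 1)
  # tp 2, fn 2, tn 6, fp 0
  calls <- c("H", "H", "LN", "LN", rep("LN", 6))
  truth <- c("H", "H", "H", "H", rep("LN", 6))
  m <- confusion_and_rates(calls, truth)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(2, 2, 6, 0))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 10)
  expect_warning(res <- confusion_and_rates(rep("LN", 4), rep("LN", 4)),
                 "sensitivity undefined")
  expect_true(is.na(res$sensitivity))
  expect_error(confusion_and_rates(c("H", "X"), c("H", "LN")), "labels")
})

test_that("macro F1 matches direct substitution into the formula", {
  expect_equal(macro_f1(c(1, 1), c(1, 1)), 1)
  # per-class harmonic means 2*0.5*1/1.5 both
  expect_equal(macro_f1(c(0.5, 1.0), c(1.0, 0.5)), 2 / 3, tolerance = 1e-12)
  expect_equal(macro_f1(c(0, 0.8), c(0, 0.9)),
               (0 + 2 * 0.8 * 0.9 / 1.7) / 2)   # 0/0 term defined as 0
  expect_error(macro_f1(c(1, 1), 1), "length")
  # symmetric under class permutation
  set.seed(1)
  for (i in 1:10) {
    sen <- runif(2); spe <- runif(2)
    expect_equal(macro_f1(sen, spe), macro_f1(rev(sen), rev(spe)))
  }
})

test_that("AUPRC has the analytic values of canonical rankings", {
  truth <- rep(c("H", "LN"), c(4, 8))
  perfect <- c(runif(4, 0.8, 1), runif(8, 0, 0.5))
  expect_equal(auprc(perfect, truth), 1)
  # constant scores: single PR point at (recall 1, precision = prevalence)
  expect_equal(auprc(rep(0.3, 12), truth), 4 / 12)
  expect_error(auprc(runif(4), rep("LN", 4)), "no positive")
  # agreement with an explicit threshold-scan oracle on random scores
  set.seed(2)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    tr <- ifelse(runif(n) < 0.3, "H", "LN")
    if (!any(tr == "H")) tr[1] <- "H"
    sc <- round(runif(n), 2)   # induce ties
    expect_equal(auprc(sc, tr), auprc_oracle(sc, tr), tolerance = 1e-12)
  }
  # reversing a separable ranking cannot increase the area
  expect_lte(auprc(-perfect, truth), auprc(perfect, truth))
})

test_that("AUPRC bootstrap reports a seeded mean and SD", {
  set.seed(3)
  truth <- rep(c("H", "LN"), c(10, 40))
  scores <- runif(50) + 0.5 * (truth == "H")
  b1 <- auprc_bootstrap(scores, truth, n_boot = 200, seed = 9)
  b2 <- auprc_bootstrap(scores, truth, n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  expect_gt(b1$boot_sd, 0)
  expect_lt(abs(b1$boot_mean - b1$auprc), 0.15)
})

test_that("the OR rule combines calls and strictly trades specificity for sensitivity", {
  expect_equal(as.character(combine_with_physician("H", "LN")), "H")
  expect_equal(as.character(combine_with_physician("LN", "LN")), "LN")
  expect_equal(as.character(combine_with_physician("H", "H")), "H")
  expect_error(combine_with_physician(c("H", "LN"), c("H", NA)), "missing")
  # monotonicity: exact on any dataset
  set.seed(4)
  for (i in 1:20) {
    n <- 80
    truth <- ifelse(runif(n) < 0.2, "H", "LN")
    if (sum(truth == "H") == 0 || sum(truth == "LN") == 0) next
    model <- ifelse(runif(n) < 0.3, "H", "LN")
    phys <- ifelse(runif(n) < 0.3, "H", "LN")
    comb <- combine_with_physician(model, phys)
    mm <- confusion_and_rates(model, truth)
    mp <- confusion_and_rates(phys, truth)
    mc <- confusion_and_rates(comb, truth)
    expect_gte(mc$sensitivity, max(mm$sensitivity, mp$sensitivity))
    expect_lte(mc$specificity, min(mm$specificity, mp$specificity))
  }
})

test_that("evaluation reports cover model, physician and combination", {
  set.seed(5)
  n <- 60
  truth <- rep(c("H", "LN"), c(12, 48))
  predictions <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    svm_probability = runif(n),
    posterior_H = runif(n) + 0.4 * (truth == "H"),
    call = factor(ifelse(runif(n) + 0.4 * (truth == "H") > 0.6, "H", "LN"),
                  levels = c("LN", "H")))
  phys <- ifelse(runif(n) < 0.25, "H", "LN")
  ev <- evaluate_predictions(predictions, truth, phys, n_boot = 100, seed = 1)
  expect_s3_class(ev$model, "colpo_metrics")
  expect_s3_class(ev$physician, "colpo_metrics")
  expect_s3_class(ev$combined, "colpo_metrics")
  stem <- file.path(tempdir(), "evalrep")
  write_evaluation_report(ev, stem)
  tab <- read.csv(paste0(stem, ".csv"))
  expect_equal(tab$source, c("model", "physician", "combined"))
  txt <- readLines(paste0(stem, ".txt"))
  expect_length(grep("truth H", txt), 3)   # three confusion matrices
  unlink(paste0(stem, c(".csv", ".txt")))
})
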