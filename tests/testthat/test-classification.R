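test_that("SMOTE balances the classes with convex synthetic rows", {
  set.seed(1)
  x <- rbind(matrix(rnorm(20 * 3), 20, 3),
             matrix(rnorm(140 * 3, 4), 140, 3))
  labels <- rep(c("H", "LN"), c(20, 140))
  out <- smote_augment(x, labels, k = 2, seed = 5)
  expect_equal(as.integer(table(out$labels)[c("H", "LN")]), c(140L, 140L))
  expect_equal(out$x[1:160, ], x)                    # originals preserved
  # every synthetic row is a convex combination of two minority originals
  xm <- x[1:20, ]
  for (i in 161:nrow(out$x)) {
    s <- out$x[i, ]
    found <- FALSE
    for (a in 1:19) for (b in (a + 1):20) {
      dir <- xm[b, ] - xm[a, ]
      lam <- sum((s - xm[a, ]) * dir) / sum(dir * dir)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            sqrt(sum((xm[a, ] + lam * dir - s)^2)) < 1e-8) {
        found <- TRUE; break
      }
    }
    expect_true(found, info = paste("synthetic row", i))
  }
})

test_that("SMOTE leaves balanced input unchanged and rejects tiny minorities", {
  x <- matrix(rnorm(40), 20, 2)
  labels <- rep(c("H", "LN"), 10)
  out <- smote_augment(x, labels, k = 2, seed = 1)
  expect_identical(out$x, x)
  small <- rbind(x[1:2, ], x)
  expect_error(smote_augment(small, c("H", "H", rep("LN", 20)), k = 2),
               "smaller k")
})

test_that("the RBF-SVM stage separates well-separated clusters", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40 * 4, -2, 0.4), 40, 4),
             matrix(rnorm(40 * 4, 2, 0.4), 40, 4))
  labels <- factor(rep(c("H", "LN"), each = 40), levels = c("LN", "H"))
  stage <- train_svm_stage(x, labels, svm_stage_config(seed = 3))
  prob <- colpocad:::predict_svm_stage(stage, x)
  acc <- mean((prob >= 0.5) == (labels == "H"))
  expect_gt(acc, 0.95)
  # a training point's own class gets the majority probability
  expect_gt(prob[1], 0.5)
  expect_lt(prob[80], 0.5)
  expect_equal(stage$config$gamma, 0.72)
  expect_equal(stage$config$C, 0.12)
  expect_error(train_svm_stage(x, factor(rep("H", 80), levels = c("LN", "H"))),
               "both classes")
})

test_that("naive Bayes input tuples follow the declared schema", {
  rec <- data.frame(age = 50, hpv16_18 = 1, hpv_hr_non1618 = 0,
                    hpv_lowrisk = 0, tct = 5)
  tup <- assemble_nb_input(0.8, rec)
  expect_equal(unname(tup), c(0.8, 50, 1, 0, 0, 5))
  expect_length(tup, 6)
  expect_equal(names(tup), c("svm_prob", "age", "hpv1", "hpv2", "hpv3", "tct"))
  expect_error(assemble_nb_input(1.2, rec), "\\[0, 1\\]")
})

test_that("naive Bayes fusion behaves like Bayes' rule", {
  set.seed(4)
  n <- 400
  labels <- factor(rep(c("H", "LN"), c(100, 300)), levels = c("LN", "H"))
  inputs <- data.frame(
    svm_prob = ifelse(labels == "H", rbeta(n, 4, 2), rbeta(n, 2, 4)),
    age = sample(16:83, n, TRUE),
    hpv1 = as.numeric(labels == "H"),   # perfectly informative flag
    hpv2 = rbinom(n, 1, 0.5), hpv3 = rbinom(n, 1, 0.1),
    tct = sample(1:6, n, TRUE))
  nb <- train_naive_bayes(inputs, labels)
  base <- data.frame(svm_prob = 0.5, age = 40, hpv1 = 0, hpv2 = 1,
                     hpv3 = 0, tct = 2)
  flipped <- base; flipped$hpv1 <- 1
  expect_gt(predict_naive_bayes(nb, flipped),
            predict_naive_bayes(nb, base))
  # uninformative inputs: posterior approaches the class prior
  uninf <- inputs
  uninf$svm_prob <- 0.5; uninf$hpv1 <- 0
  nb2 <- train_naive_bayes(uninf, labels)
  post <- predict_naive_bayes(nb2, uninf[1, ])
  expect_lt(abs(post - unname(nb2$prior["H"])), 0.1)
  # the two class posteriors are complementary by construction
  expect_true(all(predict_naive_bayes(nb, inputs) >= 0))
  expect_true(all(predict_naive_bayes(nb, inputs) <= 1))
  # unseen tct category at prediction keeps positive probability
  unseen <- base; unseen$tct <- 6
  seen_only <- inputs; seen_only$tct <- sample(1:5, n, TRUE)
  nb3 <- train_naive_bayes(seen_only, labels)
  expect_true(is.finite(predict_naive_bayes(nb3, unseen)))
})

test_that("naive Bayes recovers its own generative parameters", {
  set.seed(6)
  n <- 5000
  labels <- factor(rep(c("H", "LN"), c(n / 2, n / 2)), levels = c("LN", "H"))
  p_true <- c(H = 0.7, LN = 0.2)
  inputs <- data.frame(
    svm_prob = runif(n), age = rnorm(n, 45, 10),
    hpv1 = rbinom(n, 1, p_true[as.character(labels)]),
    hpv2 = rbinom(n, 1, 0.4), hpv3 = rbinom(n, 1, 0.1),
    tct = sample(1:6, n, TRUE))
  nb <- train_naive_bayes(inputs, labels)
  expect_lt(abs(nb$par$H$hpv[["hpv1"]] - 0.7), 0.05)
  expect_lt(abs(nb$par$LN$hpv[["hpv1"]] - 0.2), 0.05)
})

test_that("the full two-stage pipeline is deterministic and accurate when separable", {
  df <- make_feature_cohort(n_h = 20, n_ln = 120, delta = 4, seed = 8)
  sel <- c("VIA_f01", "VIA_f02", "VILI_f01", "VILI_f02")
  model <- train_pipeline(df, sel, svm_stage_config(seed = 11))
  model2 <- train_pipeline(df, sel, svm_stage_config(seed = 11))
  test <- make_feature_cohort(n_h = 20, n_ln = 120, delta = 4, seed = 9)
  pred <- predict_pipeline(model, test)
  pred2 <- predict_pipeline(model2, test)
  expect_identical(pred, pred2)
  m <- confusion_and_rates(pred$call, test$label)
  expect_gt(m$sensitivity, 0.9)
  expect_gt(m$specificity, 0.9)
  # missing clinical field is reported by name
  broken <- test; broken$tct <- NULL
  expect_error(predict_pipeline(model, broken), "tct")
})

test_that("SMOTE improves sensitivity on skewed cohorts across seeds", {
  sens_with <- numeric(10); sens_without <- numeric(10)
  spec_with <- numeric(10)
  for (s in 1:10) {
    train <- make_feature_cohort(n_h = 20, n_ln = 140, delta = 1.1,
                                 seed = 300 + s)
    test <- make_feature_cohort(n_h = 30, n_ln = 210, delta = 1.1,
                                seed = 600 + s)
    sel <- grep("_f0[12]$", names(train), value = TRUE)
    x <- as.matrix(train[, sel]); y <- train$label
    ctr <- colMeans(x); scl <- pmax(apply(x, 2, sd), 1e-8)
    xs <- scale(x, ctr, scl)
    xt <- scale(as.matrix(test[, sel]), ctr, scl)
    cfg <- svm_stage_config(seed = s)
    bal <- smote_augment(xs, y, k = cfg$smote_k, seed = s)
    m_with <- train_svm_stage(bal$x, bal$labels, cfg)
    m_without <- train_svm_stage(xs, y, cfg)
    p_with <- colpocad:::predict_svm_stage(m_with, xt) >= 0.5
    p_without <- colpocad:::predict_svm_stage(m_without, xt) >= 0.5
    truth <- test$label == "H"
    sens_with[s] <- mean(p_with[truth]); sens_without[s] <- mean(p_without[truth])
    spec_with[s] <- mean(!p_with[!truth])
  }
  expect_gt(mean(sens_with), mean(sens_without))
  expect_gte(sum(sens_with >= sens_without), 8)   # nearly every seed
  expect_gt(mean(spec_with), 0.5)                 # specificity not collapsed
})

test_that("model artifacts reload to identical predictions", {
  df <- make_feature_cohort(seed = 12)
  sel <- c("VIA_f01", "VILI_f01")
  model <- train_pipeline(df, sel, svm_stage_config(seed = 1))
  dir <- file.path(tempdir(), "artifact_test")
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "selected_features.txt")))
  expect_true(file.exists(file.path(dir, "nb_parameters.json")))
  back <- load_model(dir)
  expect_identical(predict_pipeline(back, df), predict_pipeline(model, df))
  unlink(dir, recursive = TRUE)
})
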