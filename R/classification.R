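#' Configuration of the SVM stage
#'
#' Holds the radial-basis SVM hyperparameters and the SMOTE neighbour
#' count. The defaults are the operating point of the diagnosis model:
#' kernel `exp(-gamma * ||x - x'||^2)` with `gamma = 0.72`, a soft margin
#' `C = 0.12` (a deliberately simple decision surface), and `k = 2`
#' nearest minority neighbours for SMOTE interpolation.
#'
#' @param gamma RBF kernel width, > 0.
#' @param C Regularisation trade-off, > 0.
#' @param smote_k SMOTE neighbour count, >= 1.
#' @param seed Integer seed for SMOTE and the probability calibration.
#' @return An `svm_stage_config` list.
#' @export
svm_stage_config <- function(gamma = 0.72, C = 0.12, smote_k = 2L,
                             seed = 1L) {
  stopifnot(gamma > 0, C > 0, smote_k >= 1)
  structure(list(gamma = gamma, C = C, smote_k = as.integer(smote_k),
                 seed = as.integer(seed)),
            class = "svm_stage_config")
}

#' SMOTE: synthetic minority oversampling
#'
#' Balances a two-class sample by interpolating new minority points: each
#' synthetic row is `x + lambda * (x_nn - x)` for a minority point `x`,
#' one of its `k` nearest minority neighbours `x_nn` (Euclidean distance)
#' and `lambda ~ U(0, 1)`, until the minority count reaches the majority
#' count. Base points are cycled through the minority class so the
#' synthetic mass spreads evenly; originals are preserved. Already
#' balanced input is returned unchanged.
#'
#' @param x Numeric matrix (rows = cases).
#' @param labels Two-class factor/character vector aligned with rows.
#' @param k Number of nearest minority neighbours (default 2); the
#'   minority class must have more than `k` members.
#' @param seed Integer seed.
#' @return List with the augmented `x` (originals first, synthetics
#'   appended) and `labels`.
#' @export
smote_augment <- function(x, labels, k = 2L, seed = 1L) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels))
  tab <- table(labels)
  if (length(tab) != 2) stop("smote_augment: expected exactly two classes")
  if (tab[1] == tab[2]) return(list(x = x, labels = labels))
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min <= k) {
    stop("smote_augment: minority class has ", n_min,
         " members, too few for k = ", k, " neighbours; use a smaller k")
  }
  set.seed(seed)
  xm <- x[labels == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  n_new <- n_maj - n_min
  base <- ((seq_len(n_new) - 1) %% n_min) + 1
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  lambda <- stats::runif(n_new)
  synth <- xm[base, , drop = FALSE] +
    lambda * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  rownames(synth) <- NULL
  list(x = rbind(x, synth),
       labels = factor(c(as.character(labels), rep(minority, n_new)),
                       levels = levels(labels)))
}

#' Train the SMOTE-balanced RBF-SVM stage
#'
#' Fits a radial-basis SVM with Platt-style class-probability calibration
#' on (already standardised) image features. Inputs are expected z-scored
#' with training-split statistics so that RBF distances are commensurate
#' across features.
#'
#' @param x Numeric matrix of standardised selected features.
#' @param labels Factor H/LN labels.
#' @param config An [svm_stage_config()]; `gamma`, `C` and the seed used
#'   for the internal calibration folds are recorded in the model.
#' @return List with the fitted `e1071::svm` model and `config`.
#' @export
train_svm_stage <- function(x, labels, config = svm_stage_config()) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("LN", "H"))
  if (length(unique(labels)) < 2) {
    stop("train_svm_stage: both classes must be present")
  }
  set.seed(config$seed)  # calibration uses internal random folds
  fit <- e1071::svm(x, labels, kernel = "radial", gamma = config$gamma,
                    cost = config$C, probability = TRUE, scale = FALSE)
  list(fit = fit, config = config, n_features = ncol(x))
}

# P(H) from the SVM stage for a standardised feature matrix.
predict_svm_stage <- function(stage, x) {
  pr <- attr(stats::predict(stage$fit, as.matrix(x), probability = TRUE),
             "probabilities")
  as.numeric(pr[, "H"])
}

#' Assemble the naive Bayes input tuple
#'
#' The fusion stage sees six inputs in a fixed order: the SVM probability
#' of the high-grade class, age (years), the three HPV positivity flags
#' and the TCT category code.
#'
#' @param svm_probability Value in `[0, 1]`.
#' @param record One-row clinical record (see
#'   [encode_clinical_features()]).
#' @return Named numeric vector
#'   `c(svm_prob, age, hpv1, hpv2, hpv3, tct)`.
#' @export
assemble_nb_input <- function(svm_probability, record) {
  if (!is.finite(svm_probability) || svm_probability < 0 ||
        svm_probability > 1) {
    stop("assemble_nb_input: svm_probability must be in [0, 1]")
  }
  c(svm_prob = as.numeric(svm_probability), encode_clinical_features(record))
}

nb_fields <- c("svm_prob", "age", "hpv1", "hpv2", "hpv3", "tct")

#' Train the mixed-family naive Bayes fusion stage
#'
#' Class-conditional families follow the declared type of each input:
#' Gaussian for the numerical SVM probability and age; Bernoulli for the
#' three HPV flags (Jeffreys add-half estimate, so a flag observed as
#' constant within a class never yields a zero likelihood); categorical
#' with add-one smoothing over the six codes for TCT (an unseen category
#' at prediction time keeps positive probability). Class priors are the
#' training frequencies. Gaussian SDs are floored at 1e-6 to keep the
#' density finite on degenerate inputs.
#'
#' @param inputs Matrix/data frame with columns `svm_prob`, `age`,
#'   `hpv1`, `hpv2`, `hpv3`, `tct` (see [assemble_nb_input()]).
#' @param labels Factor H/LN labels.
#' @return An `nb_model` list of priors and per-field parameters.
#' @export
train_naive_bayes <- function(inputs, labels) {
  inputs <- as.data.frame(inputs)
  stopifnot(all(nb_fields %in% names(inputs)))
  labels <- factor(as.character(labels), levels = c("LN", "H"))
  if (length(unique(labels)) < 2) {
    stop("train_naive_bayes: both classes must be present")
  }
  classes <- c("LN", "H")
  par <- lapply(classes, function(cl) {
    sub <- inputs[labels == cl, , drop = FALSE]
    n <- nrow(sub)
    gauss <- function(v) c(mean = mean(v), sd = max(stats::sd(v), 1e-6))
    list(n = n,
         svm_prob = gauss(sub$svm_prob),
         age = gauss(sub$age),
         hpv = vapply(c("hpv1", "hpv2", "hpv3"), function(f) {
           (sum(sub[[f]]) + 0.5) / (n + 1)  # Jeffreys
         }, numeric(1)),
         tct = (tabulate(sub$tct, nbins = 6) + 1) / (n + 6))  # add-one
  })
  names(par) <- classes
  structure(list(prior = prop.table(table(labels))[classes], par = par),
            class = "nb_model")
}

#' Posterior probability of the high-grade class under the fusion model
#'
#' @param model An `nb_model` from [train_naive_bayes()].
#' @param inputs Matrix/data frame of naive Bayes input tuples.
#' @return Numeric vector of `P(H | inputs)`; the LN posterior is its
#'   complement.
#' @export
predict_naive_bayes <- function(model, inputs) {
  stopifnot(inherits(model, "nb_model"))
  inputs <- as.data.frame(inputs)
  stopifnot(all(nb_fields %in% names(inputs)))
  if (any(!inputs$tct %in% 1:6)) {
    stop("predict_naive_bayes: tct outside 1..6")
  }
  loglik <- vapply(c("LN", "H"), function(cl) {
    p <- model$par[[cl]]
    ll <- log(model$prior[[cl]]) +
      stats::dnorm(inputs$svm_prob, p$svm_prob["mean"], p$svm_prob["sd"],
                   log = TRUE) +
      stats::dnorm(inputs$age, p$age["mean"], p$age["sd"], log = TRUE)
    for (i in 1:3) {
      f <- inputs[[c("hpv1", "hpv2", "hpv3")[i]]]
      ll <- ll + f * log(p$hpv[i]) + (1 - f) * log(1 - p$hpv[i])
    }
    ll + log(p$tct[inputs$tct])
  }, numeric(nrow(inputs)))
  loglik <- matrix(loglik, ncol = 2)
  m <- pmax(loglik[, 1], loglik[, 2])
  w <- exp(loglik - m)
  w[, 2] / (w[, 1] + w[, 2])
}

#' Train the full two-stage diagnosis model
#'
#' Runs the training procedure on a feature table of the training split:
#' (1) restrict to the selected image features and z-score them with
#' training statistics; (2) rebalance the H class by SMOTE in the
#' standardised space; (3) fit the probability-calibrated RBF-SVM; (4)
#' score the original (non-synthetic) training cases with the SVM and fit
#' the naive Bayes fusion stage on the six-input tuples. Deterministic
#' given `svm_config$seed`.
#'
#' @param train Training feature table from [extract_cohort_features()]
#'   (must contain the selected feature columns, the clinical columns and
#'   `label`).
#' @param selected_features Character vector of feature column names
#'   (e.g. from [select_top_k()], both modalities concatenated).
#' @param svm_config An [svm_stage_config()].
#' @param threshold Decision threshold on the H posterior (default 0.5;
#'   posteriors equal to the threshold are called H, favouring
#'   sensitivity).
#' @return A `colpo_model` holding the selected feature list,
#'   standardisation statistics, both stages, the config and the training
#'   patient ids.
#' @export
train_pipeline <- function(train, selected_features,
                           svm_config = svm_stage_config(),
                           threshold = 0.5) {
  stopifnot(all(selected_features %in% names(train)))
  labels <- factor(as.character(train$label), levels = c("LN", "H"))
  x <- as.matrix(train[, selected_features, drop = FALSE])
  center <- colMeans(x)
  scale_ <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- scale(x, center = center, scale = scale_)
  bal <- smote_augment(xs, labels, k = svm_config$smote_k,
                       seed = svm_config$seed)
  svm_stage <- train_svm_stage(bal$x, bal$labels, svm_config)
  svm_prob <- predict_svm_stage(svm_stage, xs)
  nb_in <- data.frame(svm_prob = svm_prob, encode_clinical_matrix(train))
  nb <- train_naive_bayes(nb_in, labels)
  structure(list(selected_features = selected_features, center = center,
                 scale = scale_, svm_stage = svm_stage, nb = nb,
                 config = svm_config, threshold = threshold,
                 train_ids = train$patient_id),
            class = "colpo_model")
}

#' @export
print.colpo_model <- function(x, ...) {
  cat(sprintf(paste0("<colpo_model> %d selected features ",
                     "(gamma = %g, C = %g, SMOTE k = %d, threshold = %g)\n"),
              length(x$selected_features), x$config$gamma, x$config$C,
              x$config$smote_k, x$threshold))
  invisible(x)
}

#' Predict diagnoses with a trained two-stage model
#'
#' @param model A `colpo_model` from [train_pipeline()].
#' @param cases Feature table of the cases to score (selected feature
#'   columns plus clinical columns).
#' @return Data frame with `patient_id`, `svm_probability`, `posterior_H`
#'   and the hard `call` (H iff `posterior_H >= threshold`).
#' @export
predict_pipeline <- function(model, cases) {
  stopifnot(inherits(model, "colpo_model"))
  missing_cols <- setdiff(model$selected_features, names(cases))
  if (length(missing_cols)) {
    stop("predict_pipeline: missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (f in c("age", "hpv16_18", "hpv_hr_non1618", "hpv_lowrisk", "tct")) {
    if (!f %in% names(cases) || any(is.na(cases[[f]]))) {
      stop("predict_pipeline: missing clinical field: ", f)
    }
  }
  x <- as.matrix(cases[, model$selected_features, drop = FALSE])
  xs <- scale(x, center = model$center, scale = model$scale)
  svm_prob <- predict_svm_stage(model$svm_stage, xs)
  nb_in <- data.frame(svm_prob = svm_prob, encode_clinical_matrix(cases))
  post <- predict_naive_bayes(model$nb, nb_in)
  data.frame(patient_id = cases$patient_id,
             svm_probability = svm_prob,
             posterior_H = post,
             call = factor(ifelse(post >= model$threshold, "H", "LN"),
                           levels = c("LN", "H")))
}

#' Save / load a trained model artifact
#'
#' Writes a reloadable model directory: human-readable sidecars
#' (`selected_features.txt`, `standardization.csv`, `nb_parameters.json`,
#' `config.json`) plus the serialised model object (`model.rds`).
#'
#' @param model A `colpo_model`.
#' @param dir Artifact directory (created if needed).
#' @return `dir` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "colpo_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(model$selected_features, file.path(dir, "selected_features.txt"))
  utils::write.csv(data.frame(feature = model$selected_features,
                              center = model$center, scale = model$scale),
                   file.path(dir, "standardization.csv"), row.names = FALSE)
  jsonlite::write_json(model$nb[c("prior", "par")],
                       file.path(dir, "nb_parameters.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
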