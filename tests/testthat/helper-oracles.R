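# Independent brute-force oracles used to validate the feature
# primitives, plus small fixture builders. The oracles deliberately use
# naive enumeration, not the vectorised implementation paths.

# GLCM by explicit enumeration of every ordered pixel pair at the given
# displacement (y axis pointing up; image row 1 is the top row).
glcm_oracle <- function(gray, d, theta, levels) {
  q <- matrix(pmin(floor(pmin(pmax(gray, 0), 255) * levels / 256),
                   levels - 1), nrow(gray), ncol(gray))
  shift <- switch(as.character(theta),
                  "0" = c(0, d), "45" = c(-d, d),
                  "90" = c(-d, 0), "135" = c(-d, -d))
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + shift[1]; c2 <- cc + shift[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, cc] + 1, q[r2, c2] + 1] <- P[q[r, cc] + 1, q[r2, c2] + 1] + 1
      }
    }
  }
  P / sum(P)
}

# Haralick descriptors by direct substitution into the definitions.
haralick_oracle <- function(P) {
  levels <- nrow(P)
  asm <- 0; contrast <- 0; dissim <- 0; homog <- 0
  for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
    p <- P[i + 1, j + 1]
    asm <- asm + p^2
    contrast <- contrast + p * (i - j)^2
    dissim <- dissim + p * abs(i - j)
    homog <- homog + p / (1 + (i - j)^2)
  }
  pi_ <- rowSums(P); pj <- colSums(P)
  mu_i <- sum((0:(levels - 1)) * pi_); mu_j <- sum((0:(levels - 1)) * pj)
  sd_i <- sqrt(sum(((0:(levels - 1)) - mu_i)^2 * pi_))
  sd_j <- sqrt(sum(((0:(levels - 1)) - mu_j)^2 * pj))
  corr <- if (sd_i == 0 || sd_j == 0) 1 else {
    s <- 0
    for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
      s <- s + P[i + 1, j + 1] * (i - mu_i) * (j - mu_j)
    }
    s / (sd_i * sd_j)
  }
  c(ASM = asm, Contrast = contrast, Correlation = corr,
    Dissimilarity = dissim, Energy = sqrt(asm), Homogeneity = homog)
}

# Otsu by an explicit loop over all 255 cuts, recomputing the two class
# variances from the raw values each time; same midpoint-of-ties rule.
otsu_oracle <- function(values) {
  v <- round(as.vector(values))
  n <- length(v)
  wcv <- vapply(0:254, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    s <- 0
    if (length(lo) > 0) s <- s + length(lo) / n * mean((lo - mean(lo))^2)
    if (length(hi) > 0) s <- s + length(hi) / n * mean((hi - mean(hi))^2)
    s
  }, numeric(1))
  best <- which(wcv <= min(wcv) + 1e-9)
  (0:254)[floor((min(best) + max(best)) / 2)]
}

# Area under the precision-recall curve by scanning every distinct
# threshold explicitly.
auprc_oracle <- function(scores, truths) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truths == "H")
  prev_recall <- 0; area <- 0
  for (t in thresholds) {
    called <- scores >= t
    recall <- sum(called & truths == "H") / n_pos
    precision <- sum(called & truths == "H") / sum(called)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Small image/feature fixtures -------------------------------------------

const_image <- function(rgb, h = 24, w = 24) {
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

# A synthetic per-patient feature table (no images): VIA/VILI feature
# columns from class-shifted Gaussians plus neutral clinical columns.
# `informative_via`/`informative_vili` columns get a `delta`-SD mean
# shift in the H group.
make_feature_cohort <- function(n_h = 20, n_ln = 140, n_via = 6,
                                n_vili = 6, informative_via = 2,
                                informative_vili = 2, delta = 1.5,
                                seed = 1) {
  set.seed(seed)
  n <- n_h + n_ln
  label <- factor(rep(c("H", "LN"), c(n_h, n_ln)), levels = c("LN", "H"))
  make_block <- function(prefix, n_feat, n_inf) {
    m <- matrix(rnorm(n * n_feat), n, n_feat)
    if (n_inf > 0) {
      m[label == "H", seq_len(n_inf)] <-
        m[label == "H", seq_len(n_inf)] + delta
    }
    colnames(m) <- sprintf("%s_f%02d", prefix, seq_len(n_feat))
    m
  }
  df <- data.frame(patient_id = sprintf("S%04d", seq_len(n)),
                   make_block("VIA", n_via, informative_via),
                   make_block("VILI", n_vili, informative_vili))
  df$age <- sample(16:83, n, replace = TRUE)
  df$hpv16_18 <- rbinom(n, 1, ifelse(label == "H", 0.6, 0.25))
  df$hpv_hr_non1618 <- rbinom(n, 1, 0.7)
  df$hpv_lowrisk <- rbinom(n, 1, 0.1)
  df$tct <- sample(1:6, n, replace = TRUE)
  df$pathology <- ifelse(label == "H", "HSIL", "normal")
  df$physician_call <- as.character(label)
  df$exam_month <- rep_len(1:4, n)
  df$label <- label
  df
}

# SD of one converted channel over the disc interior only: the cervix
# disc is chromatic while the background is nearly achromatic, so a
# chroma cut isolates it regardless of lesion contrast.
interior_channel_std <- function(image, channel, chroma_min = 40) {
  chroma <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
    pmin(image[, , 1], image[, , 2], image[, , 3])
  plane <- convert_color_spaces(image)[[channel]]
  sd(plane[chroma > chroma_min])
}

# One small shared image cohort, generated once per test run.
.test_cache <- new.env(parent = emptyenv())
get_test_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    cfg <- synthesis_config(
      n_per_class = c(normal = 24, LSIL = 24, HSIL = 5, cancer = 2),
      image_size = c(112, 112))
    .test_cache$cohort <- generate_cohort(cfg, seed = 420)
    .test_cache$features <- extract_cohort_features(.test_cache$cohort)
  }
  list(cohort = .test_cache$cohort, features = .test_cache$features)
}
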