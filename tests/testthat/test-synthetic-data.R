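test_that("renders are deterministic under the seed", {
  cfg <- synthesis_config()
  a <- render_via_image("H", cfg, seed = 42)
  b <- render_via_image("H", cfg, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$roi, b$roi)
  c1 <- render_vili_image("LN", cfg, seed = 42)
  c2 <- render_vili_image("LN", cfg, seed = 42)
  expect_identical(c1$image, c2$image)
  expect_false(identical(a$image, render_via_image("H", cfg, seed = 43)$image))
})

test_that("noise-free normal discs are a single constant colour", {
  cfg <- synthesis_config(noise_sd = 0, benign_strength = 0)
  for (render in list(render_via_image, render_vili_image)) {
    r <- render("LN", cfg, seed = 3)
    crop <- crop_roi(r$image, r$roi)
    # interior: erode the bounding box so only disc pixels remain
    inner <- crop[round(nrow(crop) * 0.4):round(nrow(crop) * 0.6),
                  round(ncol(crop) * 0.4):round(ncol(crop) * 0.6), ]
    expect_equal(nrow(unique(matrix(inner, ncol = 3))), 1)
  }
})

test_that("lesion patches stay inside the annotated disc box", {
  cfg <- synthesis_config(noise_sd = 0)
  bg <- c(42, 40, 46)
  for (s in 1:6) {
    for (render in list(render_via_image, render_vili_image)) {
      r <- render("H", cfg, seed = 200 + s)
      img <- r$image
      h <- dim(img)[1]; w <- dim(img)[2]
      fg <- abs(img[, , 1] - bg[1]) + abs(img[, , 2] - bg[2]) +
        abs(img[, , 3] - bg[3]) > 3
      rows <- which(rowSums(fg) > 0); cols <- which(colSums(fg) > 0)
      # every non-background pixel (disc and all patches) inside the box
      expect_gte(min(cols) - 1, r$roi$x)
      expect_lte(max(cols) - 1, r$roi$x + r$roi$width - 1)
      expect_gte(h - max(rows), r$roi$y)
      expect_lte(h - min(rows), r$roi$y + r$roi$height)
    }
  }
})

test_that("clinical sampling reproduces the pooled HPV/TCT marginals", {
  n <- 8000
  set.seed(99)
  labels <- ifelse(runif(n) < 1 / 8, "H", "LN")  # 1:7 skew
  draws <- do.call(rbind, lapply(seq_len(n), function(i) {
    sample_clinical(labels[i], seed = 10000 + i)
  }))
  hpv_neg <- mean(draws$hpv16_18 == 0 & draws$hpv_hr_non1618 == 0 &
                    draws$hpv_lowrisk == 0)
  expect_lt(abs(hpv_neg - 0.102), 0.02)
  expect_lt(abs(mean(draws$tct == 1) - 0.516), 0.03)
  expect_true(all(draws$age >= 16 & draws$age <= 83))
  # high-grade records skew toward HPV 16/18 and cytology ASC-H or worse
  expect_gt(mean(draws$hpv16_18[labels == "H"]),
            mean(draws$hpv16_18[labels == "LN"]))
  expect_gt(mean(draws$tct[labels == "H"] >= 3),
            mean(draws$tct[labels == "LN"] >= 3))
  expect_identical(sample_clinical("H", seed = 5), sample_clinical("H", seed = 5))
})

test_that("generated cohorts have the configured composition", {
  tc <- get_test_cohort()
  cohort <- tc$cohort
  expect_equal(nrow(cohort$clinical), 55)
  expect_equal(sum(cohort$clinical$label == "H"), 7)
  # one VIA and one VILI image per patient
  expect_true(all(vapply(cohort$images, length, integer(1)) == 2))
  expect_equal(nrow(cohort$rois), 2 * 55)
  # determinism of the whole cohort
  cohort2 <- generate_cohort(cohort$config, seed = 420)
  expect_identical(cohort2$clinical, cohort$clinical)
  expect_identical(cohort2$images[[10]], cohort$images[[10]])
  # default-sized cohort arithmetic: 160 cases at 1:7
  cfg <- synthesis_config()
  grades <- rep(c("normal", "LSIL", "HSIL", "cancer"),
                times = cfg$n_per_class[c("normal", "LSIL", "HSIL", "cancer")])
  lab <- binary_label(grades)
  expect_equal(sum(lab == "H"), 20)
  expect_equal(sum(lab == "LN"), 140)
})

test_that("simulated physician hits the configured operating point", {
  set.seed(1)
  n <- 6000
  labels <- rep(c("H", "LN"), c(n / 2, n / 2))
  calls <- colpocad:::simulate_physician(labels, 0.537, 0.898)
  sens <- mean(calls[labels == "H"] == "H")
  spec <- mean(calls[labels == "LN"] == "LN")
  expect_lt(abs(sens - 0.537), 0.03)
  expect_lt(abs(spec - 0.898), 0.03)
})

test_that("lesion contrast acts as a separability dial", {
  # univariate AUC of the VILI blue-yellow spread, rising with contrast
  auc_for <- function(contrast, seed0) {
    cfg <- synthesis_config(image_size = c(96, 96),
                            lesion_contrast = contrast)
    n_h <- 10; n_ln <- 14
    vals <- vapply(seq_len(n_h + n_ln), function(i) {
      lab <- if (i <= n_h) "H" else "LN"
      r <- render_vili_image(lab, cfg, seed = seed0 + i)
      interior_channel_std(r$image, "Lb")
    }, numeric(1))
    lab <- rep(c("H", "LN"), c(n_h, n_ln))
    w <- wilcox.test(vals[lab == "H"], vals[lab == "LN"], exact = FALSE)
    unname(w$statistic) / (n_h * n_ln)   # rank AUC
  }
  aucs <- vapply(c(4, 45, 200), auc_for, numeric(1), seed0 = 5000)
  expect_lt(aucs[1], aucs[3] - 0.2)   # dial spans chance-ish to strong
  expect_lte(aucs[1], aucs[2] + 0.1)  # monotone trend up to sampling noise
  expect_lte(aucs[2], aucs[3] + 0.1)
})
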