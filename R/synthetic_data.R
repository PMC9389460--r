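#' Configuration of the synthetic cervigram cohort
#'
#' The generator emulates the class structure the diagnosis pipeline
#' assumes: a light-pink cervix disc on a dark background for VIA (with
#' high-contrast whitish mosaic patches inside the disc for high-grade
#' cases), a dark-brown disc for VILI (with pale-yellow iodine-negative
#' patches for high-grade cases), a roughly 1:7 H:LN class skew, and
#' HPV/TCT distributions whose class-conditional skew pulls high-grade
#' records toward HPV 16/18 positivity and cytology ASC-H or worse.
#'
#' @param n_per_class Named counts of patients per pathology grade. The
#'   default `c(normal = 70, LSIL = 70, HSIL = 15, cancer = 5)` gives 160
#'   patients at the 1:7 high-grade to low-grade/normal skew of a
#'   colposcopy referral population.
#' @param image_size `c(width, height)` in pixels. 160 px comfortably
#'   holds the disc, lesion patches and the largest co-occurrence offset
#'   (15 px) while keeping a full cohort render cheap.
#' @param h_to_ln_ratio_target Intended H:(LN) ratio, checked against
#'   `n_per_class` (warning when off by more than rounding).
#' @param lesion_patch_count_range Range of mosaic/iodine-negative patch
#'   counts per high-grade image.
#' @param lesion_contrast Intensity offset (0-255) controlling lesion
#'   visibility: it scales both the blend of the patch colour into the
#'   disc colour (`lesion_contrast / 255`) and the amplitude of the
#'   checkerboard micro-texture (`lesion_contrast / 3` gray levels). 0
#'   makes high-grade images indistinguishable from low-grade ones; the
#'   default 45 gives the moderate separability of a realistically hard
#'   screening problem rather than a toy separable one.
#' @param noise_sd Gaussian pixel noise SD per channel (default 8).
#' @param benign_strength Fraction of the lesion strength at which benign
#'   mottling — faint patches of the same appearance, present in every
#'   image of both classes — is rendered (default 0.35). This emulates
#'   normal epithelium shades and faint metaplastic whitening, the main
#'   clinical confounders: classes then differ in the strength and count
#'   of patches, not in their mere presence, which keeps the synthetic
#'   problem hard the way the clinical one is.
#' @param physician_sensitivity,physician_specificity Operating point of
#'   the simulated colposcopist (label-noise channel on the true H/LN
#'   label); defaults 0.537 and 0.898, a realistic colposcopy operating
#'   point for detecting high-grade disease.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(n_per_class = c(normal = 70, LSIL = 70,
                                             HSIL = 15, cancer = 5),
                             image_size = c(160, 160),
                             h_to_ln_ratio_target = 1 / 7,
                             lesion_patch_count_range = c(1, 3),
                             lesion_contrast = 45,
                             noise_sd = 8,
                             benign_strength = 0.35,
                             physician_sensitivity = 0.537,
                             physician_specificity = 0.898) {
  stopifnot(all(pathology_levels %in% names(n_per_class)),
            length(image_size) == 2, all(image_size >= 48),
            lesion_contrast >= 0, lesion_contrast <= 255,
            noise_sd >= 0, benign_strength >= 0, benign_strength <= 1,
            lesion_patch_count_range[1] >= 1,
            lesion_patch_count_range[2] >= lesion_patch_count_range[1])
  n_h <- sum(n_per_class[c("HSIL", "cancer")])
  n_ln <- sum(n_per_class[c("normal", "LSIL")])
  if (n_ln > 0 && abs(n_h / n_ln - h_to_ln_ratio_target) >
        1 / max(1, n_ln)) {
    warning("synthesis_config: n_per_class implies H:LN = ", n_h, ":", n_ln,
            ", off the stated target ratio")
  }
  structure(list(n_per_class = n_per_class, image_size = image_size,
                 h_to_ln_ratio_target = h_to_ln_ratio_target,
                 lesion_patch_count_range = lesion_patch_count_range,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 benign_strength = benign_strength,
                 physician_sensitivity = physician_sensitivity,
                 physician_specificity = physician_specificity),
            class = "synthesis_config")
}

# Base colours of the renders (8-bit RGB). Only relative contrasts matter;
# the pale-yellow is chosen with a clearly higher CIELAB b than the brown
# so iodine-negative patches perturb the blue-yellow axis, and the mosaic
# whites straddle the pink's Cb value.
synth_palette <- list(
  background = c(42, 40, 46),
  via_disc = c(230, 175, 185),    # light pink
  via_lesion_a = c(250, 248, 240), # warm acetowhite
  via_lesion_b = c(235, 240, 250), # bluish acetowhite
  vili_disc = c(95, 55, 25),      # iodine dark brown
  vili_lesion = c(235, 225, 120)  # pale yellow
)

# Fill colour `col` into image `img` where `mask` is TRUE, blending with
# weight alpha.
blend_mask <- function(img, mask, col, alpha = 1) {
  for (k in 1:3) {
    plane <- img[, , k]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * col[k]
    img[, , k] <- plane
  }
  img
}

# Shared disc-scene renderer. Draws the cervix disc, optional lesion
# patches for high-grade cases, then adds Gaussian pixel noise. All
# randomness is governed by `seed`. Returns the image and the disc's
# bounding box (bottom-left origin).
render_scene <- function(label, config, seed, modality) {
  stopifnot(label %in% c("H", "LN"), inherits(config, "synthesis_config"),
            modality %in% c("VIA", "VILI"))
  set.seed(seed)
  w <- config$image_size[1]; h <- config$image_size[2]
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- synth_palette$background[k]

  # pixel-centre coordinates, bottom-left origin
  xx <- matrix(rep(0:(w - 1), each = h), h, w)
  yy <- matrix(rep((h - 1):0, times = w), h, w)

  r <- 0.38 * min(w, h) * stats::runif(1, 0.92, 1.05)
  cx <- (w - 1) / 2 + stats::runif(1, -4, 4)
  cy <- (h - 1) / 2 + stats::runif(1, -4, 4)
  disc <- (xx - cx)^2 + (yy - cy)^2 <= r^2

  disc_col <- (if (modality == "VIA") synth_palette$via_disc
               else synth_palette$vili_disc) + stats::runif(3, -10, 10)
  img <- blend_mask(img, disc, disc_col)

  # one acetowhite/iodine-negative patch at `strength` (1 = full lesion)
  draw_patch <- function(img, strength) {
    alpha <- strength * min(1, config$lesion_contrast / 255)
    amp <- strength * config$lesion_contrast / 3
    pr <- r * stats::runif(1, 0.12, 0.26)
    # keep the whole patch inside the disc
    rho <- stats::runif(1, 0, max(0, r - pr - 2))
    ang <- stats::runif(1, 0, 2 * pi)
    px <- cx + rho * cos(ang); py <- cy + rho * sin(ang)
    patch <- (xx - px)^2 + (yy - py)^2 <= pr^2
    if (modality == "VIA") {
      # jittered checkerboard mosaic micro-texture
      period <- sample(4:12, 1)
      phase <- stats::runif(2, 0, period)
      parity <- (floor((xx + phase[1]) / period) +
                   floor((yy + phase[2]) / period)) %% 2
      img <- blend_mask(img, patch & parity == 0,
                        synth_palette$via_lesion_a, alpha)
      img <- blend_mask(img, patch & parity == 1,
                        synth_palette$via_lesion_b, alpha)
      lum <- amp * (2 * parity - 1)
      for (k in 1:3) {
        plane <- img[, , k]
        plane[patch] <- plane[patch] + lum[patch]
        img[, , k] <- plane
      }
    } else {
      img <- blend_mask(img, patch, synth_palette$vili_lesion, alpha)
    }
    img
  }

  # benign mottling: both classes carry patches of variable faint-to-
  # moderate strength (normal epithelium shades, metaplastic whitening
  # that can mimic true acetowhitening), so the classes overlap in
  # degree rather than separating on the mere presence of texture
  if (config$benign_strength > 0) {
    for (p in seq_len(sample.int(3, 1))) {
      s <- min(1, config$benign_strength * stats::runif(1, 0.5, 2.2))
      img <- draw_patch(img, s)
    }
  }
  if (label == "H") {
    counts <- seq(config$lesion_patch_count_range[1],
                  config$lesion_patch_count_range[2])
    n_patch <- counts[sample.int(length(counts), 1)]
    for (p in seq_len(n_patch)) {
      img <- draw_patch(img, stats::runif(1, 0.65, 1))
    }
  }

  if (config$noise_sd > 0) {
    img <- img + array(stats::rnorm(h * w * 3, 0, config$noise_sd),
                       dim = c(h, w, 3))
  }
  img <- round(pmin(pmax(img, 0), 255))

  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  list(image = img, roi = roi_box(x0, y0, x1 - x0 + 1, y1 - y0 + 1))
}

#' Render one synthetic VIA cervigram
#'
#' A light-pink cervix disc on a dark background; for high-grade (`H`)
#' cases, whitish acetowhite patches with jittered checkerboard mosaic
#' micro-texture (period 4-12 px) are placed fully inside the disc. The
#' mosaic provides the gray-level contrast/dissimilarity signal and the
#' white-vs-pink blend the blue-difference chroma signal that separate
#' high-grade images.
#'
#' @param label `"H"` or `"LN"`.
#' @param config A [synthesis_config()].
#' @param seed Integer seed; identical seeds give identical rasters.
#' @return List with `image` (`h x w x 3` array, 0-255) and `roi` (the
#'   disc's bounding `roi_box`).
#' @export
render_via_image <- function(label, config = synthesis_config(), seed = 1) {
  render_scene(label, config, seed, "VIA")
}

#' Render one synthetic VILI cervigram
#'
#' A dark-brown (iodine-stained) disc; for high-grade cases, pale-yellow
#' iodine-negative patches inside the disc. The yellow patches perturb
#' mainly the CIELAB blue-yellow axis and the chroma channels.
#'
#' @inheritParams render_via_image
#' @return List with `image` and `roi` as in [render_via_image()].
#' @export
render_vili_image <- function(label, config = synthesis_config(), seed = 1) {
  render_scene(label, config, seed, "VILI")
}

# Class-conditional clinical distributions. Pooled at the default 1:7
# class skew these approximate a colposcopy referral population: HPV
# negative ~10.2%, HPV 16/18 ~27.7% of patients, cytology NILM ~51.6%.
# The class-conditional split (high-grade cases skewed toward HPV 16/18
# positivity and cytology ASC-H or worse) is a synthetic modelling choice;
# only the pooled marginals are calibrated.
synth_clinical_tables <- function() {
  list(
    p_hpv_negative = c(H = 0.03, LN = 0.1123),
    # per-flag probability given HPV positive: 16/18, high-risk
    # non-16/18, low-risk
    p_flags_given_positive = list(
      H = c(0.62, 0.75, 0.10),
      LN = c(0.264, 0.730, 0.118)),
    # NILM, ASCUS, ASC-H, LSIL, HSIL, AGC
    p_tct = list(
      H = c(0.10, 0.15, 0.14, 0.25, 0.30, 0.06),
      LN = c(0.5754, 0.2540, 0.0234, 0.1380, 0.0075, 0.0017))
  )
}

#' Sample one synthetic clinical record
#'
#' Age is uniform on 16..83. HPV status is drawn hierarchically: first
#' negative versus positive with a class-conditional rate, then — for
#' positives — the three genotype flags (16/18, high-risk non-16/18,
#' low-risk) as independent Bernoullis, redrawn if all come up zero
#' (multiple positives are permitted). The cytology (TCT) category is
#' drawn from a class-conditional categorical distribution. High-grade
#' records skew toward HPV 16/18 positivity and TCT ASC-H or worse.
#'
#' @param label `"H"` or `"LN"`.
#' @param seed Integer seed.
#' @param tables Class-conditional distributions (defaults to the
#'   calibrated tables of `synth_clinical_tables()`).
#' @return One-row data frame with the clinical fields (no paths).
#' @export
sample_clinical <- function(label, seed = 1, tables = synth_clinical_tables()) {
  stopifnot(label %in% c("H", "LN"))
  set.seed(seed)
  age <- sample(16:83, 1)
  flags <- c(0, 0, 0)
  if (stats::runif(1) >= tables$p_hpv_negative[[label]]) {
    p <- tables$p_flags_given_positive[[label]]
    repeat {
      flags <- as.numeric(stats::runif(3) < p)
      if (sum(flags) > 0) break
    }
  }
  tct <- sample(1:6, 1, prob = tables$p_tct[[label]])
  data.frame(age = age, hpv16_18 = flags[1], hpv_hr_non1618 = flags[2],
             hpv_lowrisk = flags[3], tct = tct)
}

# Physician diagnosis as a label-noise channel on the true binary label.
simulate_physician <- function(label, sensitivity, specificity) {
  u <- stats::runif(length(label))
  ifelse(label == "H",
         ifelse(u < sensitivity, "H", "LN"),
         ifelse(u < specificity, "LN", "H"))
}

#' Generate a full synthetic cohort
#'
#' Produces, per patient, a VIA and a VILI render, the disc bounding-box
#' annotations, a clinical record drawn from the class-conditional
#' distributions, a simulated physician call (a label-noise channel with
#' the configured sensitivity/specificity) and an examination month.
#' Months are assigned round-robin (1, 2, 3, 4, 1, ...) within each
#' pathology grade, so the temporal split retains about three quarters of
#' each grade for training. One master seed drives a per-patient sequence
#' of child seeds, so cohorts are byte-identical under the same seed and
#' individual cases are independently reproducible.
#'
#' @param config A [synthesis_config()].
#' @param seed Master integer seed.
#' @return A `colpo_cohort` list: `clinical` (data frame in the cohort
#'   schema, incl. derived `label`), `images` (named list per patient with
#'   `via`/`vili` arrays), `rois` (annotation data frame), `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = synthesis_config(), seed = 1) {
  stopifnot(inherits(config, "synthesis_config"))
  grades <- rep(pathology_levels, times = config$n_per_class[pathology_levels])
  n <- length(grades)
  set.seed(seed)
  child <- matrix(sample.int(.Machine$integer.max - 1L, n * 4L), n, 4)
  month <- unlist(lapply(config$n_per_class[pathology_levels], function(k) {
    rep_len(1:4, k)
  }), use.names = FALSE)
  ids <- sprintf("P%04d", seq_len(n))
  labels <- as.character(binary_label(grades))

  clin <- do.call(rbind, lapply(seq_len(n), function(i) {
    sample_clinical(labels[i], seed = child[i, 1])
  }))
  set.seed(seed + 1L)
  physician <- simulate_physician(labels, config$physician_sensitivity,
                                  config$physician_specificity)

  images <- vector("list", n)
  names(images) <- ids
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    via <- render_scene(labels[i], config, child[i, 2], "VIA")
    vili <- render_scene(labels[i], config, child[i, 3], "VILI")
    images[[i]] <- list(via = via$image, vili = vili$image)
    rois[[i]] <- data.frame(
      patient_id = ids[i], modality = c("VIA", "VILI"),
      x = c(via$roi$x, vili$roi$x), y = c(via$roi$y, vili$roi$y),
      width = c(via$roi$width, vili$roi$width),
      height = c(via$roi$height, vili$roi$height),
      source = "annotated")
  }

  clinical <- data.frame(patient_id = ids, clin,
                         pathology = grades, physician_call = physician,
                         exam_month = month,
                         via_path = sprintf("images/%s_VIA.png", ids),
                         vili_path = sprintf("images/%s_VILI.png", ids),
                         excl_blurred = 0L, excl_surgery = 0L,
                         excl_missing = 0L)
  clinical$label <- binary_label(clinical$pathology)
  structure(list(clinical = clinical, images = images,
                 rois = do.call(rbind, rois), config = config, seed = seed),
            class = "colpo_cohort")
}

#' @export
print.colpo_cohort <- function(x, ...) {
  tab <- table(x$clinical$label)
  cat(sprintf("<colpo_cohort> %d patients (H = %d, LN = %d), %d x %d px images\n",
              nrow(x$clinical), tab[["H"]], tab[["LN"]],
              x$config$image_size[1], x$config$image_size[2]))
  invisible(x)
}

#' Write a cohort directory
#'
#' Writes `clinical.csv` (cohort schema), `rois.csv` and one PNG per
#' image under `images/`.
#'
#' @param cohort A `colpo_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "colpo_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  clin <- cohort$clinical
  clin$label <- NULL  # derived, not stored
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  for (id in names(cohort$images)) {
    png::writePNG(cohort$images[[id]]$via / 255,
                  file.path(dir, sprintf("images/%s_VIA.png", id)))
    png::writePNG(cohort$images[[id]]$vili / 255,
                  file.path(dir, sprintf("images/%s_VILI.png", id)))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `clinical.csv`, `rois.csv` and
#'   `images/`.
#' @return A `colpo_cohort` (without the generator config).
#' @export
read_cohort <- function(dir) {
  clinical <- read_clinical_table(file.path(dir, "clinical.csv"))
  rois <- read_roi_table(file.path(dir, "rois.csv"))
  images <- lapply(seq_len(nrow(clinical)), function(i) {
    list(via = read_image(file.path(dir, clinical$via_path[i])),
         vili = read_image(file.path(dir, clinical$vili_path[i])))
  })
  names(images) <- clinical$patient_id
  structure(list(clinical = clinical, images = images, rois = rois,
                 config = NULL, seed = NULL),
            class = "colpo_cohort")
}

#' Read an RGB image file (PNG) as a 0-255 array
#'
#' @param path PNG file path.
#' @return Numeric array `h x w x 3` with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  round(img[, , 1:3, drop = FALSE] * 255)
}
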