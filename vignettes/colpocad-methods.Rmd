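---
title: "Methods: a two-stage multimodal pipeline for cervical dysplasia screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage multimodal pipeline for cervical dysplasia screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Colposcopy-guided biopsy is the reference procedure for grading cervical
intraepithelial neoplasia, but visual grading of cervigrams has limited
sensitivity for the lesions that matter most: high-grade disease (HSIL or
invasive cancer, the *H* group) versus low-grade or normal findings (LSIL
or normal, the *LN* group). `colpocad` implements a computer-aided
diagnosis pipeline that grades a patient from three inputs:

* a **VIA image** — the cervix photographed after acetic acid, where
  high-grade lesions turn acetowhite with mosaic micro-texture while
  normal epithelium stays light pink;
* a **VILI image** — the cervix after Lugol's iodine, where glycogen-rich
  normal epithelium stains dark brown and glycogen-deficient lesions stay
  pale yellow;
* a **clinical record** — age, three HPV genotype flags (16/18, high-risk
  non-16/18, low-risk; multiple positives allowed, all-zero meaning HPV
  negative), and the cytology (TCT) category on the six-level Bethesda
  scale.

The pathology of the colposcopy-guided biopsy is the ground truth, and
the binary H/LN mapping (`H` iff pathology is HSIL or cancer) lives in
one place, `binary_label()`, so every stage sees the same target.

## Pipeline

1. **ROI**. Each image is cropped to an axis-aligned cervix bounding box
   (left-bottom corner plus extent, y up). Boxes come from annotations;
   `detect_roi_heuristic()` is a colour-threshold stand-in for a learned
   segmenter, and predicted boxes are scored by `mismatch_loss()`
   (1 − intersection-over-union) with a review flag when the
   symmetric-difference deviation exceeds 10% of the truth area.
2. **Colour features (65)**. The crop is expanded into 13 channel planes
   — R, G, B; H, S, V; gray; CIELAB Ll/La/Lb; BT.601 Y/Cb/Cr — each
   rescaled to [0, 255], and summarised by mean, median, mode, standard
   deviation and Otsu threshold.
3. **Texture features (24)**. Gray-level co-occurrence matrices at pixel
   offsets 1, 5, 10 and 15 and angles 0°, 45°, 90°, 135° yield six
   Haralick descriptors per offset (ASM, contrast, correlation,
   dissimilarity, energy, homogeneity), averaged over the four angles.
   Per patient this gives 89 features per image, 178 across both
   modalities.
4. **Selection**. Welch t-tests between the H and LN training patients
   rank each modality's features by Benjamini–Hochberg-adjusted p-value;
   `grid_search_combination()` picks the (k_VIA, k_VILI) pair that
   maximises the mean macro-averaged F1 of the full downstream pipeline
   under repeated stratified cross-validation on the training split.
5. **Classification**. The selected features are z-scored with training
   statistics, the minority H class is rebalanced by SMOTE (k = 2
   nearest minority neighbours, convex interpolation until the classes
   match), and a radial-basis SVM with kernel `exp(-γ‖x − x′‖²)`,
   γ = 0.72, C = 0.12 produces a calibrated probability of H. A naive
   Bayes stage fuses six inputs — the SVM probability, age, the three
   HPV flags and the TCT code — into the final posterior; the call is H
   when the posterior reaches the 0.5 threshold (ties to H, favouring
   sensitivity).
6. **Evaluation**. Sensitivity, specificity, accuracy, the macro
   F1 `mean_i(2·Sen_i·Spec_i/(Sen_i+Spec_i))` — note it deliberately
   pairs per-class *sensitivity with specificity*, not precision with
   recall — AUPRC with a seeded bootstrap SD, and the model∨physician OR
   rule, which provably never lowers sensitivity and never raises
   specificity relative to either input.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.72 | RBF kernel width on z-scored features |
| `C` | 0.12 | SVM regularisation; small values favour a simple decision surface |
| `smote_k` | 2 | minority neighbours used for SMOTE interpolation |
| `k_via_grid`, `k_vili_grid` | 3, 5, 8 | candidate feature counts; the (5, 5) operating point is always in the default grid |
| `threshold` | 0.5 | posterior cut; ties are called H |
| `levels` | 64 | GLCM gray-level quantisation |

γ, C and the SMOTE neighbour count are treated as fixed operating
parameters of the method, not tuned by this package.

## The synthetic cohort generator

No public cervigram cohort with paired VIA/VILI images and pathology
exists, so `generate_cohort()` builds one that reproduces the *structure*
the pipeline relies on:

* a light-pink (VIA) or dark-brown (VILI) cervix disc on a dark
  background, with per-patient jitter of disc colour, radius and centre;
* for H cases, 1–3 lesion patches inside the disc: acetowhite
  checkerboard mosaic (period 4–12 px) for VIA, pale-yellow patches for
  VILI. The pale-yellow/brown pair is chosen with a large CIELAB-b gap so
  iodine-negative patches perturb the blue-yellow axis, and the mosaic
  whites straddle the pink's Cb value;
* **benign mottling in every image of both classes**: 1–3 patches of the
  same appearance at a random fraction (centred on `benign_strength`,
  default 0.35) of the lesion strength, emulating normal epithelium
  shades and metaplastic whitening. Without it the two classes differ in
  the mere presence of texture and any classifier is perfect; with it
  they overlap in degree, which is what makes the clinical problem hard.
  Setting `benign_strength = 0` and `noise_sd = 0` recovers the
  degenerate regime in which an LN disc interior is one constant colour;
* a 1:7 H:LN skew (default 20:140), clinical records whose pooled HPV/TCT
  marginals are calibrated (HPV negative ≈ 10.2%, cytology NILM ≈ 51.6%
  at the default skew) while the class-conditional split — H records
  skewed toward HPV 16/18 positivity and cytology ASC-H or worse — is a
  synthetic modelling choice with no measured counterpart;
* a simulated physician: a label-noise channel at sensitivity 0.537 and
  specificity 0.898, a realistic colposcopy operating point;
* months 1–4 assigned round-robin within each pathology grade, so the
  temporal split holds out about a quarter of each grade.

`lesion_contrast` (default 45) scales both the colour blend and the
mosaic amplitude of *all* patches, benign and malignant, and therefore
acts as a separability dial: near 0 the classes converge (feature AUC
→ 0.5) and large values drive the AUC toward 1. The default sits in the
middle so that the trained model is clearly imperfect, the SMOTE benefit
is visible, and the OR rule has room to help — the qualitative regime of
a real screening population.

What the generator does **not** emulate: specular glare, speculum and
instrument occlusion, illumination gradients, anatomy (os, columnar
epithelium), or any correlation between a patient's VIA and VILI lesion
geometry (the two renders are independent given the label). Passing
tests on synthetic cohorts therefore demonstrate that the machinery is
correct and directionally sensible, not that its headline numbers
transfer to real cervigrams.

## Numerical choices

* **Otsu threshold**: exhaustive scan of the 255 cuts of the 256-bin
  histogram, minimising the weighted within-class variance; when a run
  of cuts ties at the minimum (constant plane, well-separated modes) the
  midpoint of the run is returned so the threshold lands centrally in
  the histogram gap.
* **Mode**: most frequent 8-bit bin after rounding, ties to the smaller
  bin.
* **GLCM**: ordered pixel pairs (asymmetric matrix), normalised after
  counting; features — not matrices — are averaged over the four angles.
  Grayscale is quantised to 64 levels: 256-level matrices on ~100 px
  crops are sparse, slow, and noisier per cell.
* **GLCM correlation** with a zero marginal variance is defined as 1
  (constant texture is perfectly self-correlated), avoiding 0/0.
* **Colour conversion**: CIELAB via the sRGB/D65 transform; YCbCr via
  BT.601 in the digital 128-offset form; hue and saturation mapped from
  [0, 1] to [0, 255]; a/b axes shifted by +128.
* **Standardise-then-SMOTE**: interpolation happens in z-scored space so
  Euclidean neighbourhoods are commensurate across features.
* **SVM probabilities**: Platt-style calibration as provided by the SVM
  fit, seeded for reproducibility of its internal folds.
* **Naive Bayes families** follow the declared type of each input:
  Gaussian (SD floored at 1e-6) for the SVM probability and age;
  Bernoulli with a Jeffreys add-half estimate for the HPV flags;
  categorical with add-one smoothing over the six codes for TCT, so an
  unseen category keeps positive mass at prediction time.
* **Degenerate metrics**: a rate with an empty denominator is `NA` with
  a warning; a per-class 0/0 term of the macro F1 is 0; AUPRC of a
  constant score vector equals the prevalence (single PR point).
* **Heuristic detector**: Otsu on the chroma `max(RGB) − min(RGB)`
  (saturation scaled by value) rather than raw saturation, because
  saturation is numerically unstable on dark noisy pixels; 3×3 majority
  filtering, then the largest 4-connected component's bounding box, with
  a full-frame fallback.
* **Mismatch loss** is 1 − IoU; the review rule flags a symmetric
  difference strictly above 10% of the truth area. Both definitions are
  package conventions for quantities whose exact original form is a
  choice left open.

## Problem sizes

The test-suite cohorts use 55 patients at 112 × 112 px; the acceptance
script uses 320 patients (1:7 skew) at the default 160 × 160 px with the
3/5/8 feature-count grid and five repeated 5-fold cross-validations.
These sizes give stable qualitative behaviour — a disc of radius ~60 px
comfortably supports the 15-px co-occurrence offset and 4–12 px mosaic
periods — while keeping a full run on one CPU inside a coffee break.
With only ~9–10 H cases in a held-out month, per-run sensitivity moves
in steps of ~11 percentage points; the reported `n` makes that
granularity explicit.

## Known limitations

* The CNN segmenters that motivated the bounding-box data model are out
  of scope; the heuristic detector is only validated on synthetic discs.
* Real-data headline metrics cannot be reproduced here — the clinical
  cohort this class of model is built for is not public — so evaluation
  on synthetic cohorts is structural and directional by design.
* The naive Bayes stage inherits the usual conditional-independence
  inaccuracy of its posterior probabilities; the decision threshold, not
  the calibration, is the operative quantity.
* The paper-style macro F1 (sensitivity/specificity inside the harmonic
  mean) is nonstandard; comparisons with conventional macro-F1 values
  from other software are not meaningful.
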