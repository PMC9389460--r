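#' @keywords internal
"_PACKAGE"

clinical_columns <- c("patient_id", "age", "hpv16_18", "hpv_hr_non1618",
                      "hpv_lowrisk", "tct", "pathology", "physician_call",
                      "exam_month")
cohort_columns <- c(clinical_columns, "via_path", "vili_path",
                    "excl_blurred", "excl_surgery", "excl_missing")
pathology_levels <- c("normal", "LSIL", "HSIL", "cancer")

#' Binary diagnostic label from the pathology ground truth
#'
#' Maps the four-way pathology grade to the binary target used throughout
#' the pipeline: `H` (high-grade; HSIL or cancer, the cases needing
#' treatment) versus `LN` (low-grade or normal; LSIL or normal). This is
#' the single source of the H/LN labelling.
#'
#' @param pathology Character vector with values in
#'   `normal, LSIL, HSIL, cancer`.
#' @return Factor with levels `LN`, `H`.
#' @export
binary_label <- function(pathology) {
  bad <- setdiff(unique(pathology), pathology_levels)
  if (length(bad)) {
    stop("binary_label: unknown pathology value(s): ",
         paste(bad, collapse = ", "))
  }
  factor(ifelse(pathology %in% c("HSIL", "cancer"), "H", "LN"),
         levels = c("LN", "H"))
}

#' Read a cohort clinical table
#'
#' Reads the per-patient CSV (one row per patient) holding the clinical
#' record, image paths, exclusion flags and the examination month, and
#' validates the schema: all required columns present, `tct` in 1..6,
#' `pathology` one of normal/LSIL/HSIL/cancer, `physician_call` H or LN,
#' `exam_month` in 1..4, the three HPV flags 0/1. Malformed values are
#' reported with their row index. A derived `label` column (H/LN, from
#' pathology) is appended.
#'
#' @param path Path to a UTF-8 CSV file with header columns `patient_id`,
#'   `age`, `hpv16_18`, `hpv_hr_non1618`, `hpv_lowrisk`, `tct`,
#'   `pathology`, `physician_call`, `exam_month`, `via_path`, `vili_path`,
#'   `excl_blurred`, `excl_surgery`, `excl_missing`.
#' @param require_paths If `FALSE`, the image-path and exclusion columns
#'   may be absent (clinical-only tables).
#' @return A validated data frame, one row per patient.
#' @export
read_clinical_table <- function(path, require_paths = TRUE) {
  if (!file.exists(path)) stop("read_clinical_table: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- if (require_paths) cohort_columns else clinical_columns
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("read_clinical_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_clinical(df)
}

validate_clinical <- function(df) {
  check_rows <- function(ok, what) {
    if (!all(ok)) {
      stop("clinical table: invalid ", what, " in row(s) ",
           paste(which(!ok), collapse = ", "))
    }
  }
  check_rows(is.finite(df$age), "age")
  check_rows(df$tct %in% 1:6, "tct (must be 1..6)")
  check_rows(df$pathology %in% pathology_levels, "pathology")
  check_rows(df$physician_call %in% c("H", "LN"), "physician_call")
  check_rows(df$exam_month %in% 1:4, "exam_month")
  for (fl in c("hpv16_18", "hpv_hr_non1618", "hpv_lowrisk")) {
    check_rows(df[[fl]] %in% c(0, 1), fl)
  }
  if (any(df$age < 16 | df$age > 83)) {
    warning("clinical table: age outside the expected in-cohort range [16, 83]")
  }
  df$label <- binary_label(df$pathology)
  df
}

#' Apply the cohort exclusion filters
#'
#' Retains patients with no exclusion flag and tallies the excluded ones.
#' Each excluded patient is counted exactly once, under the first flag
#' that applies in the priority order blurred/obscured images, prior
#' cervical surgery, missing information — so a multi-flagged patient
#' appears in a single tally and `nrow(retained) + sum(tally)` always
#' equals the input size.
#'
#' @param cases Data frame with logical/0-1 columns `excl_blurred`,
#'   `excl_surgery`, `excl_missing` (as read by [read_clinical_table()]).
#' @return List with `retained` (data frame) and `tally` (named counts
#'   `blurred_or_obscured`, `prior_cervical_surgery`,
#'   `missing_information`).
#' @export
apply_exclusion_filters <- function(cases) {
  need <- c("excl_blurred", "excl_surgery", "excl_missing")
  stopifnot(all(need %in% names(cases)))
  b <- cases$excl_blurred > 0
  s <- cases$excl_surgery > 0
  m <- cases$excl_missing > 0
  tally <- c(blurred_or_obscured = sum(b),
             prior_cervical_surgery = sum(!b & s),
             missing_information = sum(!b & !s & m))
  list(retained = cases[!(b | s | m), , drop = FALSE], tally = tally)
}

#' Temporal train/test split
#'
#' Splits the cohort by examination month: months 1-3 form the training
#' set and month 4 the test set, emulating a prospective evaluation on
#' later patients. The two parts are disjoint and their union is the
#' input.
#'
#' @param cases Data frame with an `exam_month` column in 1..4.
#' @return List with data frames `train` and `test`.
#' @export
temporal_split <- function(cases) {
  if (!all(cases$exam_month %in% 1:4)) {
    stop("temporal_split: exam_month outside 1..4")
  }
  list(train = cases[cases$exam_month <= 3, , drop = FALSE],
       test = cases[cases$exam_month == 4, , drop = FALSE])
}

#' Encode the clinical covariates for the fusion stage
#'
#' Produces the ordered numeric encoding used by the naive Bayes stage
#' (after the SVM probability): age in years, the three HPV positivity
#' flags (16/18, high-risk non-16/18, low-risk; multiple flags may be 1,
#' all-zero means HPV negative) and the cytology (TCT) category code
#' 1 NILM, 2 ASCUS, 3 ASC-H, 4 LSIL, 5 HSIL, 6 AGC.
#'
#' @param record One-row data frame (or list) with the clinical fields.
#' @return Named numeric vector `c(age, hpv1, hpv2, hpv3, tct)`.
#' @export
encode_clinical_features <- function(record) {
  out <- c(age = as.numeric(record$age),
           hpv1 = as.numeric(record$hpv16_18),
           hpv2 = as.numeric(record$hpv_hr_non1618),
           hpv3 = as.numeric(record$hpv_lowrisk),
           tct = as.numeric(record$tct))
  stopifnot(length(out) == 5)
  out
}

# Matrix form of encode_clinical_features for a whole cohort.
encode_clinical_matrix <- function(cases) {
  m <- cbind(age = as.numeric(cases$age),
             hpv1 = as.numeric(cases$hpv16_18),
             hpv2 = as.numeric(cases$hpv_hr_non1618),
             hpv3 = as.numeric(cases$hpv_lowrisk),
             tct = as.numeric(cases$tct))
  rownames(m) <- cases$patient_id
  m
}

#' Read ROI annotations
#'
#' Reads the `rois.csv` companion table: one row per (patient, modality)
#' with the bottom-left-origin box geometry and its provenance
#' (`annotated`, `heuristic` or `corrected`).
#'
#' @param path CSV path with columns `patient_id`, `modality`, `x`, `y`,
#'   `width`, `height`, `source`.
#' @return Data frame of annotations.
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop("read_roi_table: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "modality", "x", "y", "width", "height", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("read_roi_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$modality %in% c("VIA", "VILI"))) {
    stop("read_roi_table: modality must be VIA or VILI")
  }
  if (any(df$width <= 0 | df$height <= 0)) {
    stop("read_roi_table: non-positive box extent")
  }
  df
}

roi_for <- function(rois, patient_id, modality) {
  r <- rois[rois$patient_id == patient_id & rois$modality == modality, ]
  if (nrow(r) == 0) return(NULL)
  roi_box(r$x[1], r$y[1], r$width[1], r$height[1])
}
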