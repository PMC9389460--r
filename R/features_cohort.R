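#' Extract the 178-feature table of a cohort
#'
#' Crops each patient's VIA and VILI image to its annotated cervix box
#' (or, when no annotation exists, to a heuristically detected one) and
#' extracts the 89 per-image descriptors, giving one row per patient with
#' `VIA_`- and `VILI_`-prefixed feature columns followed by the clinical
#' columns.
#'
#' @param cohort A `colpo_cohort` (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param use_roi Crop to the ROI before extraction (default `TRUE`);
#'   `FALSE` extracts from the full frame.
#' @param levels Gray-level count for the texture quantisation.
#' @return Data frame: `patient_id`, 89 `VIA_*` columns, 89 `VILI_*`
#'   columns, then the clinical columns including the binary `label`.
#' @export
extract_cohort_features <- function(cohort, use_roi = TRUE, levels = 64L) {
  stopifnot(inherits(cohort, "colpo_cohort"))
  clin <- cohort$clinical
  rows <- lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$patient_id[i]
    imgs <- cohort$images[[id]]
    one <- function(img, modality) {
      box <- roi_for(cohort$rois, id, modality)
      if (is.null(box)) box <- detect_roi_heuristic(img)
      f <- extract_image_features(crop_roi(img, box), levels = levels)
      names(f) <- paste0(modality, "_", names(f))
      f
    }
    c(one(imgs$via, "VIA"), one(imgs$vili, "VILI"))
  })
  feat <- as.data.frame(do.call(rbind, rows))
  if (any(!is.finite(as.matrix(feat)))) {
    stop("extract_cohort_features: non-finite feature value")
  }
  cbind(patient_id = clin$patient_id, feat,
        clin[, setdiff(names(clin), "patient_id"), drop = FALSE],
        row.names = NULL)
}

feature_columns <- function(df, modality = c("VIA", "VILI")) {
  modality <- match.arg(modality, several.ok = TRUE)
  unlist(lapply(modality, function(m) {
    grep(paste0("^", m, "_"), names(df), value = TRUE)
  }))
}
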