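#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(i, j)` such that gray level `j` occurs at
#' displacement `(d, theta)` from a pixel of gray level `i`, then
#' normalises the table to sum to 1. Angles follow the usual GLCM
#' convention with the y axis pointing up: 0 degrees pairs each pixel with
#' the pixel `d` columns to its right, 45 degrees up-right, 90 degrees up,
#' 135 degrees up-left. The matrix is kept asymmetric (ordered pairs);
#' directional symmetry is recovered later by averaging features over the
#' four angles. Input intensities in `[0, 255]` are quantised uniformly to
#' `levels` gray levels.
#'
#' @param gray Numeric matrix with values in `[0, 255]`.
#' @param d Positive integer pixel offset (the extractor uses 1, 5, 10, 15).
#' @param theta Angle in degrees: one of 0, 45, 90, 135.
#' @param levels Number of gray levels after quantisation.
#' @return A `glcm` object: list with the `levels x levels` matrix `P`
#'   (sums to 1), `d`, `theta` and `levels`.
#' @export
compute_glcm <- function(gray, d, theta, levels = 64L) {
  stopifnot(is.matrix(gray), d >= 1, levels >= 2)
  if (!theta %in% c(0, 45, 90, 135)) {
    stop("compute_glcm: theta must be one of 0, 45, 90, 135")
  }
  h <- nrow(gray); w <- ncol(gray)
  # displacement in (row, col) terms; image row 1 is the top, so "up" is -d
  shift <- switch(as.character(theta),
                  "0"   = c(0L, d),
                  "45"  = c(-d, d),
                  "90"  = c(-d, 0L),
                  "135" = c(-d, -d))
  if (abs(shift[1]) >= h || abs(shift[2]) >= w) {
    stop("compute_glcm: offset ", d, " at ", theta,
         " degrees exceeds the plane extent ", h, " x ", w)
  }
  q <- matrix(pmin(floor(pmin(pmax(gray, 0), 255) * levels / 256), levels - 1),
              h, w)
  rows <- seq_len(h - abs(shift[1]))
  cols <- seq_len(w - abs(shift[2]))
  r_ref <- if (shift[1] < 0) rows - shift[1] else rows
  c_ref <- if (shift[2] < 0) cols - shift[2] else cols
  ref <- q[r_ref, c_ref, drop = FALSE]
  tgt <- q[r_ref + shift[1], c_ref + shift[2], drop = FALSE]
  idx <- as.vector(ref) * levels + as.vector(tgt) + 1L
  P <- matrix(tabulate(idx, nbins = levels * levels),
              levels, levels, byrow = TRUE)
  P <- P / sum(P)
  structure(list(P = P, d = d, theta = theta, levels = levels),
            class = "glcm")
}

# The six Haralick descriptors of one normalised GLCM.
haralick_from_matrix <- function(P) {
  levels <- nrow(P)
  lev <- seq_len(levels) - 1
  i <- matrix(lev, levels, levels)
  j <- t(i)
  asm <- sum(P^2)
  contrast <- sum(P * (i - j)^2)
  dissimilarity <- sum(P * abs(i - j))
  homogeneity <- sum(P / (1 + (i - j)^2))
  mu_i <- sum(lev * rowSums(P))
  mu_j <- sum(lev * colSums(P))
  sd_i <- sqrt(sum((lev - mu_i)^2 * rowSums(P)))
  sd_j <- sqrt(sum((lev - mu_j)^2 * colSums(P)))
  correlation <- if (sd_i == 0 || sd_j == 0) {
    1  # constant texture: perfectly self-correlated, avoids 0/0
  } else {
    sum(P * (i - mu_i) * (j - mu_j)) / (sd_i * sd_j)
  }
  c(ASM = asm, Contrast = contrast, Correlation = correlation,
    Dissimilarity = dissimilarity, Energy = sqrt(asm),
    Homogeneity = homogeneity)
}

#' Angle-averaged Haralick features at one pixel offset
#'
#' Computes the six Haralick descriptors — angular second moment (ASM),
#' contrast, correlation, dissimilarity, energy and homogeneity — for each
#' of the four directional GLCMs of one offset, then arithmetic-averages
#' each feature over the angles (features are averaged, not the matrices).
#' Definitions: contrast `sum P (i-j)^2`, dissimilarity `sum P |i-j|`,
#' homogeneity `sum P / (1 + (i-j)^2)`, `ASM = sum P^2`,
#' `energy = sqrt(ASM)`, and the standard GLCM correlation
#' `sum P (i - mu_i)(j - mu_j) / (sd_i sd_j)`, defined as 1 when a
#' marginal variance is zero (a constant plane is perfectly
#' self-correlated).
#'
#' @param glcms List of `glcm` objects at a common offset (one per angle).
#' @return Named numeric vector of the 6 averaged features.
#' @export
haralick_features <- function(glcms) {
  stopifnot(length(glcms) >= 1,
            all(vapply(glcms, inherits, logical(1), "glcm")))
  feats <- vapply(glcms, function(g) haralick_from_matrix(g$P), numeric(6))
  rowMeans(feats)
}

#' Extract the 24 texture features of one cropped image
#'
#' Quantises the grayscale plane to `levels` gray levels and computes the
#' six angle-averaged Haralick features at pixel offsets 1, 5, 10 and 15,
#' giving 24 values named `ASM(1)`, `Contrast(1)`, ..., `Homogeneity(15)`
#' (the offset in parentheses).
#'
#' @param image Numeric array `h x w x 3`, values in `[0, 255]`; both
#'   dimensions must be at least 16 px so that the largest offset fits.
#' @param levels Gray-level count for quantisation (default 64).
#' @param offsets Pixel offsets (default `c(1, 5, 10, 15)`).
#' @return Named numeric vector of length `6 * length(offsets)`.
#' @export
extract_texture_features <- function(image, levels = 64L,
                                     offsets = c(1L, 5L, 10L, 15L)) {
  stopifnot(is.array(image), length(dim(image)) == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < max(offsets) + 1 || w < max(offsets) + 1) {
    stop("extract_texture_features: crop ", h, " x ", w,
         " is too small for offset ", max(offsets))
  }
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  out <- numeric(0)
  for (d in offsets) {
    glcms <- lapply(c(0, 45, 90, 135), function(th) {
      compute_glcm(gray, d, th, levels)
    })
    f <- haralick_features(glcms)
    names(f) <- sprintf("%s(%d)", names(f), d)
    out <- c(out, f)
  }
  out
}

#' Full 89-feature descriptor of one cropped image
#'
#' Concatenates the 65 colour features and 24 texture features in a fixed
#' order. Per patient, the VIA and VILI descriptors are concatenated with
#' `VIA_`/`VILI_` name prefixes to a 178-dimensional vector.
#'
#' @inheritParams extract_texture_features
#' @return Named numeric vector of length 89.
#' @export
extract_image_features <- function(image, levels = 64L) {
  c(extract_color_features(image),
    extract_texture_features(image, levels = levels))
}
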