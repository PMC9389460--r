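#' Channel planes used by the colour-feature extractor
#'
#' Converts an 8-bit RGB image into the 13 intensity planes that the
#' colour descriptors are computed on: R, G, B; hue, saturation, value
#' (HSV); grayscale luminance; CIELAB lightness Ll, green-red axis La and
#' blue-yellow axis Lb; and BT.601 luma Y with the offset chroma channels
#' Cb and Cr. Every plane is rescaled to `[0, 255]` so that the histogram
#' statistics (mode, Otsu threshold) operate on a common 256-bin scale:
#' hue and saturation are mapped from `[0, 1]`, CIELAB L from `[0, 100]`,
#' the a/b axes are shifted by +128, and Cb/Cr use the digital 128-offset
#' form. CIELAB uses the sRGB/D65 transform of [grDevices::convertColor()].
#'
#' @param image Numeric array `h x w x 3` with values in `[0, 255]`.
#' @return A named list of 13 matrices (class `channel_set`), in the fixed
#'   order R, G, B, H, S, V, Gray, Ll, La, Lb, Y, Cb, Cr.
#' @export
convert_color_spaces <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("convert_color_spaces: expected an h x w x 3 RGB array")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  plane <- function(v) matrix(v, h, w)
  clip255 <- function(m) pmin(pmax(m, 0), 255)

  hsv <- grDevices::rgb2hsv(r = as.vector(R), g = as.vector(G),
                            b = as.vector(B), maxColorValue = 255)
  lab <- grDevices::convertColor(cbind(as.vector(R), as.vector(G),
                                       as.vector(B)) / 255,
                                 from = "sRGB", to = "Lab")

  gray <- 0.299 * R + 0.587 * G + 0.114 * B
  structure(list(
    R = R, G = G, B = B,
    H = plane(hsv[1, ] * 255),
    S = plane(hsv[2, ] * 255),
    V = plane(hsv[3, ] * 255),
    Gray = gray,
    Ll = clip255(plane(lab[, 1] * 255 / 100)),
    La = clip255(plane(lab[, 2] + 128)),
    Lb = clip255(plane(lab[, 3] + 128)),
    Y = gray,
    Cb = clip255(128 - 0.168736 * R - 0.331264 * G + 0.5 * B),
    Cr = clip255(128 + 0.5 * R - 0.418688 * G - 0.081312 * B)
  ), class = "channel_set")
}

channel_set_names <- c("R", "G", "B", "H", "S", "V", "Gray",
                       "Ll", "La", "Lb", "Y", "Cb", "Cr")

#' Otsu threshold of an intensity plane
#'
#' Exhaustively scans the 255 candidate cuts `t = 0..254` of a 256-bin
#' histogram and returns the cut minimising the weighted within-class
#' variance of the split `value <= t` versus `value > t` (an empty class
#' contributes zero). When several cuts attain the minimum — e.g. for a
#' constant plane, where every cut is equivalent, or for well-separated
#' bimodal data, where any cut through the gap is optimal — the midpoint
#' of the minimising range is returned, so the threshold lands centrally
#' in the histogram gap.
#'
#' @param values Numeric vector or matrix of intensities in `[0, 255]`;
#'   rounded to integer bins.
#' @return Integer threshold in `0..254`.
#' @export
otsu_threshold <- function(values) {
  v <- as.vector(values)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("otsu_threshold: empty plane")
  counts <- tabulate(pmin(pmax(round(v), 0), 255) + 1L, nbins = 256L)
  n <- sum(counts)
  lev <- 0:255
  cw <- cumsum(counts)                 # class-0 size at cut t = lev
  cm <- cumsum(counts * lev)           # class-0 intensity sum
  cs <- cumsum(counts * lev^2)         # class-0 squared sum
  tot_m <- cm[256]; tot_s <- cs[256]
  t <- 0:254
  n0 <- cw[t + 1]; n1 <- n - n0
  s0 <- cs[t + 1] - ifelse(n0 > 0, cm[t + 1]^2 / n0, 0)
  s1 <- (tot_s - cs[t + 1]) - ifelse(n1 > 0, (tot_m - cm[t + 1])^2 / n1, 0)
  wcv <- (ifelse(n0 > 0, s0, 0) + ifelse(n1 > 0, s1, 0)) / n
  best <- which(wcv <= min(wcv) + 1e-9)
  t[floor((min(best) + max(best)) / 2)]
}

#' Five summary statistics of one intensity plane
#'
#' Computes the colour descriptors used per channel: mean, median, mode,
#' standard deviation and the Otsu threshold. The mode is the most
#' frequent 8-bit bin after rounding, with ties broken toward the smaller
#' bin; the standard deviation is the sample SD (0 for a single pixel).
#'
#' @param plane Numeric matrix or vector with values in `[0, 255]`.
#' @return Named numeric vector `c(mean, median, mode, std, otsu)`.
#' @export
channel_statistics <- function(plane) {
  v <- as.vector(plane)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("channel_statistics: empty plane")
  counts <- tabulate(pmin(pmax(round(v), 0), 255) + 1L, nbins = 256L)
  s <- if (length(v) > 1) stats::sd(v) else 0
  c(mean = mean(v),
    median = stats::median(v),
    mode = which.max(counts) - 1,   # ties -> smaller bin (first maximum)
    std = s,
    otsu = otsu_threshold(v))
}

#' Extract the 65 colour features of one cropped image
#'
#' 13 channel planes x 5 statistics, named `Mean(R)`, `Median(R)`,
#' `Mode(R)`, `Std(R)`, `Otsu(R)`, ... through `Otsu(Cr)`, in a fixed
#' documented order (channels R, G, B, H, S, V, Gray, Ll, La, Lb, Y, Cb,
#' Cr; the five statistics grouped within each channel).
#'
#' @param image Numeric array `h x w x 3`, values in `[0, 255]`.
#' @return Named numeric vector of length 65.
#' @export
extract_color_features <- function(image) {
  cs <- convert_color_spaces(image)
  out <- numeric(0)
  for (ch in channel_set_names) {
    st <- channel_statistics(cs[[ch]])
    names(st) <- sprintf("%s(%s)",
                         c("Mean", "Median", "Mode", "Std", "Otsu"), ch)
    out <- c(out, st)
  }
  out
}
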