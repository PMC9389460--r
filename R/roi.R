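#' Axis-aligned cervix region of interest
#'
#' An `roi_box` describes the rectangular cervix region of a colposcopic
#' image. The coordinate origin is the image's bottom-left corner, pixel
#' indices are 0-based, and the box covers the half-open pixel ranges
#' `[x, x + width)` horizontally and `[y, y + height)` vertically (y grows
#' upwards). This is the convention used for bounding-box annotations of
#' the cervix: the box is stored as its left-bottom corner plus extent.
#'
#' @param x,y Left and bottom pixel coordinate of the box (0-based).
#' @param width,height Box extent in pixels; both must be positive.
#' @return An object of class `roi_box`.
#' @examples
#' roi_box(10, 20, 100, 80)
#' @export
roi_box <- function(x, y, width, height) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(width), is.numeric(height))
  if (width <= 0 || height <= 0) {
    stop("roi_box: width and height must be positive (got ",
         width, " x ", height, ")")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height)),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> left-bottom (%g, %g), %g x %g px\n",
              x$x, x$y, x$width, x$height))
  invisible(x)
}

roi_area <- function(box) box$width * box$height

# Intersection area of two boxes under the half-open convention.
roi_intersection_area <- function(a, b) {
  w <- min(a$x + a$width, b$x + b$width) - max(a$x, b$x)
  h <- min(a$y + a$height, b$y + b$height) - max(a$y, b$y)
  if (w <= 0 || h <= 0) return(0)
  w * h
}

#' Bounding-box mismatch loss (1 - intersection over union)
#'
#' Scores a predicted cervix bounding box against ground truth as
#' `1 - IoU`: 0 for identical boxes, 1 for disjoint boxes, symmetric in its
#' arguments and bounded in `[0, 1]`.
#'
#' @param pred,truth `roi_box` objects.
#' @return Loss in `[0, 1]`.
#' @examples
#' mismatch_loss(roi_box(0, 0, 10, 10), roi_box(5, 0, 10, 10)) # 1 - 50/150
#' @export
mismatch_loss <- function(pred, truth) {
  stopifnot(inherits(pred, "roi_box"), inherits(truth, "roi_box"))
  if (roi_area(pred) <= 0 || roi_area(truth) <= 0) {
    stop("mismatch_loss: zero-area box")
  }
  inter <- roi_intersection_area(pred, truth)
  union <- roi_area(pred) + roi_area(truth) - inter
  1 - inter / union
}

#' Relative deviation of a predicted box from ground truth
#'
#' The symmetric-difference area of the two boxes divided by the truth
#' area. Predicted boxes deviating by more than `threshold` (default 10%)
#' are flagged for manual review, mirroring the manual double-check step
#' applied to automatically segmented cervigrams.
#'
#' @param pred,truth `roi_box` objects; `truth` must have positive area.
#' @param threshold Review threshold on the deviation fraction.
#' @return A list with `fraction` and logical `review` (raised when
#'   `fraction` strictly exceeds `threshold`).
#' @export
deviation_fraction <- function(pred, truth, threshold = 0.10) {
  stopifnot(inherits(pred, "roi_box"), inherits(truth, "roi_box"))
  at <- roi_area(truth)
  if (at <= 0) stop("deviation_fraction: zero-area truth box")
  inter <- roi_intersection_area(pred, truth)
  frac <- (roi_area(pred) + at - 2 * inter) / at
  list(fraction = frac, review = frac > threshold)
}

# Clip a box to [0, width) x [0, height) image bounds. Returns NULL when the
# box does not intersect the image.
clip_roi <- function(box, img_width, img_height) {
  x0 <- max(box$x, 0)
  y0 <- max(box$y, 0)
  x1 <- min(box$x + box$width, img_width)
  y1 <- min(box$y + box$height, img_height)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  roi_box(x0, y0, x1 - x0, y1 - y0)
}

#' Crop an image to a region of interest
#'
#' Copies the pixels covered by `box` (clipped to the image bounds) into a
#' new image; values are not transformed. Images are `height x width x 3`
#' arrays with the first row at the top of the picture, while `roi_box`
#' coordinates are measured from the bottom-left corner.
#'
#' @param image Numeric array `h x w x 3` with values in `[0, 255]`.
#' @param box An `roi_box`.
#' @return The cropped image array.
#' @export
crop_roi <- function(image, box) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3,
            inherits(box, "roi_box"))
  h <- dim(image)[1]; w <- dim(image)[2]
  cl <- clip_roi(box, w, h)
  if (is.null(cl)) stop("crop_roi: box lies fully outside the image")
  cols <- (cl$x + 1):(cl$x + cl$width)
  rows <- (h - cl$y - cl$height + 1):(h - cl$y)
  image[rows, cols, , drop = FALSE]
}

#' Heuristic cervix detector for synthetic cervigrams
#'
#' A colour-threshold stand-in for a learned cervix segmenter: the cervix
#' disc is assumed to be the dominant chromatic region on a dark, nearly
#' achromatic background. The detector thresholds the per-pixel chroma
#' (`max(R,G,B) - min(R,G,B)`, i.e. HSV saturation scaled by value, which
#' is robust to noisy saturation on dark pixels) with Otsu's criterion,
#' removes speckle with a 3x3 majority filter, and returns the bounding
#' rectangle of the largest 4-connected foreground component. If no
#' foreground survives, the full image frame is returned.
#'
#' @param image Numeric array `h x w x 3`, values in `[0, 255]`.
#' @return An `roi_box` within the image bounds.
#' @export
detect_roi_heuristic <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  full <- roi_box(0, 0, w, h)
  chroma <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
    pmin(image[, , 1], image[, , 2], image[, , 3])
  thr <- otsu_threshold(round(chroma))
  mask <- round(chroma) > thr
  if (!any(mask)) return(full)
  mask <- majority3x3(mask)
  if (!any(mask)) return(full)
  lab <- label_components(mask)
  best <- which.max(tabulate(lab[lab > 0L]))
  keep <- lab == best
  rows <- which(rowSums(keep) > 0)
  cols <- which(colSums(keep) > 0)
  # convert top-based row indices to bottom-origin y
  y0 <- h - max(rows)
  roi_box(min(cols) - 1, y0, max(cols) - min(cols) + 1,
          max(rows) - min(rows) + 1)
}

# 3x3 majority vote on a logical matrix (edges padded with FALSE).
majority3x3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0L, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- mask
  s <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    s <- s + p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  s >= 5L
}

# Two-pass 4-connected component labelling with union-find.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (c in seq_len(w)) for (r in seq_len(h)) {
    if (!mask[r, c]) next
    up <- if (r > 1 && mask[r - 1, c]) lab[r - 1, c] else 0L
    lf <- if (c > 1 && mask[r, c - 1]) lab[r, c - 1] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      parent[max(ru, rl)] <- min(ru, rl)
      lab[r, c] <- min(ru, rl)
    } else {
      lab[r, c] <- max(up, lf)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}
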