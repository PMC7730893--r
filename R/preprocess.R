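#' @title Background-cropping preprocessor
#' @description
#' The preprocessor converts a raw single-fruit photograph into a
#' background-free `100 x 100` crop through a fixed operator chain:
#' Gaussian smoothing (11 x 11 kernel), grayscale conversion, adaptive
#' thresholding, Laplacian filtering, Canny edge extraction, the minimal
#' bounding rectangle of the largest edge component, and a bilinear resize
#' of the cropped RGB region. Every step is deterministic: identical input
#' bytes give identical output bytes.
#' @name preprocess
NULL

# 1-d Gaussian kernel; sigma follows the usual 0.3*((k-1)/2 - 1) + 0.8 rule
gaussian_kernel1d <- function(k) {
  if (k == 1) return(1)
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  i <- seq_len(k) - (k + 1) / 2
  g <- exp(-i^2 / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian smoothing
#'
#' Channel-wise convolution with a normalized Gaussian kernel; borders are
#' handled by reflection, so constant images are preserved exactly.
#'
#' @param img `H x W x 3` 8-bit image array.
#' @param kernel_size Odd positive kernel width (default 11; sigma is
#'   derived as `0.3 * ((k - 1)/2 - 1) + 0.8`).
#' @return Smoothed image, same shape, 8-bit.
#' @export
gaussian_smooth <- function(img, kernel_size = 11) {
  assert_image(img)
  if (kernel_size < 1 || kernel_size %% 2 == 0) {
    stop("kernel_size must be a positive odd integer")
  }
  if (kernel_size == 1) return(img)
  g <- gaussian_kernel1d(kernel_size)
  out <- img
  for (ch in 1:3) {
    out[, , ch] <- clip8(.sep_filter_reflect(img[, , ch], g, g))
  }
  out
}

#' Grayscale conversion
#'
#' Standard luminance weighting `0.299 R + 0.587 G + 0.114 B`, rounded to
#' 8-bit.
#'
#' @param img `H x W x 3` image array.
#' @return `H x W` matrix of 8-bit intensities.
#' @export
to_grayscale <- function(img) {
  assert_image(img)
  clip8(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Adaptive (local-mean) binarization
#'
#' Each pixel is compared with the mean of its `block_size x block_size`
#' neighbourhood raised by `offset`: pixels strictly brighter than
#' `local_mean + offset` become foreground (255), all others background (0).
#' A constant image with a positive offset therefore yields an all-zero
#' mask, and `offset = -256` marks every pixel as foreground.
#'
#' @param gray `H x W` grayscale matrix.
#' @param block_size Odd neighbourhood width, at least 3 (default 101).
#' @param offset Scalar added to the local mean before comparison
#'   (default 5).
#' @return `H x W` matrix with values in `{0, 255}`.
#' @export
adaptive_binarize <- function(gray, block_size = 101, offset = 5) {
  if (!is.matrix(gray)) stop("expected a single-channel (matrix) image")
  if (block_size < 3 || block_size %% 2 == 0) {
    stop("block_size must be an odd integer >= 3")
  }
  box <- rep(1 / block_size, block_size)
  local_mean <- .sep_filter_reflect(gray, box, box)
  ifelse(gray > local_mean + offset, 255, 0) * 1 # keep matrix shape
}

#' Laplacian filter
#'
#' 3 x 3 Laplacian (4-neighbour stencil) with reflected borders. The
#' rectified negative lobe is returned: at a dark-to-bright step the
#' Laplacian is negative on the bright (interior) side, so this response
#' is a one-pixel ridge hugging the inside of the fruit boundary, which
#' localizes the subsequent Canny edge more sharply than the two-sided
#' absolute response.
#'
#' @param gray `H x W` grayscale matrix.
#' @return `H x W` matrix of 8-bit magnitudes.
#' @export
laplacian_filter <- function(gray) {
  if (!is.matrix(gray)) stop("expected a single-channel (matrix) image")
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  pmin(pmax(-.conv2d_reflect(gray, k), 0), 255)
}

#' Canny edge extraction
#'
#' Sobel gradients, non-maximum suppression along the quantized gradient
#' direction, and double-threshold hysteresis (weak edges are kept only
#' when 8-connected to a strong edge).
#'
#' @param gray `H x W` intensity matrix.
#' @param low,high Hysteresis thresholds on the gradient magnitude
#'   (defaults 50 and 150).
#' @return `H x W` 0/1 integer matrix of edge pixels.
#' @export
canny_edges <- function(gray, low = 50, high = 150) {
  if (!is.matrix(gray)) stop("expected a single-channel (matrix) image")
  if (low > high) stop("low threshold must not exceed high threshold")
  .canny_edges(gray, low, high)
}

#' Minimal bounding rectangle of the fruit
#'
#' Runs the full edge chain (Gaussian smoothing, grayscale, adaptive
#' threshold, Laplacian, Canny) and returns the axis-aligned minimal
#' bounding rectangle of the largest 8-connected edge component. Ties on
#' component size are broken by the smallest box x, then smallest y.
#'
#' @param img `H x W x 3` image array.
#' @param kernel_size Gaussian kernel width (default 11).
#' @param block_size,offset Adaptive-threshold parameters (defaults 101, 5).
#' @param canny_low,canny_high Canny hysteresis thresholds (defaults
#'   50, 150).
#' @return A list with 0-based, half-open box coordinates `x`, `y`, `w`,
#'   `h` (columns `[x, x + w)`, rows `[y, y + h)`).
#' @export
extract_fruit_box <- function(img, kernel_size = 11, block_size = 101,
                              offset = 5, canny_low = 50, canny_high = 150) {
  sm <- gaussian_smooth(img, kernel_size)
  gray <- to_grayscale(sm)
  mask <- adaptive_binarize(gray, block_size, offset)
  if (all(mask == 0)) {
    stop("no object found: adaptive threshold produced an empty mask")
  }
  lap <- laplacian_filter(mask)
  edges <- canny_edges(lap, canny_low, canny_high)
  if (all(edges == 0)) {
    stop("no object found: Canny produced an empty edge map")
  }
  labels <- .label_components(edges)
  sizes <- tabulate(labels[labels > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: smallest box x, then smallest y
    key <- vapply(best, function(l) {
      idx <- which(labels == l, arr.ind = TRUE)
      c(min(idx[, 2]), min(idx[, 1]))
    }, numeric(2))
    best <- best[order(key[1, ], key[2, ])]
  }
  idx <- which(labels == best[1], arr.ind = TRUE)
  x0 <- min(idx[, 2]) - 1L
  y0 <- min(idx[, 1]) - 1L
  list(x = x0, y = y0,
       w = max(idx[, 2]) - 1L - x0 + 1L,
       h = max(idx[, 1]) - 1L - y0 + 1L)
}

#' Crop a box and resize to a square output
#'
#' The box is cut from the original RGB image and stretched (bilinear
#' interpolation, aspect ratio not preserved) to `size x size`. A box that
#' already has the output size is returned pixel-identically.
#'
#' @param img `H x W x 3` image array.
#' @param box List with 0-based half-open fields `x`, `y`, `w`, `h`, as
#'   returned by [extract_fruit_box()].
#' @param size Output edge length in pixels (default 100).
#' @return `size x size x 3` 8-bit array.
#' @export
crop_resize <- function(img, box, size = 100) {
  assert_image(img)
  d <- dim(img)
  if (box$w < 1 || box$h < 1 || box$x < 0 || box$y < 0 ||
      box$x + box$w > d[2] || box$y + box$h > d[1]) {
    stop("bounding box lies outside the image")
  }
  crop <- img[box$y + seq_len(box$h), box$x + seq_len(box$w), , drop = FALSE]
  if (box$h == size && box$w == size) return(crop)
  out <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    out[, , ch] <- clip8(.bilinear_resize(crop[, , ch], size, size))
  }
  out
}

#' Full preprocessing chain
#'
#' Applies [extract_fruit_box()] followed by [crop_resize()] on the
#' original RGB pixels; the derived box (not the binarized image) drives
#' the crop.
#'
#' @inheritParams extract_fruit_box
#' @param size Output edge length (default 100).
#' @return `size x size x 3` array with the detected box attached as
#'   attribute `"box"`.
#' @export
preprocess_image <- function(img, size = 100, kernel_size = 11,
                             block_size = 101, offset = 5,
                             canny_low = 50, canny_high = 150) {
  box <- extract_fruit_box(img, kernel_size, block_size, offset,
                           canny_low, canny_high)
  out <- crop_resize(img, box, size)
  attr(out, "box") <- box
  out
}

#' Preprocess a directory tree of images
#'
#' Mirrors a directory-per-class input layout into an output directory of
#' processed PNGs.
#'
#' @param input Directory containing one subdirectory per class (or loose
#'   image files).
#' @param output Output directory (created if missing).
#' @param ... Passed to [preprocess_image()].
#' @return Tibble manifest with columns `input`, `output` and `status`
#'   (`"ok"` or the failure message).
#' @export
preprocess_dir <- function(input, output, ...) {
  files <- list.files(input, pattern = "\\.(png|jpg|jpeg)$",
                      recursive = TRUE, ignore.case = TRUE)
  if (length(files) == 0) stop("no images found under ", input)
  rows <- lapply(files, function(f) {
    dst <- file.path(output, sub("\\.(jpg|jpeg)$", ".png", f,
                                 ignore.case = TRUE))
    dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
    status <- tryCatch({
      img <- read_image(file.path(input, f))
      write_image(preprocess_image(img, ...), dst)
      "ok"
    }, error = function(e) conditionMessage(e))
    tibble::tibble(input = f, output = dst, status = status)
  })
  do.call(rbind, rows)
}
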