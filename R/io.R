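#' Read an RGB image into an 8-bit array
#'
#' PNG files are read with the \pkg{png} package; JPEG files require
#' \pkg{EBImage}. The result is an `H x W x 3` numeric array of integers in
#' `[0, 255]` (rows = image y, top to bottom).
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return `H x W x 3` array of 8-bit intensities.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package")
    }
    img <- EBImage::readImage(path)
    x <- aperm(EBImage::imageData(img), c(2, 1, 3)) # EBImage stores x first
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(x)) == 2) {
    x <- array(rep(x, 3), dim = c(dim(x), 3))
  }
  if (dim(x)[3] > 3) {
    x <- x[, , 1:3, drop = FALSE] # drop alpha
  }
  round(x * 255)
}

#' Write an 8-bit RGB array as PNG
#'
#' @param img `H x W x 3` array with values in `[0, 255]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

# shared validation: H x W x 3 array of finite values in [0, 255]
assert_image <- function(img, channels = 3) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[3] != channels) {
    stop("expected an H x W x ", channels, " image array")
  }
  if (d[1] < 1 || d[2] < 1) stop("image has empty extent")
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 255) {
    stop("image values must be finite and within [0, 255]")
  }
  invisible(img)
}

# round-half-up to the 8-bit range
clip8 <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}
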