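#' The tenfold augmentation scheme
#'
#' Expands one square image into exactly 10 variants: the original, its
#' rotations by 45, 90, ..., 315 degrees, a horizontal mirror, and the
#' mirror rotated by 45 degrees. Axis-aligned rotations (90/180/270) are
#' exact pixel permutations; the 45-degree family resamples with bilinear
#' interpolation and reflected padding so the output keeps the input size.
#'
#' @return Character vector of the 10 augmentation tags, in output order.
#' @export
augmentation_tags <- function() {
  c("orig", "rot45", "rot90", "rot135", "rot180", "rot225", "rot270",
    "rot315", "mirror", "mirror_rot45")
}

rot90_exact <- function(m) t(m)[ncol(m):1, , drop = FALSE] # 90 deg CCW

rotate_channelwise <- function(img, deg) {
  out <- img
  if (deg %% 90 == 0) {
    k <- (deg / 90) %% 4
    for (ch in 1:3) {
      m <- img[, , ch]
      for (i in seq_len(k)) m <- rot90_exact(m)
      out[, , ch] <- m
    }
  } else {
    for (ch in 1:3) {
      out[, , ch] <- clip8(.rotate_bilinear_reflect(img[, , ch], deg))
    }
  }
  out
}

mirror_horizontal <- function(img) img[, dim(img)[2]:1, , drop = FALSE]

#' Augment one processed image tenfold
#'
#' @param img Square `S x S x 3` 8-bit image (typically a 100 x 100
#'   processed crop).
#' @return Named list of 10 images in [augmentation_tags()] order; the
#'   first element is the input itself.
#' @export
augment_image <- function(img) {
  assert_image(img)
  d <- dim(img)
  if (d[1] != d[2]) stop("augmentation requires a square input image")
  out <- list(
    orig = img,
    rot45 = rotate_channelwise(img, 45),
    rot90 = rotate_channelwise(img, 90),
    rot135 = rotate_channelwise(img, 135),
    rot180 = rotate_channelwise(img, 180),
    rot225 = rotate_channelwise(img, 225),
    rot270 = rotate_channelwise(img, 270),
    rot315 = rotate_channelwise(img, 315),
    mirror = mirror_horizontal(img))
  out$mirror_rot45 <- rotate_channelwise(out$mirror, 45)
  out
}

#' Split original images into train and test per class
#'
#' The split happens on ORIGINAL images, before any augmentation, so no
#' augmented variant of a test original can leak into training. Within each
#' class the rows are shuffled with the given seed and the first
#' `round(ratio * n)` go to training (round half up). Explicit per-class
#' `train_counts` override the ratio, which allows reproducing published
#' splits that deviate slightly from exact 4:1.
#'
#' @param manifest Tibble/data frame with at least columns `source_id` and
#'   `label`.
#' @param ratio Training fraction (default 0.8, i.e. 4:1).
#' @param seed Integer seed for the per-class shuffle.
#' @param train_counts Optional named integer vector (class -> number of
#'   training originals).
#' @return The manifest with an added `split` column (`"train"`/`"test"`).
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = 1,
                          train_counts = NULL) {
  if (!all(c("source_id", "label") %in% names(manifest))) {
    stop("manifest needs columns source_id and label")
  }
  manifest$split <- NA_character_
  with_local_seed(as.integer(seed), {
    for (cls in unique(manifest$label)) {
      rows <- which(manifest$label == cls)
      n <- length(rows)
      if (n < 5) {
        warning("class ", cls, " has fewer than 5 originals; ",
                "split is degenerate")
      }
      n_train <- if (!is.null(train_counts) && cls %in% names(train_counts)) {
        as.integer(train_counts[[cls]])
      } else {
        floor(ratio * n + 0.5)
      }
      n_train <- min(max(n_train, 0L), n)
      perm <- sample(rows)
      manifest$split[perm[seq_len(n_train)]] <- "train"
      if (n_train < n) {
        manifest$split[perm[(n_train + 1):n]] <- "test"
      }
    }
  })
  tibble::as_tibble(manifest)
}

#' Augment a list of images after splitting
#'
#' Applies [augment_image()] to every image and returns the expanded image
#' list together with an expanded manifest carrying `source_id`,
#' `augmentation_tag` and any columns of the input manifest (such as
#' `label` and `split`). Augmentation multiplies every class count by
#' exactly 10 on both sides of the split.
#'
#' @param images List of square images, parallel to `manifest` rows.
#' @param manifest Tibble with one row per image (needs `source_id`).
#' @return List with elements `images` (length `10 * n`) and `manifest`.
#' @export
augment_set <- function(images, manifest) {
  if (length(images) != nrow(manifest)) {
    stop("images and manifest must be parallel")
  }
  tags <- augmentation_tags()
  out_images <- vector("list", length(images) * 10)
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    aug <- augment_image(images[[i]])
    out_images[(i - 1) * 10 + seq_len(10)] <- aug
    rep_row <- manifest[rep(i, 10), , drop = FALSE]
    rep_row$augmentation_tag <- tags
    rows[[i]] <- rep_row
  }
  list(images = out_images, manifest = do.call(rbind, rows))
}

#' Published per-class dataset counts
#'
#' The per-class counts of the reference study design this package
#' reproduces: 1240 originals split 4:1 into training and test originals
#' and expanded tenfold. The rot class uses a 310/80 split of its 390
#' originals (the published deviation from exact 4:1), exposed here as the
#' `train_counts` override for [split_dataset()].
#'
#' @return Tibble with columns `class`, `originals`, `train_originals`,
#'   `test_originals`, `train_augmented`, `test_augmented`.
#' @export
reference_split_counts <- function() {
  tb <- tibble::tibble(
    class = defect_classes(),
    originals = c(390L, 400L, 140L, 80L, 230L),
    train_originals = c(310L, 320L, 112L, 64L, 184L))
  tb$test_originals <- tb$originals - tb$train_originals
  tb$train_augmented <- tb$train_originals * 10L
  tb$test_augmented <- tb$test_originals * 10L
  tb
}
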