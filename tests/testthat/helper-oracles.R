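# Independent oracles and fixture builders shared across test files.

# brute-force 2-d convolution with edge-repeating reflected borders,
# independent of the package's separable C++ path
brute_conv_reflect <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  kh <- nrow(k); kw <- ncol(k)
  rh <- kh %/% 2; rw <- kw %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n - i + 1
    }
    i
  }
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    s <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      s <- s + k[i, j] * m[refl(y + i - 1 - rh, H), refl(x + j - 1 - rw, W)]
    }
    out[y, x] <- s
  }
  out
}

# brute-force local mean over a b x b window with reflected borders
brute_local_mean <- function(m, b) {
  brute_conv_reflect(m, matrix(1 / b^2, b, b))
}

# bright axis-aligned ellipse on black, with the analytic 0-based box over
# pixel centres
make_ellipse_image <- function(size, cx, cy, a, b, level = 200) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- level
    img[, , ch] <- plane
  }
  attr(img, "true_box") <- list(
    x = ceiling(cx - a) - 1, y = ceiling(cy - b) - 1,
    w = floor(cx + a) - ceiling(cx - a) + 1,
    h = floor(cy + b) - ceiling(cy - b) + 1)
  img
}

# session-level cache of generated plum batches so several tests can share
# one generation pass
.gen_cache <- new.env(parent = emptyenv())

cached_plums <- function(cls, n, seed = 101) {
  key <- paste(cls, n, seed, sep = "_")
  if (is.null(.gen_cache[[key]])) {
    cfg <- generator_config(seed = seed)
    .gen_cache[[key]] <- lapply(seq_len(n), function(i) {
      generate_plum_image(cls, cfg, i)
    })
  }
  .gen_cache[[key]]
}

random_unit_columns <- function(d, C) {
  W <- matrix(stats::rnorm(d * C), d, C)
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

# dark-component areas inside the (hole-filled) fruit mask, used to audit
# class morphology; mirrors the baseline classifier's conventions
max_dark_component <- function(img, background_level = 18) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  fruit <- lum > background_level + 25
  holes <- plumvision:::.label_components(ifelse(fruit, 0L, 1L))
  border_labels <- unique(c(holes[1, ], holes[nrow(holes), ],
                            holes[, 1], holes[, ncol(holes)]))
  fruit <- fruit | (holes > 0 & !(holes %in% border_labels))
  med <- stats::median(lum[fruit])
  dark <- fruit & lum < 0.7 * med
  if (!any(dark)) return(0)
  labels <- plumvision:::.label_components(ifelse(dark, 1L, 0L))
  max(tabulate(labels[labels > 0]))
}
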