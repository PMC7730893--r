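test_that("gaussian smoothing preserves constants and matches the brute-force kernel", {
  const <- array(128, dim = c(20, 20, 3))
  expect_identical(gaussian_smooth(const), const)
  expect_identical(gaussian_smooth(const, kernel_size = 1), const)

  # single impulse: smoothed image equals the (rounded) outer-product kernel
  imp <- array(0, dim = c(25, 25, 3))
  imp[13, 13, ] <- 255
  sm <- gaussian_smooth(imp, kernel_size = 11)
  g <- plumvision:::gaussian_kernel1d(11)
  expected <- pmin(pmax(floor(255 * outer(g, g) + 0.5), 0), 255)
  expect_equal(sm[8:18, 8:18, 1], expected, ignore_attr = TRUE)
  expect_equal(sm[, , 2], sm[, , 1])

  # agrees with an independent brute-force 2-d convolution near borders too
  set.seed(3)
  img <- array(sample(0:255, 15 * 15 * 3, replace = TRUE), dim = c(15, 15, 3))
  sm5 <- gaussian_smooth(img, kernel_size = 5)
  g5 <- plumvision:::gaussian_kernel1d(5)
  oracle <- pmin(pmax(floor(brute_conv_reflect(img[, , 1], outer(g5, g5)) + 0.5), 0), 255)
  expect_equal(sm5[, , 1], oracle)

  expect_error(gaussian_smooth(const, kernel_size = 4), "odd")
  expect_error(gaussian_smooth(const, kernel_size = -3), "odd")
})

test_that("grayscale conversion uses 0.299/0.587/0.114 luminance", {
  white <- array(255, dim = c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))
  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 255
  expect_true(all(to_grayscale(red) == 76))
  gray <- array(97, dim = c(3, 3, 3))
  expect_true(all(to_grayscale(gray) == 97))
  expect_error(to_grayscale(matrix(0, 4, 4)), "H x W x 3")
})

test_that("adaptive binarization thresholds against the raised local mean", {
  const <- matrix(120, 20, 20)
  expect_true(all(adaptive_binarize(const, 5, offset = 3) == 0))
  expect_true(all(adaptive_binarize(const, 5, offset = -256) == 255))

  # bright disk on dark field: agrees with a brute-force local-mean oracle
  set.seed(4)
  m <- matrix(10, 24, 24)
  xs <- matrix(rep(1:24, each = 24), 24, 24)
  ys <- matrix(rep(1:24, times = 24), 24, 24)
  m[(xs - 12)^2 + (ys - 12)^2 <= 36] <- 220
  got <- adaptive_binarize(m, block_size = 9, offset = 5)
  oracle <- ifelse(m > brute_local_mean(m, 9) + 5, 255, 0)
  expect_equal(got, oracle)

  expect_error(adaptive_binarize(m, block_size = 8), "odd")
})

test_that("fruit box extraction recovers analytic ellipse boxes and picks the larger blob", {
  img <- make_ellipse_image(120, cx = 60, cy = 55, a = 35, b = 28)
  tb <- attr(img, "true_box")
  bx <- extract_fruit_box(img)
  expect_lte(abs(bx$x - tb$x), 2)
  expect_lte(abs(bx$y - tb$y), 2)
  expect_lte(abs((bx$x + bx$w) - (tb$x + tb$w)), 2)
  expect_lte(abs((bx$y + bx$h) - (tb$y + tb$h)), 2)

  expect_error(extract_fruit_box(array(0, dim = c(64, 64, 3))), "no object")

  # two disjoint blobs: the one with the larger edge perimeter wins
  two <- array(0, dim = c(120, 120, 3))
  for (ch in 1:3) {
    pl <- two[, , ch]
    xs <- matrix(rep(1:120, each = 120), 120, 120)
    ys <- matrix(rep(1:120, times = 120), 120, 120)
    pl[(xs - 40)^2 + (ys - 40)^2 <= 28^2] <- 210 # big disk
    pl[(xs - 95)^2 + (ys - 95)^2 <= 10^2] <- 210 # small disk
    two[, , ch] <- pl
  }
  bx2 <- extract_fruit_box(two)
  expect_lt(bx2$x + bx2$w / 2, 60) # centred on the big disk
  expect_lt(bx2$y + bx2$h / 2, 60)
})

test_that("crop_resize is exact for identity crops and preserves means under downsampling", {
  set.seed(5)
  img <- array(sample(0:255, 300 * 300 * 3, replace = TRUE), dim = c(300, 300, 3))
  crop <- crop_resize(img, list(x = 20, y = 30, w = 100, h = 100))
  expect_identical(crop, img[31:130, 21:120, ])

  const <- array(77, dim = c(300, 300, 3))
  out <- crop_resize(const, list(x = 10, y = 10, w = 200, h = 200))
  expect_true(all(out == 77))

  checker <- array(0, dim = c(300, 300, 3))
  pat <- outer(1:200, 1:200, function(i, j) ((i + j) %% 2) * 255)
  for (ch in 1:3) checker[1:200, 1:200, ch] <- pat
  dn <- crop_resize(checker, list(x = 0, y = 0, w = 200, h = 200))
  expect_lt(abs(mean(dn) - mean(pat)), 1)

  expect_error(crop_resize(img, list(x = 250, y = 0, w = 100, h = 50)),
               "outside")
})

test_that("the preprocessing chain is deterministic and always yields 100 x 100 x 3", {
  img <- cached_plums("scar", 2)[[1]]
  p1 <- preprocess_image(img)
  p2 <- preprocess_image(img)
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(100L, 100L, 3L))

  big <- make_ellipse_image(300, 150, 140, 90, 70)
  expect_identical(dim(preprocess_image(big))[1:2], c(100L, 100L))
})
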