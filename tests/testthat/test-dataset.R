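test_that("severity-priority labelling picks the most severe defect", {
  expect_identical(assign_label(c("crack", "rot")), "rot")
  expect_identical(assign_label(character()), "normal")
  expect_identical(assign_label(c("spot", "scar")), "scar")
  expect_identical(assign_label("spot"), "spot")
  expect_identical(assign_label(c("spot", "crack", "scar")), "crack")
  expect_error(assign_label("bruise"), "unknown defect")
})

test_that("augmentation produces exactly 10 variants with the identity first", {
  img <- array(sample(0:255, 40 * 40 * 3, replace = TRUE), dim = c(40, 40, 3))
  aug <- augment_image(img)
  expect_length(aug, 10)
  expect_identical(names(aug), augmentation_tags())
  expect_identical(aug$orig, img)
  # axis-aligned rotations are exact permutations: four 90-degree turns
  # restore the input
  r <- img
  for (i in 1:4) r <- plumvision:::rotate_channelwise(r, 90)
  expect_identical(r, img)
  # a rotationally symmetric disk is invariant under the exact rotations
  xs <- matrix(rep(1:41, each = 41), 41, 41)
  ys <- matrix(rep(1:41, times = 41), 41, 41)
  disk <- array(0, dim = c(41, 41, 3))
  for (ch in 1:3) disk[, , ch] <- ifelse((xs - 21)^2 + (ys - 21)^2 <= 144, 200, 10)
  expect_identical(augment_image(disk)$rot90, disk)
  expect_identical(augment_image(disk)$rot180, disk)
  expect_error(augment_image(array(0, dim = c(30, 40, 3))), "square")
})

test_that("splitting is per class, leak-free, reproducible, and matches 4:1 arithmetic", {
  manifest <- tibble::tibble(
    source_id = c(sprintf("spot_%03d", 1:400), sprintf("crack_%03d", 1:80),
                  sprintf("normal_%03d", 1:5)),
    label = c(rep("spot", 400), rep("crack", 80), rep("normal", 5)))
  sp <- split_dataset(manifest, ratio = 0.8, seed = 9)
  counts <- table(sp$label, sp$split)
  expect_equal(unname(counts["spot", "train"]), 320)
  expect_equal(unname(counts["spot", "test"]), 80)
  expect_equal(unname(counts["crack", "train"]), 64)
  expect_equal(unname(counts["crack", "test"]), 16)
  expect_equal(unname(counts["normal", "train"]), 4)
  expect_equal(unname(counts["normal", "test"]), 1)

  # tenfold augmentation then multiplies both sides exactly
  expect_equal(320 * 10, 3200)
  expect_equal(80 * 10, 800)

  # no source appears on both sides
  expect_length(intersect(sp$source_id[sp$split == "train"],
                          sp$source_id[sp$split == "test"]), 0)
  # reproducible
  sp2 <- split_dataset(manifest, ratio = 0.8, seed = 9)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(manifest, ratio = 0.8, seed = 10)
  expect_false(identical(sp$split, sp3$split))

  small <- tibble::tibble(source_id = c("a", "b"), label = "rot")
  expect_warning(split_dataset(small, seed = 1), "fewer than 5")
})

test_that("augment_set expands images and manifest in lockstep", {
  imgs <- lapply(1:3, function(i) array(i * 10, dim = c(12, 12, 3)))
  man <- tibble::tibble(source_id = c("a", "b", "c"),
                        label = c("rot", "spot", "normal"))
  out <- augment_set(imgs, man)
  expect_length(out$images, 30)
  expect_equal(nrow(out$manifest), 30)
  expect_equal(sum(out$manifest$source_id == "b"), 10)
  expect_identical(out$manifest$augmentation_tag[1:10], augmentation_tags())
  expect_identical(out$images[[1]], imgs[[1]])
})

test_that("the published split table is internally consistent", {
  tb <- reference_split_counts()
  expect_equal(tb$train_originals + tb$test_originals, tb$originals)
  expect_equal(sum(tb$originals), 1240)
  expect_equal(tb$train_augmented, c(3100, 3200, 1120, 640, 1840))
  expect_equal(tb$test_augmented, c(800, 800, 280, 160, 460))
})
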