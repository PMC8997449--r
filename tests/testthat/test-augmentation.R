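make_img <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

test_that("trivial affine transforms are identities or involutions", {
  img <- make_img()
  expect_identical(apply_affine(img, "rotation", angle = 0), img)
  refl <- apply_affine(img, "reflection", axis = "horizontal")
  expect_identical(apply_affine(refl, "reflection", axis = "horizontal"), img)
  refl_v <- apply_affine(img, "reflection", axis = "vertical")
  expect_identical(apply_affine(refl_v, "reflection", axis = "vertical"), img)
  expect_identical(apply_affine(img, "shift", shift = c(0, 0)), img)
})

test_that("right-angle rotation is the exact index permutation", {
  img <- make_img(h = 5, w = 8, seed = 2)
  r90 <- apply_affine(img, "rotation", angle = 90)
  expect_identical(dim(r90), c(8L, 5L, 3L))
  # CCW: pixel (i, j) of the input lands at (W + 1 - j, i)
  for (i in c(1, 3, 5)) for (j in c(1, 4, 8)) for (ch in 1:3)
    expect_identical(r90[8 + 1 - j, i, ch], img[i, j, ch])
  # four quarter turns compose to the identity
  r360 <- Reduce(function(x, .) apply_affine(x, "rotation", angle = 90),
                 1:4, accumulate = FALSE, init = img)
  expect_identical(r360, img)
  expect_identical(apply_affine(img, "rotation", angle = 180),
                   img[5:1, 8:1, , drop = FALSE])
})

test_that("general-angle rotation preserves shape and a constant image", {
  img <- array(88, dim = c(16, 16, 3))
  out <- apply_affine(img, "rotation", angle = 33)
  expect_identical(dim(out), dim(img))
  expect_true(all(abs(out - 88) < 1e-9))
})

test_that("crop and shift follow their index semantics", {
  img <- make_img(h = 6, w = 6, seed = 3)
  cr <- apply_affine(img, "crop", box = c(2, 3, 4, 6))
  expect_identical(cr, img[2:4, 3:6, , drop = FALSE])
  expect_error(apply_affine(img, "crop", box = c(0, 1, 4, 4)), "inside")
  sh <- apply_affine(img, "shift", shift = c(2, -1))
  expect_identical(sh[3:6, 1:5, ], img[1:4, 2:6, ])
})

test_that("resize is exact at own size, constant-preserving, and block-averaging", {
  img <- make_img(h = 7, w = 9, seed = 4)
  same <- resize_for_backbone(img, c(7, 9))
  expect_lte(max(abs(same - img)), 1)

  const <- resize_for_backbone(array(123, dim = c(5, 5, 3)), c(11, 13))
  expect_identical(dim(const), c(11L, 13L, 3L))
  expect_true(all(abs(const - 123) < 1e-9))

  # 4x4 checkerboard downscaled to 2x2 gives the 2x2 block means
  cb <- array(0, dim = c(4, 4, 3))
  cb[, , 1] <- matrix(c(0, 255, 0, 255,
                        255, 0, 255, 0,
                        0, 255, 0, 255,
                        255, 0, 255, 0), 4, 4, byrow = TRUE)
  cb[, , 2] <- cb[, , 1]; cb[, , 3] <- cb[, , 1]
  small <- resize_for_backbone(cb, c(2, 2))
  for (ch in 1:3) for (i in 1:2) for (j in 1:2) {
    block <- cb[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
    expect_equal(small[i, j, ch], mean(block))
  }
})

test_that("class balancing tops every class up with transformed copies", {
  ds <- c(generate_dataset(4, classes = lesion_classes()[2], seed = 1,
                           height = 16, width = 16),
          generate_dataset(2, classes = lesion_classes()[10], seed = 2,
                           height = 16, width = 16))
  bal <- balance_classes(ds, seed = 5)
  labels <- vapply(bal, `[[`, character(1), "label")
  expect_true(all(table(labels) == 4))
  # originals all preserved, augmented additions flagged and not raw copies
  expect_identical(bal[seq_along(ds)], ds)
  added <- bal[-seq_along(ds)]
  expect_true(all(vapply(added, function(s) isTRUE(s$augmented), logical(1))))
  for (s in added) {
    dup <- any(vapply(ds, function(o)
      identical(o$image, s$image), logical(1)))
    expect_false(dup)
  }
  # already balanced input keeps its cardinality; determinism under the seed
  expect_length(balance_classes(bal, seed = 1), length(bal))
  expect_identical(balance_classes(ds, seed = 5), bal)
})

test_that("train/val split is a stratified partition", {
  ds <- c(generate_dataset(10, classes = lesion_classes()[1], seed = 1,
                           height = 8, width = 8),
          generate_dataset(20, classes = lesion_classes()[2], seed = 2,
                           height = 8, width = 8))
  sp <- split_train_val(ds, seed = 3)
  labels_tr <- vapply(sp$train, `[[`, character(1), "label")
  labels_va <- vapply(sp$val, `[[`, character(1), "label")
  expect_identical(sum(labels_tr == lesion_classes()[1]), 8L)
  expect_identical(sum(labels_tr == lesion_classes()[2]), 16L)
  expect_length(sp$val, 6L)
  # disjoint and exhaustive
  key <- function(s) paste(s$label, paste(s$metadata, collapse = "|"),
                           sum(s$image), mean(s$image))
  all_keys <- sort(c(vapply(sp$train, key, ""), vapply(sp$val, key, "")))
  expect_identical(all_keys, sort(vapply(ds, key, "")))

  one <- generate_dataset(10, classes = lesion_classes()[5], seed = 4,
                          height = 8, width = 8)
  sp1 <- split_train_val(one, seed = 1)
  expect_length(sp1$train, 8L)
  expect_length(sp1$val, 2L)
  expect_error(split_train_val(one[1], seed = 1), ">= 2 samples")
  expect_error(split_train_val(one, train_fraction = 1), "strictly between")
})
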