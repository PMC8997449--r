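test_that("structuring element footprint equals brute-force membership", {
  for (r in 1:3) {
    se <- structuring_element(r)
    offs <- expand.grid(dx = -r:r, dy = -r:r)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
    got <- se$offsets[order(se$offsets[, 1], se$offsets[, 2]), ]
    want <- as.matrix(offs[order(offs$dx, offs$dy), ])
    dimnames(got) <- dimnames(want) <- NULL
    expect_identical(got, want)
    # symmetric under negation, contains the origin
    expect_true(any(se$offsets[, 1] == 0 & se$offsets[, 2] == 0))
    neg <- -se$offsets
    expect_identical(nrow(merge(as.data.frame(se$offsets), as.data.frame(neg))),
                     nrow(se$offsets))
  }
  expect_error(structuring_element(0), ">= 1")
})

test_that("channel split/merge is an exact round trip", {
  img <- array(rep(c(10, 20, 30), each = 4), dim = c(2, 2, 3))
  pl <- split_channels(img)
  expect_true(all(pl$R == 10) && all(pl$G == 20) && all(pl$B == 30))
  expect_identical(merge_channels(pl), img)

  rimg <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  expect_identical(split_channels(rimg)$R, rimg[, , 1])
  expect_identical(merge_channels(split_channels(rimg)), rimg)
  expect_error(split_channels(matrix(0, 4, 4)), "H x W x 3")
})

test_that("closing fills a dark pit and matches the footprint oracle", {
  p <- matrix(200, 5, 5); p[3, 3] <- 50
  expect_true(all(morph_close(p, structuring_element(1)) == 200))
  # constant plane is a fixed point
  k <- matrix(77, 6, 6)
  expect_identical(morph_close(k, structuring_element(2)), k)
})

test_that("morphology equals the exhaustive per-pixel oracle", {
  set.seed(101)
  for (rep in 1:25) for (r in 1:3) {
    p <- random_plane(9, 9)
    se <- structuring_element(r)
    expect_identical(morph_dilate(p, se), oracle_morph(p, r, "dilate"))
    expect_identical(morph_erode(p, se), oracle_morph(p, r, "erode"))
    expect_identical(morph_close(p, se), oracle_close(p, r))
  }
})

test_that("closing is extensive and idempotent", {
  set.seed(202)
  se <- structuring_element(2)
  for (rep in 1:50) {
    p <- random_plane(9, 9)
    cl <- morph_close(p, se)
    expect_true(all(cl >= p))
    expect_identical(morph_close(cl, se), cl)
  }
})

test_that("subtraction follows the closing residual definition", {
  p <- matrix(200, 4, 4)
  expect_true(all(subtract_planes(p, p) == 0))
  q <- p; q[2, 2] <- 50
  d <- subtract_planes(p, q)
  expect_identical(d[2, 2], 150)
  expect_identical(sum(d), 150)
  expect_error(subtract_planes(p, matrix(0, 3, 3)), "shape")
  set.seed(3)
  se <- structuring_element(1)
  for (rep in 1:20) {
    r <- random_plane(8, 8)
    expect_true(all(subtract_planes(morph_close(r, se), r) >= 0))
  }
})

test_that("threshold zeroing keeps strictly-greater values only", {
  p <- matrix(c(0, 40, 41, 150), 2, 2)
  out <- threshold_zero(p, 40)
  expect_identical(as.numeric(out), c(0, 0, 41, 150))
  # value exactly K falls in the <= K branch
  expect_identical(threshold_zero(matrix(40, 1, 1), 40)[1, 1], 0)
  # idempotent
  expect_identical(threshold_zero(out, 40), out)
  expect_true(all(threshold_zero(matrix(0:40, 41, 1), 40) == 0))
})

test_that("dilation expands support per the oracle and mask is the support", {
  z <- matrix(0, 5, 5)
  se <- structuring_element(1)
  expect_identical(morph_dilate(z, se), z)

  p <- z; p[3, 3] <- 150
  d <- morph_dilate(p, se)
  cross <- z; cross[3, 2:4] <- 150; cross[2:4, 3] <- 150
  expect_identical(d, cross)
  m <- extract_mask(d)
  expect_identical(sum(m), 5L)
  expect_identical(m, d > 0)
  expect_false(any(extract_mask(z)))
})

test_that("detection is monotone in K and r2", {
  img <- generate_lesion_image(lesion_image_spec(height = 64, width = 64, seed = 11))
  ov <- overlay_hair(img, hair_overlay_spec(n_strokes = 3, seed = 12))
  mask_for <- function(K, r2) {
    remove_hair(ov$image, hair_removal_config(threshold = K, r2 = r2))$merged_mask
  }
  m40 <- mask_for(40, 3)
  expect_true(all(m40[mask_for(80, 3)]))   # raising K never grows the mask
  expect_true(all(m40[mask_for(40, 2)]))   # lowering r2 never grows it
})

test_that("inpainting is exact outside the mask and harmonic inside", {
  p <- matrix(200, 9, 9)
  mask <- matrix(FALSE, 9, 9)
  expect_identical(inpaint_laplace(p, mask), p)  # empty mask: bit-exact

  mask[5, 4:6] <- TRUE; mask[4:6, 5] <- TRUE     # plus-shaped hole
  noisy <- p; noisy[mask] <- 0
  out <- inpaint_laplace(noisy, mask)
  expect_identical(out[!mask], noisy[!mask])
  expect_true(all(abs(out[mask] - 200) < 1e-6))  # constant boundary -> constant

  expect_error(inpaint_laplace(p, !logical(81) & matrix(TRUE, 9, 9)),
               "entire image")
})

test_that("inpainting recovers a linear ramp through a masked column", {
  ramp <- matrix(rep(seq(10, 150, length.out = 15), each = 15), 15, 15)
  mask <- matrix(FALSE, 15, 15); mask[, 8] <- TRUE
  out <- inpaint_laplace(ramp, mask)
  # harmonic extension of a linear field is the field itself
  expect_lt(max(abs(out[, 8] - ramp[, 8])), 0.5)
  expect_identical(out[!mask], ramp[!mask])
})

test_that("a near-total mask still solves from a single boundary pixel", {
  p <- matrix(100, 5, 5)
  mask <- matrix(TRUE, 5, 5); mask[1, 1] <- FALSE
  p[mask] <- 0; p[1, 1] <- 7
  out <- inpaint_laplace(p, mask)
  expect_identical(out[1, 1], 7)            # the lone Dirichlet pixel is kept
  expect_true(all(abs(out - 7) < 1e-6))     # harmonic fill of one value
})

test_that("remove_hair is a no-op on constant images", {
  img <- array(137, dim = c(32, 32, 3))
  res <- remove_hair(img)
  expect_identical(res$image, img)
  expect_false(any(res$merged_mask))
  expect_false(any(res$masks$R | res$masks$G | res$masks$B))
})

test_that("remove_hair detects synthetic strokes and improves the image", {
  spec <- lesion_image_spec(seed = 21)
  clean <- generate_lesion_image(spec)
  ov <- overlay_hair(clean, hair_overlay_spec(n_strokes = 5,
                                              stroke_width_range = c(1, 3),
                                              stroke_darkness = 120, seed = 22))
  res <- remove_hair(ov$image, keep_intermediates = TRUE)
  recall <- mean(res$merged_mask[ov$mask])
  expect_gte(recall, 0.95)
  mae_clean <- mean(abs(res$image[rep(ov$mask, 3)] - clean[rep(ov$mask, 3)]))
  mae_hairy <- mean(abs(ov$image[rep(ov$mask, 3)] - clean[rep(ov$mask, 3)]))
  expect_lt(mae_clean, mae_hairy)
  # pixels outside the merged mask pass through untouched
  outside <- !res$merged_mask
  expect_identical(res$image[rep(outside, 3)], ov$image[rep(outside, 3)])
  # intermediates satisfy the stage invariants
  ir <- res$intermediates$R
  expect_true(all(ir$difference >= 0))
  expect_true(all(ir$thresholded <= ir$difference))
  expect_true(all(res$masks$R[ir$thresholded > 0]))
})
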