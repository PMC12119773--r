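test_that("pseudo-planar projection sums along the AP axis and conserves
           counts", {
  v <- ActivityVolume(array(1, c(3, 3, 3)))
  img <- projectVolume(v)
  expect_equal(pixels(img), matrix(3, 3, 3))
  expect_equal(sum(pixels(img)), sum(voxels(v)))
  expect_identical(viewTag(img), "pseudo")

  one <- array(0, c(5, 6, 7)); one[2, 3, 4] <- 2.5
  p <- pixels(projectVolume(ActivityVolume(one)))
  expect_equal(sum(p > 0), 1L)
  expect_equal(p[2, 3], 2.5)

  set.seed(4)
  r <- array(runif(24 * 20 * 16), c(24, 20, 16))
  pv <- projectVolume(ActivityVolume(r))
  expect_equal(sum(pixels(pv)), sum(r), tolerance = 1e-12)
  # direct-summation oracle, pixel by pixel
  oracle <- matrix(0, 24, 20)
  for (i in 1:24) for (j in 1:20) oracle[i, j] <- sum(r[i, j, ])
  expect_equal(pixels(pv), oracle, tolerance = 1e-12)
})

test_that("projection requires a declared AP axis and respects it", {
  v <- ActivityVolume(array(1, c(4, 4, 4)), apAxis = NA)
  expect_error(projectVolume(v), "anterior-posterior")
  v1 <- ActivityVolume(array(seq_len(8), c(2, 2, 2)), apAxis = 1L)
  expect_equal(dim(pixels(projectVolume(v1))), c(2L, 2L))
  expect_equal(sum(pixels(projectVolume(v1))), sum(seq_len(8)))
})

test_that("mask projection is a per-ray logical OR", {
  empty <- LabelMask(array(0, c(4, 4, 4)), "lv")
  expect_equal(sum(maskData(projectMask(empty))), 0)
  full <- LabelMask(array(1, c(4, 4, 4)), "lv")
  expect_equal(sum(maskData(projectMask(full))), 16)

  set.seed(9)
  m <- array(rbinom(6 * 5 * 4, 1, 0.1), c(6, 5, 4))
  pm <- maskData(projectMask(LabelMask(m, "ribcage")))
  oracle <- matrix(0, 6, 5)
  for (i in 1:6) for (j in 1:5) oracle[i, j] <- as.numeric(any(m[i, j, ] == 1))
  expect_equal(pm, oracle)

  # non-binary data is rejected at the container level already
  bad <- array(0.5, c(3, 3, 3))
  expect_error(new("LabelMask", data = bad, structure = "lv",
                   spacingMm = rep(2.8, 3)), "0 or 1")
})

test_that("projected mask equals thresholded projected volume", {
  set.seed(11)
  m <- array(rbinom(8 * 8 * 8, 1, 0.2), c(8, 8, 8))
  as_mask <- maskData(projectMask(LabelMask(m, "lv")))
  as_counts <- (pixels(projectVolume(ActivityVolume(m))) > 0) * 1
  expect_equal(as_mask, as_counts)
})

test_that("mask dilation uses a physical-radius ball and is monotone", {
  m <- array(0, c(9, 9, 9)); m[5, 5, 5] <- 1
  lm <- LabelMask(m, "lv", 2.8)
  expect_identical(maskData(dilateMask(lm, 0)), maskData(lm))
  # 2 mm at 2.8 mm spacing -> 1-voxel-radius neighborhood (6-connectivity)
  d <- maskData(dilateMask(lm, 2))
  expect_equal(sum(d), 7)
  expect_equal(d[4, 5, 5] + d[6, 5, 5] + d[5, 4, 5] + d[5, 6, 5] +
                 d[5, 5, 4] + d[5, 5, 6] + d[5, 5, 5], 7)
  expect_error(dilateMask(lm, -1), ">= 0")

  set.seed(21)
  r <- array(rbinom(10^3, 1, 0.1), c(10, 10, 10))
  rm_ <- LabelMask(r, "ribcage", 2.8)
  dil <- maskData(dilateMask(rm_, 3))
  expect_true(all(dil[r == 1] == 1))
  expect_gte(sum(dil), sum(r))

  # 2D disk dilation
  m2 <- rect_mask(7, 7, 4, 4)
  d2 <- maskData(dilateMask(m2, 2))
  expect_equal(sum(d2), 5)
})

test_that("resampling preserves physical extent and interpolation rules", {
  img <- rand_image(10, 12, seed = 5)
  expect_identical(pixels(resamplePlanar(img, c(2.8, 2.8))), pixels(img))
  expect_error(resamplePlanar(img, 0), "positive")

  cst <- PlanarImage(matrix(4, 8, 8), spacingMm = 1)
  out <- resamplePlanar(cst, 2)
  expect_equal(dim(pixels(out)), c(4L, 4L))
  expect_true(all(abs(pixels(out) - 4) < 1e-12))

  # linear ramp along columns, 2x downsample: doubled per-pixel step
  ramp <- PlanarImage(matrix(rep(1:16, each = 4), 4, 16), spacingMm = 1)
  down <- resamplePlanar(ramp, c(1, 2), "linear")
  vals <- pixels(down)[1, ]
  # output center j at physical (j - 0.5) * 2 -> source index (j - 0.5)*2 + 0.5
  expected <- pmin(pmax((seq_len(8) - 0.5) * 2 + 0.5, 1), 16)
  expect_equal(vals, expected, tolerance = 1e-9)
  expect_equal(diff(vals[2:7]), rep(2, 5), tolerance = 1e-9)

  # nearest keeps masks binary
  mk <- PlanarImage(matrix(rbinom(64, 1, 0.4), 8, 8), spacingMm = 1)
  near <- resamplePlanar(mk, 0.5, "nearest")
  expect_true(all(pixels(near) %in% c(0, 1)))
  expect_equal(dim(pixels(near)), c(16L, 16L))
})
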