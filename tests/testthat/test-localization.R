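test_that("mask bounding boxes are tight and half-open", {
  m <- rect_mask(10, 12, 6, 8, "lv")
  b <- maskBbox(m)
  expect_equal(unname(regionBounds(b)), c(5L, 6L, 7L, 8L))
  full <- rect_mask(10, 12, 1:10, 1:12, "whole_heart")
  expect_equal(unname(regionBounds(maskBbox(full))), c(0L, 10L, 0L, 12L))

  set.seed(5)
  r <- matrix(rbinom(20 * 18, 1, 0.05), 20, 18)
  r[3, 4] <- 1
  rb <- regionBounds(maskBbox(LabelMask(r, "ribcage")))
  idx <- which(r == 1, arr.ind = TRUE)
  expect_equal(unname(rb), c(min(idx[, 1]) - 1L, max(idx[, 1]),
                             min(idx[, 2]) - 1L, max(idx[, 2])))
})

test_that("an empty mask signals a catchable emptyMaskError", {
  e <- rect_mask(6, 6, integer(0), 1, "lv")
  expect_error(maskBbox(e), class = "emptyMaskError")
  caught <- tryCatch(maskBbox(e), emptyMaskError = function(cond) "fallback")
  expect_identical(caught, "fallback")
})

test_that("physical margins convert to pixels by rounding", {
  img <- PlanarImage(matrix(runif(120 * 120), 120), spacingMm = 2.8)
  box <- CropRegion(50L, 60L, 50L, 60L, "lv")
  res <- cropWithMargin(img, box, 70)
  # 70 mm / 2.8 mm = 25 px each side
  expect_equal(unname(regionBounds(res$region)),
               c(50L - 25L, 60L + 25L, 50L - 25L, 60L + 25L))
  expect_equal(dim(pixels(res$image)), c(60L, 60L))

  res0 <- cropWithMargin(img, box, 0)
  expect_equal(dim(pixels(res0$image)), c(10L, 10L))
  expect_equal(pixels(res0$image), pixels(img)[51:60, 51:60])

  # clamped at the corner
  corner <- CropRegion(0L, 5L, 0L, 5L, "whole_heart")
  resc <- cropWithMargin(img, corner, 70)
  expect_equal(unname(regionBounds(resc$region)), c(0L, 30L, 0L, 30L))
})

test_that("localizeAll produces three strategy crops containing the
           heart", {
  coh <- cohort_fixture("segtrain", 10, c(1, 0, 0, 0), seed = 11, grid = 48L)
  cs <- coh[[1]]
  img <- caseImages(cs)$anterior
  crops <- localizeAll(img, caseMasks(cs))
  expect_named(crops, c("lv", "whole_heart", "ribcage"))
  heart_box <- regionBounds(maskBbox(caseMasks(cs)$whole_heart))
  for (s in c("lv", "whole_heart")) {
    rb <- regionBounds(crops[[s]]$region)
    expect_lte(rb["rowMin"], heart_box["rowMin"])
    expect_gte(rb["rowMax"], heart_box["rowMax"])
    expect_lte(rb["colMin"], heart_box["colMin"])
    expect_gte(rb["colMax"], heart_box["colMax"])
  }
  # containment: each crop contains its driving mask's bbox
  for (s in names(crops)) {
    mb <- regionBounds(maskBbox(caseMasks(cs)[[s]]))
    rb <- regionBounds(crops[[s]]$region)
    expect_true(rb["rowMin"] <= mb["rowMin"] && rb["rowMax"] >= mb["rowMax"])
  }
})

test_that("empty masks fall back to the thorax band or the full image", {
  img <- rand_image(40, 40)
  masks <- list(lv = rect_mask(40, 40, integer(0), 1, "lv"),
                whole_heart = rect_mask(40, 40, 10:20, 10:20, "whole_heart"),
                ribcage = rect_mask(40, 40, 5:35, 5:35, "ribcage"))
  expect_warning(crops <- localizeAll(img, masks), "fallback")
  expect_named(crops, c("lv", "whole_heart", "ribcage"))
  # the fallback lv crop is the margin-expanded central band
  expect_equal(dim(pixels(crops$lv$image))[1], 40L)

  empty <- lapply(masks, function(m) {
    LabelMask(matrix(0, 40, 40), structureName(m))
  })
  expect_warning(crops2 <- localizeAll(img, empty), "full image")
  for (s in names(crops2)) {
    expect_equal(dim(pixels(crops2[[s]]$image)), c(40L, 40L))
  }
})

test_that("full-image masks yield clamped full-image crops", {
  img <- rand_image(30, 30)
  masks <- list(lv = rect_mask(30, 30, 1:30, 1:30, "lv"),
                whole_heart = rect_mask(30, 30, 1:30, 1:30, "whole_heart"),
                ribcage = rect_mask(30, 30, 1:30, 1:30, "ribcage"))
  crops <- localizeAll(img, masks)
  for (s in names(crops)) {
    expect_equal(dim(pixels(crops[[s]]$image)), c(30L, 30L))
  }
})

test_that("a bright extraneous blob outside the thorax does not shift the
           whole-heart crop by more than its margin", {
  coh <- cohort_fixture("segtrain", 10, c(1, 0, 0, 0), seed = 11, grid = 48L)
  fit <- aug_segmenter_fixture()
  cs <- coh[[9]]
  img <- caseImages(cs)$anterior
  px <- pixels(img)
  # urine-bag analogue: bright blob near the caudal image border
  px[20:26, 44:47] <- max(px) * 1.5
  img_blob <- PlanarImage(px, spacingMm(img), viewTag(img))
  crop_of <- function(im) {
    m <- slidingWindowSegment(fit$model, im, c(48L, 48L))
    rb <- regionBounds(cropWithMargin(im, maskBbox(m), 50)$region)
    c((rb["rowMin"] + rb["rowMax"]) / 2, (rb["colMin"] + rb["colMax"]) / 2)
  }
  shift <- abs(crop_of(img) - crop_of(img_blob))
  margin_px <- 50 / 2.8
  expect_true(all(shift <= margin_px))
})
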