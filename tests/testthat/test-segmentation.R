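test_that("Dice score follows its closed form", {
  a <- rect_mask(8, 8, 1:4, 1:4, "lv")
  expect_equal(diceScore(a, a), 1)
  b <- rect_mask(8, 8, 5:8, 5:8, "lv")
  expect_equal(diceScore(a, b), 0)
  # |a| = 4, |b| = 4, overlap 2 -> 0.5
  a2 <- rect_mask(4, 4, 1, 1:4, "lv")
  b2 <- rect_mask(4, 4, 1, 3:4, "lv")
  b2@data[2, 1:2] <- 1
  expect_equal(diceScore(a2, b2), 2 * 2 / (4 + 4))
  # both empty -> 1 by convention
  e <- rect_mask(4, 4, integer(0), 1, "lv")
  expect_equal(diceScore(e, e), 1)
  expect_error(diceScore(a, rect_mask(9, 8, 1, 1, "lv")), "same shape")
})

test_that("sliding-window tiling follows the window-count formula", {
  starts <- asNamespace("scintigrade")$.window_starts
  expect_equal(starts(704L, 704L, 0.5), 0L)
  expect_equal(starts(1056L, 704L, 0.5), c(0L, 352L))
  # ceil((W - p) / (p (1 - o))) + 1 windows
  for (W in c(704L, 900L, 1056L, 1500L)) {
    n <- length(starts(W, 704L, 0.5))
    expect_equal(n, ceiling((W - 704) / (704 * 0.5)) + 1)
  }
  expect_equal(length(starts(1000L, 256L, 0)), ceiling((1000 - 256) / 256) + 1)
})

test_that("constant-logit mock segmenter yields a full mask under any
           tiling, including padded small images", {
  mock <- mock_seg_model(function(patch) matrix(5, nrow(patch), ncol(patch)))
  img <- rand_image(20, 30, seed = 1)
  out <- slidingWindowSegment(mock, img, patchHw = c(16L, 16L), overlap = 0.5)
  expect_equal(dim(maskData(out)), c(20L, 30L))
  expect_true(all(maskData(out) == 1))
  # image smaller than the patch: padded, then cropped back
  small <- rand_image(10, 10, seed = 2)
  out2 <- slidingWindowSegment(mock, small, patchHw = c(16L, 16L))
  expect_equal(dim(maskData(out2)), c(10L, 10L))
  expect_true(all(maskData(out2) == 1))
})

test_that("sliding-window fusion matches a single-window forward pass", {
  # position-dependent logits: single window over a padded image is the
  # reference; tiling with overlap must average to the same values
  logit_of <- function(patch) {
    r <- row(patch) / nrow(patch) - 0.5
    c_ <- col(patch) / ncol(patch) - 0.5
    patch + r - c_
  }
  mock <- mock_seg_model(logit_of)
  img <- rand_image(24, 24, seed = 3)
  whole <- slidingWindowSegment(mock, img, patchHw = c(24L, 24L))
  expect_equal(maskData(whole), (logit_of(pixels(img)) > 0) * 1)
})

test_that("a segmenter learns easy phantom geometry from 20 pairs in 10
           epochs", {
  coh <- cohort_fixture("seg20", 20, c(1, 0, 0, 0), seed = 11, grid = 64L)
  vac <- cohort_fixture("segval64", 4, c(1, 0, 0, 0), seed = 12, grid = 64L)
  pairs <- segmentationPairs(coh, "whole_heart", views = "anterior")
  val <- segmentationPairs(vac, "whole_heart", views = "anterior")
  cfg <- SegTrainConfig(patchHw = c(64L, 64L), epochs = 10L, seed = 1L)
  fit <- trainSegmenter(pairs, val, cfg)
  expect_equal(nrow(fit$history), 10L)
  expect_gte(fit$model$bestValDice, 0.85)
  # best checkpoint bookkeeping
  expect_equal(fit$model$bestEpoch, which.max(fit$history$val_dice))
  expect_equal(fit$model$bestValDice, max(fit$history$val_dice))
})

test_that("training on full-image masks converges to near-full
           predictions", {
  coh <- cohort_fixture("segtrain", 10, c(1, 0, 0, 0), seed = 11, grid = 48L)
  full_pairs <- lapply(coh[1:6], function(cs) {
    list(image = caseImages(cs)$anterior,
         mask = LabelMask(matrix(1, 48, 48), "whole_heart", 2.8))
  })
  cfg <- SegTrainConfig(patchHw = c(48L, 48L), epochs = 4L, seed = 2L)
  fit <- trainSegmenter(full_pairs[1:4], full_pairs[5:6], cfg)
  expect_gte(fit$model$bestValDice, 0.99)
})

test_that("mixed-structure training runs are rejected", {
  coh <- cohort_fixture("segtrain", 10, c(1, 0, 0, 0), seed = 11, grid = 48L)
  p1 <- segmentationPairs(coh[1:2], "lv", views = "anterior")
  p2 <- segmentationPairs(coh[3:4], "ribcage", views = "anterior")
  expect_error(trainSegmenter(c(p1, p2), p1,
                              SegTrainConfig(patchHw = c(48L, 48L))),
               "single structure")
})
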