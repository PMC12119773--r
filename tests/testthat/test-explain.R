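test_that("GradCAM concentrates on the region a linear probe reads", {
  # class-0 score = mean of the input over rows 10:20 x cols 12:22
  mock <- mock_region_model(10:20, 12:22)
  img <- PlanarImage(matrix(runif(40 * 40, 0.2, 1), 40))
  sal <- gradCAM(mock, img, targetClass = 0L)
  v <- saliencyValues(sal)
  expect_equal(dim(v), c(40L, 40L))
  inside <- sum(v[10:20, 12:22]) / sum(v)
  expect_gte(inside, 0.8)
  expect_equal(max(v), 1)
})

test_that("a constant model yields a flat rectified map", {
  mock <- list(kind = "mock_cls",
               convForward = function(px) array(1, c(dim(px), 1L)),
               denseW = rbind(0, 0))
  class(mock) <- "scintModel"
  sal <- gradCAM(mock, rand_image(20, 20), targetClass = 0L)
  expect_true(all(saliencyValues(sal) == 0))
})

test_that("GradCAM on a trained classifier focuses on the cardiac region
           of high-uptake phantoms", {
  coh03 <- cohort_fixture("cls03", 24, c(0.5, 0, 0, 0.5), seed = 19,
                          grid = 96L)
  task <- TaskSpec("detection")
  samples <- lapply(coh03, function(cs) {
    crops <- localizeAll(caseImages(cs)$anterior, caseMasks(cs))
    list(image = crops$whole_heart$image, region = crops$whole_heart$region,
         label = assignTaskLabel(caseGrade(cs), task), case = cs)
  })
  labs <- vapply(samples, function(s) s$label, integer(1))
  tr <- samples[1:16]; va <- samples[17:20]; te <- samples[21:24]
  fit <- trainClassifier(tr, va, task, ClsTrainConfig(epochs = 10L,
                                                      seed = 2L))
  pos <- Filter(function(s) s$label == 1, te)
  expect_gte(length(pos), 2L)
  # the decision-relevant saliency (the map's peak and its thresholded
  # overlay, the package's Fig-style output) must sit on the heart; the
  # unthresholded map keeps a diffuse floor from broadly active channels
  inside <- vapply(pos, function(s) {
    inp <- prepareClassifierInput(s$image)
    sal <- gradCAM(fit$model, inp, targetClass = 1L)
    v <- saliencyValues(sal)
    # map the projected whole-heart mask into the crop/letterbox frame
    rb <- regionBounds(s$region)
    wh <- maskData(caseMasks(s$case)$whole_heart)
    crop_mask <- wh[(rb["rowMin"] + 1):rb["rowMax"],
                    (rb["colMin"] + 1):rb["colMax"]]
    hm <- pixels(prepareClassifierInput(
      PlanarImage(crop_mask, spacingMm(s$image)), normalize = FALSE)) > 0.5
    am <- arrayInd(which.max(v), dim(v))
    expect_true(hm[am])
    ov <- maskData(thresholdOverlay(sal, 0.5)) == 1
    sum(v[hm & ov]) / sum(v[ov])
  }, numeric(1))
  expect_gte(mean(inside), 0.5)
})

test_that("occlusion sensitivity pinpoints a single informative pixel", {
  # model that reads pixel (5, 7) only
  mock <- mock_prob_model(function(px) {
    p <- plogis(4 * px[5, 7] - 2)
    c(1 - p, p)
  })
  img <- PlanarImage(matrix(1, 16, 16))
  sal <- occlusionSensitivity(mock, img, targetClass = 1L,
                              patchHw = c(4L, 4L), stride = 2L)
  v <- saliencyValues(sal)
  expect_equal(dim(v), c(16L, 16L))
  # maximal drop exactly where windows cover (5, 7)
  expect_equal(max(v), 1)
  expect_gte(v[5, 7], max(v[12:16, 12:16]) + 0.5)
})

test_that("occlusion handles constant models and tiling edge cases", {
  flat <- mock_prob_model(function(px) c(0.5, 0.5))
  sal <- occlusionSensitivity(flat, PlanarImage(matrix(1, 12, 12)),
                              patchHw = c(4L, 4L), stride = 4L)
  expect_true(all(saliencyValues(sal) == 0))
  expect_error(
    occlusionSensitivity(flat, PlanarImage(matrix(1, 8, 8)),
                         patchHw = c(8L, 8L), stride = 2L),
    "smaller")
})

test_that("threshold overlays binarize the saliency map", {
  set.seed(3)
  v <- matrix(runif(100), 10, 10)
  v <- (v - min(v)) / (max(v) - min(v))
  sal <- new("SaliencyMap", values = v, method = "occlusion",
             targetClass = 1L, threshold = NA_real_)
  expect_equal(sum(maskData(thresholdOverlay(sal, 0))), 100)
  top <- thresholdOverlay(sal, 1)
  expect_equal(sum(maskData(top)), sum(v == 1))
  half <- thresholdOverlay(sal, 0.5)
  expect_equal(maskData(half), (v >= 0.5) * 1)
})
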