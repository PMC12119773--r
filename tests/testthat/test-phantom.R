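test_that("phantom generation is a pure function of spec and seed", {
  ph1 <- generatePhantom(tiny_spec(seed = 7))
  ph2 <- generatePhantom(tiny_spec(seed = 7))
  expect_identical(voxels(ph1$volume), voxels(ph2$volume))
  expect_identical(maskData(anatomyMasks(ph1$anatomy)$lv),
                   maskData(anatomyMasks(ph2$anatomy)$lv))
  ph3 <- generatePhantom(tiny_spec(seed = 8))
  expect_false(identical(voxels(ph1$volume), voxels(ph3$volume)))
})

test_that("zero organ intensities give a zero volume but non-empty masks", {
  oi <- c(soft_tissue = 0, ribcage = 0, kidneys = 0, bladder = 0,
          heart_blood = 0)
  ph <- generatePhantom(PhantomSpec(gridShape = 48, organIntensities = oi))
  expect_equal(sum(voxels(ph$volume)), 0)
  for (m in anatomyMasks(ph$anatomy)) expect_gt(sum(maskData(m)), 0)
})

test_that("too-small grids raise an explicit sizing error", {
  expect_error(generatePhantom(PhantomSpec(gridShape = 16)),
               "grid too small")
})

test_that("LV is a strict subset of the whole heart", {
  for (seed in 1:3) {
    ph <- generatePhantom(tiny_spec(seed = seed))
    lv <- maskData(anatomyMasks(ph$anatomy)$lv)
    wh <- maskData(anatomyMasks(ph$anatomy)$whole_heart)
    expect_equal(sum(lv == 1 & wh == 0), 0)
    expect_lt(sum(lv), sum(wh))
  }
})

test_that("cardiac uptake changes voxels only inside the LV mask, at the
           calibrated projected level", {
  ph0 <- generatePhantom(tiny_spec(grid = 64L, f = 0, seed = 5))
  ph1 <- generatePhantom(tiny_spec(grid = 64L, f = 1.5, seed = 5))
  d <- voxels(ph1$volume) - voxels(ph0$volume)
  lv <- maskData(anatomyMasks(ph0$anatomy)$lv)
  expect_equal(sum(abs(d[lv == 0])), 0)
  expect_gt(min(d[lv == 1]), 0)
  # projected mean over the LV support equals f x P99 of the baseline
  p0 <- pixels(projectVolume(ph0$volume))
  p1 <- pixels(projectVolume(ph1$volume))
  lv2d <- maskData(projectMask(anatomyMasks(ph0$anatomy)$lv))
  achieved <- mean((p1 - p0)[lv2d == 1]) / quantile_oracle(p0, 0.99)
  expect_equal(achieved, 1.5, tolerance = 1e-9)
})

test_that("counting noise preserves the expected total and is seeded", {
  vol <- ActivityVolume(array(5, c(20, 20, 20)))
  n1 <- addCountingNoise(vol, 1e7, seed = 3)
  n2 <- addCountingNoise(vol, 1e7, seed = 3)
  expect_identical(voxels(n1), voxels(n2))
  expect_true(all(voxels(n1) >= 0))
  expect_true(all(voxels(n1) == round(voxels(n1))))
  # relative deviation of the total below 0.1% (3 sigma of Poisson(1e7))
  expect_lt(abs(sum(voxels(n1)) - 1e7) / 1e7, 1e-3)
  expect_error(addCountingNoise(ActivityVolume(array(0, c(4, 4, 4))), 10, 1),
               "all-zero")
})

test_that("a one-count target draws a Poisson(1) total", {
  img <- PlanarImage(matrix(1, 8, 8))
  totals <- vapply(1:300, function(s)
    sum(pixels(addCountingNoise(img, 1, seed = s))), numeric(1))
  # mean of 300 Poisson(1) draws: 1 +/- 3/sqrt(300)
  expect_lt(abs(mean(totals) - 1), 3 / sqrt(300))
})

test_that("cohort generation validates proportions and reproduces grades", {
  expect_error(generateCohort(4, c(0.5, 0.5, 0.5, 0.5), tiny_spec()),
               "sum to 1")
  expect_error(generateCohort(3, c(1, 0, 0, 0), tiny_spec()), ">= 4")
  coh <- cohort_fixture("grade0", 4, c(1, 0, 0, 0), seed = 2)
  expect_true(all(vapply(coh, caseGrade, integer(1)) == 0L))
  expect_true(all(vapply(coh, uptakeFraction, numeric(1)) == 0))
  coh2 <- generateCohort(4, c(1, 0, 0, 0), tiny_spec(), seed = 2)
  expect_identical(pixels(caseImages(coh[[1]])$anterior),
                   pixels(caseImages(coh2[[1]])$anterior))
})

test_that("cohort grade frequencies fall in the multinomial 99% region", {
  coh <- generateCohort(100, rep(0.25, 4), PhantomSpec(gridShape = 32 + 16),
                        seed = 31, totalCountsPerView = 1e5)
  counts <- table(factor(vapply(coh, caseGrade, integer(1)), levels = 0:3))
  # per-class Binomial(100, 0.25): 99% central region approx 25 +/- 11.5
  expect_true(all(counts >= 13 & counts <= 37))
})

test_that("projected LV intensity grows with grade before noise", {
  coh <- generateCohort(32, rep(0.25, 4), tiny_spec(), seed = 13,
                        totalCountsPerView = NULL, dilateMm = 0)
  grades <- vapply(coh, caseGrade, integer(1))
  expect_equal(length(unique(grades)), 4L)
  lv_mean <- vapply(coh, function(cs) {
    img <- pixels(caseImages(cs)$anterior)
    lv <- maskData(caseMasks(cs)$lv)
    mean(img[lv == 1])
  }, numeric(1))
  by_grade <- tapply(lv_mean, grades, mean)
  expect_true(all(diff(by_grade) > 0))
})

test_that("posterior views mirror the anterior geometry", {
  coh <- generateCohort(4, c(1, 0, 0, 0), tiny_spec(), seed = 17,
                        totalCountsPerView = NULL)
  ant <- pixels(caseImages(coh[[1]])$anterior)
  post <- pixels(caseImages(coh[[1]])$posterior)
  expect_equal(post, ant[rev(seq_len(nrow(ant))), ])
})
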