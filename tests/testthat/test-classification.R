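test_that("task labels follow the two clinical splits", {
  det <- TaskSpec("detection"); sev <- TaskSpec("severity")
  expect_equal(assignTaskLabel(0, det), 0L)
  expect_equal(assignTaskLabel(1, det), 1L)
  expect_equal(assignTaskLabel(1, sev), 0L)
  expect_equal(assignTaskLabel(2, sev), 1L)
  expect_equal(assignTaskLabel(3, sev), 1L)
  expect_equal(assignTaskLabel(0, sev), 0L)
  expect_error(assignTaskLabel(4, det), "0..3")
  expect_error(TaskSpec("screening"), "positiveGrades")
})

test_that("patient-wise folds partition patients evenly and keep
           acquisitions together", {
  pats <- sprintf("P%02d", 1:9)
  folds <- patientwiseFolds(pats, 3, seed = 2)
  expect_setequal(names(folds), pats)
  expect_equal(as.integer(table(folds)), c(3L, 3L, 3L))
  # repeated patient ids (several acquisitions) map to one fold
  folds2 <- patientwiseFolds(c(pats, pats), 3, seed = 2)
  expect_identical(folds2, folds)
  expect_identical(patientwiseFolds(pats, 3, seed = 2), folds)
  expect_false(identical(patientwiseFolds(pats, 3, seed = 3), folds))
  expect_error(patientwiseFolds(pats[1:2], 3), "at least 3")
  # no leakage: train/test patient sets are disjoint by construction
  for (fd in 1:3) {
    expect_length(intersect(names(folds)[folds == fd],
                            names(folds)[folds != fd]), 0)
  }
})

test_that("classifier training separates synthetic classes and records its
           checkpoint", {
  s <- blob_samples(40, seed = 2)
  tr <- s[1:24]; va <- s[25:32]; te <- s[33:40]
  cfg <- ClsTrainConfig(epochs = 10L, seed = 3L)
  fit <- trainClassifier(tr, va, TaskSpec("detection"), cfg,
                         fold = 2, crop = "whole_heart", view = "anterior")
  expect_equal(nrow(fit$history), 10L)
  # checkpoint = argmax of the stored mean metric, ties to earlier epoch
  expect_equal(fit$model$bestEpoch, which.max(fit$history$mean_metric))
  probs_te <- lapply(te, function(x) predictProba(fit$model, x$image))
  yte <- vapply(te, function(x) x$label, integer(1))
  rep_ <- computeMetrics(yte, probs_te)
  expect_gte(metricValues(rep_)["auc"], 0.9)
  # provenance propagates to predictions
  pr <- provenance(probs_te[[1]])
  expect_equal(pr$fold, 2)
  expect_equal(pr$crop, "whole_heart")
  expect_equal(pr$view, "anterior")
})

test_that("label-permuted training stays near chance", {
  s <- blob_samples(56, seed = 4)
  # zero-information permutation across train, validation and test: flip
  # exactly half of each class, so no feature carries a consistent label
  # association anywhere in the permuted task
  labs <- vapply(s, function(x) x$label, integer(1))
  set.seed(77)
  for (block in list(1:24, 25:32, 33:56)) {
    for (cl in 0:1) {
      idx <- block[labs[block] == cl]
      labs[sample(idx, length(idx) / 2)] <- 1L - cl
    }
  }
  perm <- lapply(seq_along(s), function(i) list(image = s[[i]]$image,
                                                label = labs[i]))
  fit <- trainClassifier(perm[1:24], perm[25:32], TaskSpec("detection"),
                         ClsTrainConfig(epochs = 6L, seed = 5L))
  te <- perm[33:56]
  probs_te <- lapply(te, function(x) predictProba(fit$model, x$image))
  auc <- metricValues(computeMetrics(vapply(te, function(x) x$label,
                                            integer(1)), probs_te))["auc"]
  expect_gte(auc, 0.3)
  expect_lte(auc, 0.7)
})

test_that("single-class training or validation sets are rejected", {
  s <- blob_samples(12, seed = 6)
  ones <- Filter(function(x) x$label == 1, s)
  expect_error(trainClassifier(ones, s[1:4], TaskSpec("detection")),
               "single-class")
  expect_error(trainClassifier(s[1:8], ones[1:2], TaskSpec("detection")),
               "single-class")
})

test_that("predicted probabilities live on the simplex and are
           deterministic", {
  s <- blob_samples(12, seed = 7)
  fit <- trainClassifier(s[1:8], s[9:12], TaskSpec("detection"),
                         ClsTrainConfig(epochs = 2L, seed = 1L))
  p1 <- predictProba(fit$model, s[[1]]$image)
  p2 <- predictProba(fit$model, s[[1]]$image)
  expect_equal(sum(probs(p1)), 1, tolerance = 1e-9)
  expect_true(all(probs(p1) >= 0))
  expect_identical(probs(p1), probs(p2))
  # unnormalized dynamic range at network size triggers the on-the-fly path
  raw <- PlanarImage(matrix(runif(64 * 64, 0, 500), 64))
  expect_warning(p3 <- predictProba(fit$model, raw), "normalizing")
  expect_equal(sum(probs(p3)), 1, tolerance = 1e-9)
})

test_that("a mock with equal logits yields the uniform distribution", {
  softmax <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  mock <- mock_prob_model(function(px) softmax(c(0, 0)))
  p <- predictProba(mock, rand_image(8, 8))
  expect_equal(probs(p), c(0.5, 0.5))
})
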