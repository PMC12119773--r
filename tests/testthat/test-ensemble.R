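test_that("probability averaging reproduces the three-model worked
           example", {
  members <- list(ClassProbabilities(c(0.45, 0.55)),
                  ClassProbabilities(c(0.95, 0.05)),
                  ClassProbabilities(c(0.48, 0.52)))
  avg <- averageProbabilities(members)
  expect_equal(round(probs(avg), 3), c(0.627, 0.373))
  expect_equal(decide(avg), 0L)
  # majority voting would have said class 1; averaging trusts the
  # confident member
  votes <- vapply(members, function(m) suppressWarnings(decide(m)),
                  integer(1))
  expect_equal(sum(votes == 1L), 2L)
})

test_that("averaging is an identity for one member and is commutative", {
  m <- ClassProbabilities(c(0.3, 0.7))
  expect_equal(probs(averageProbabilities(list(m))), c(0.3, 0.7))
  ms <- lapply(1:5, function(i) {
    p <- (i:(i + 1)) / sum(i:(i + 1))
    ClassProbabilities(p)
  })
  expect_equal(probs(averageProbabilities(ms)),
               probs(averageProbabilities(rev(ms))), tolerance = 1e-15)
  expect_equal(sum(probs(averageProbabilities(ms))), 1, tolerance = 1e-12)
  expect_error(averageProbabilities(list()), "empty")
})

test_that("decide takes the argmax with ties to the negative class", {
  expect_equal(decide(ClassProbabilities(c(0.2, 0.8))), 1L)
  expect_warning(d <- decide(ClassProbabilities(c(0.5, 0.5))), "tie")
  expect_equal(d, 0L)
})

test_that("the two-stage ensemble averages folds within groups, then
           groups", {
  grid <- expand.grid(fold = 1:3, crop = c("lv", "whole_heart", "ribcage"),
                      view = c("anterior", "posterior", "summation"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 27L)
  # identical members -> idempotent
  same <- lapply(seq_len(27), function(i) {
    ClassProbabilities(c(0.6, 0.4), grid$fold[i], grid$crop[i], grid$view[i])
  })
  res <- twoStageEnsemble(same)
  expect_equal(probs(averagedProbs(res)), c(0.6, 0.4), tolerance = 1e-12)
  expect_length(ensembleStage1(res), 9L)
  expect_length(ensembleMembers(res), 27L)

  # balanced grid (equal members per group) == flat mean of all members
  set.seed(3)
  p1 <- runif(27)
  mixed <- lapply(seq_len(27), function(i) {
    ClassProbabilities(c(1 - p1[i], p1[i]), grid$fold[i], grid$crop[i],
                       grid$view[i])
  })
  res2 <- twoStageEnsemble(mixed)
  expect_equal(probs(averagedProbs(res2)), c(1 - mean(p1), mean(p1)),
               tolerance = 1e-12)
  expect_equal(ensembleDecision(res2),
               as.integer(mean(p1) > 1 - mean(p1)))

  # the worked three-model example as a single group decides class 0
  one_group <- list(ClassProbabilities(c(0.45, 0.55), 1, "lv", "anterior"),
                    ClassProbabilities(c(0.95, 0.05), 2, "lv", "anterior"),
                    ClassProbabilities(c(0.48, 0.52), 3, "lv", "anterior"))
  expect_equal(ensembleDecision(twoStageEnsemble(one_group)), 0L)
  expect_error(twoStageEnsemble(list()), "empty")
})

test_that("unbalanced groups weigh strategies, not members", {
  # group A has two members at 0.9, group B one member at 0.3: stage
  # averaging gives (0.9 + 0.3) / 2, a flat mean would give 0.7
  ms <- list(ClassProbabilities(c(0.1, 0.9), 1, "lv", "anterior"),
             ClassProbabilities(c(0.1, 0.9), 2, "lv", "anterior"),
             ClassProbabilities(c(0.7, 0.3), 1, "ribcage", "anterior"))
  res <- twoStageEnsemble(ms)
  expect_equal(probs(averagedProbs(res))[2], 0.6, tolerance = 1e-12)
})

test_that("metric reports satisfy their defining identities", {
  expect_equal(balancedAccuracy(0.969, 0.981), 0.975)
  expect_equal(round(f1Score(0.984, 0.969), 3), 0.976)
  expect_equal(balancedAccuracy(0.960, 0.952), 0.956)

  labels <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.9, 0.7, 0.6, 0.8, 0.9, 0.6, 0.3, 0.2,
              0.1, 0.4, 0.2, 0.3, 0.1, 0.2, 0.6, 0.7, 0.1, 0.2)
  probs_ <- lapply(scores, function(s) ClassProbabilities(c(1 - s, s)))
  rep_ <- computeMetrics(labels, probs_)
  cf <- confusionCounts(rep_)
  m <- metricValues(rep_)
  expect_equal(unname(cf["TP"] + cf["FN"]), 10L)
  expect_equal(unname(m["sensitivity"]), unname(cf["TP"] / 10))
  expect_equal(unname(m["specificity"]), unname(cf["TN"] / 10))
  expect_equal(unname(m["bac"]),
               balancedAccuracy(m[["sensitivity"]], m[["specificity"]]))
  expect_equal(unname(m["f1"]),
               f1Score(m[["precision"]], m[["sensitivity"]]))
  expect_equal(unname(m["accuracy"]), unname((cf["TP"] + cf["TN"]) / 20))
})

test_that("AUC equals the all-pairs Mann-Whitney count, ties at 1/2", {
  set.seed(12)
  for (rep_i in 1:5) {
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(20), 2)  # duplicates force tie handling
    m <- computeMetrics(labels, scores)
    expect_equal(unname(metricValues(m)["auc"]), auc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
  # perfectly separated scores
  expect_equal(unname(metricValues(
    computeMetrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)))["auc"]), 1)
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  labels <- rbinom(40, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- round(runif(40), 2)
  ours <- unname(metricValues(computeMetrics(labels, scores))["auc"])
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(14)
  labels <- rbinom(30, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(30)
  a1 <- unname(metricValues(computeMetrics(labels, scores))["auc"])
  a2 <- unname(metricValues(computeMetrics(labels,
                                           plogis(5 * scores - 2)))["auc"])
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("single-class labels leave AUC undefined with a warning", {
  expect_warning(m <- computeMetrics(c(1, 1, 1), c(0.2, 0.6, 0.9)),
                 "AUC undefined")
  expect_true(is.na(metricValues(m)["auc"]))
})

test_that("ROC curves run from (0,0) to (1,1) monotonically", {
  set.seed(15)
  labels <- rbinom(25, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(25)
  roc <- rocPoints(computeMetrics(labels, scores))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("normalized confusion matrices divide rows by their totals", {
  rep_ <- new("MetricsReport", f1 = NA_real_, sensitivity = 0.9,
              specificity = 0.8, precision = NA_real_, accuracy = 0.85,
              bac = 0.85, auc = NA_real_,
              confusion = c(TP = 9L, FP = 2L, TN = 8L, FN = 1L),
              roc = data.frame(fpr = numeric(), tpr = numeric()))
  nm <- confusionMatrixNormalized(rep_)
  expect_equal(unname(nm["true_0", ]), c(0.8, 0.2))
  expect_equal(unname(nm["true_1", ]), c(0.1, 0.9))

  perfect <- computeMetrics(c(0, 1), list(ClassProbabilities(c(0.9, 0.1)),
                                          ClassProbabilities(c(0.1, 0.9))))
  expect_equal(unname(confusionMatrixNormalized(perfect)),
               diag(2))

  all_pos <- computeMetrics(c(0, 1), list(ClassProbabilities(c(0.1, 0.9)),
                                          ClassProbabilities(c(0.2, 0.8))))
  expect_equal(unname(confusionMatrixNormalized(all_pos)),
               matrix(c(0, 0, 1, 1), 2))
})
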