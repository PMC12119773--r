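#' @include AllClasses.R
NULL

#' Average class probabilities across models
#'
#' Arithmetic mean per class of the members' probability vectors; the result
#' stays on the probability simplex. Averaging probabilities (rather than
#' voting) lets a confident model outweigh two marginal ones: members
#' (0.45, 0.55), (0.95, 0.05) and (0.48, 0.52) average to (0.627, 0.373),
#' so the ensemble decides class 0 although two of three members lean to
#' class 1.
#'
#' @param members non-empty list of [ClassProbabilities-class] with equal
#'   class count.
#' @return a [ClassProbabilities-class] (provenance fields NA).
#' @examples
#' members <- list(ClassProbabilities(c(0.45, 0.55)),
#'                 ClassProbabilities(c(0.95, 0.05)),
#'                 ClassProbabilities(c(0.48, 0.52)))
#' round(probs(averageProbabilities(members)), 3)  # 0.627 0.373
#' @export
averageProbabilities <- function(members) {
  if (length(members) == 0L) stop("cannot average an empty member list")
  ps <- lapply(members, function(m) {
    if (is(m, "ClassProbabilities")) m@p else as.numeric(m)
  })
  nc <- unique(vapply(ps, length, integer(1)))
  if (length(nc) != 1L) stop("members must share one class count")
  ClassProbabilities(Reduce(`+`, ps) / length(ps))
}

#' Decide a class from a probability vector
#'
#' Argmax over classes, 0-based. An exact tie resolves to class 0 (the
#' negative class) with a warning.
#'
#' @param p a [ClassProbabilities-class] or numeric simplex vector.
#' @return integer class index (0-based).
#' @examples
#' decide(ClassProbabilities(c(0.627, 0.373)))  # 0
#' @export
decide <- function(p) {
  v <- if (is(p, "ClassProbabilities")) p@p else as.numeric(p)
  top <- which(v == max(v))
  if (length(top) > 1L) {
    warning("probability tie; deciding the negative class")
    return(min(top) - 1L)
  }
  as.integer(which.max(v) - 1L)
}

#' Two-stage probability-averaging ensemble
#'
#' Stage 1 averages fold models within each (crop strategy, view) group;
#' stage 2 averages the group means. The decision is the argmax of the final
#' average. With a complete, balanced grid (equal members per group) the
#' result equals the flat mean of all members; with unbalanced groups stage
#' averaging keeps each strategy's weight equal.
#'
#' @param perModel list of [ClassProbabilities-class], each stamped with
#'   `fold`, `crop`, `view` provenance (NA provenance members form one
#'   group).
#' @return an [EnsembleResult-class] retaining both stages' intermediates.
#' @export
twoStageEnsemble <- function(perModel) {
  if (length(perModel) == 0L) stop("empty model grid")
  keys <- vapply(perModel, function(m) {
    pr <- m@provenance
    paste(pr$crop %||% NA, pr$view %||% NA, sep = "|")
  }, character(1))
  groups <- split(perModel, keys)
  stage1 <- lapply(groups, averageProbabilities)
  final <- averageProbabilities(stage1)
  dec <- suppressWarnings(decide(final))
  new("EnsembleResult", averagedP = final, decision = as.integer(dec),
      members = perModel, stage1 = stage1)
}

#' Metric identities
#'
#' Balanced accuracy is the arithmetic mean of sensitivity and specificity;
#' F1 is the harmonic mean of precision and sensitivity. Exposed as
#' functions so reported tables can be checked for internal consistency.
#'
#' @param sensitivity,specificity,precision scalars in `[0, 1]`.
#' @return the derived metric.
#' @examples
#' balancedAccuracy(0.969, 0.981)
#' f1Score(0.984, 0.969)
#' @export
balancedAccuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' @rdname balancedAccuracy
#' @export
f1Score <- function(precision, sensitivity) {
  2 * precision * sensitivity / (precision + sensitivity)
}

# Mann-Whitney AUC with ties counted 1/2, computed via average ranks.
.auc_mann_whitney <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# ROC by threshold sweep over the unique scores plus sentinels; predicts
# positive when score >= threshold.
.roc_points <- function(labels, scores) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  tpr <- fpr <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    tpr[i] <- if (np > 0) sum(pred & labels == 1) / np else NA_real_
    fpr[i] <- if (nn > 0) sum(pred & labels == 0) / nn else NA_real_
  }
  data.frame(fpr = fpr, tpr = tpr)
}

#' Classification metrics from labels and probabilities
#'
#' Decisions are taken per case by argmax of the probability vector (ties to
#' the negative class); the confusion matrix, sensitivity, specificity,
#' precision, accuracy, F1 and balanced accuracy (BAC, the mean of
#' sensitivity and specificity) follow from the counts. AUC is the
#' Mann-Whitney statistic of the positive-class probabilities (ties counted
#' 1/2) and the ROC curve sweeps all unique scores. A single-class label
#' vector leaves AUC as NA with a warning.
#'
#' @param labels binary vector (0/1) of true labels.
#' @param probs list of [ClassProbabilities-class] (or a numeric vector of
#'   positive-class scores), one per label.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(labels, probs) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  if (is.numeric(probs)) {
    scores <- as.numeric(probs)
    decisions <- as.integer(scores > 0.5)
  } else {
    stopifnot(length(probs) == length(labels))
    scores <- vapply(probs, function(p) p@p[2], numeric(1))
    decisions <- vapply(probs, function(p) suppressWarnings(decide(p)),
                        integer(1))
  }
  stopifnot(length(scores) == length(labels))
  tp <- sum(decisions == 1 & labels == 1)
  fp <- sum(decisions == 1 & labels == 0)
  tn <- sum(decisions == 0 & labels == 0)
  fn <- sum(decisions == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- (tp + tn) / length(labels)
  bac <- if (is.na(sens) || is.na(spec)) NA_real_ else {
    balancedAccuracy(sens, spec)
  }
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    f1Score(prec, sens)
  } else NA_real_
  if (length(unique(labels)) < 2L) {
    warning("single-class label vector: AUC undefined, reported as NA")
  }
  auc <- .auc_mann_whitney(labels, scores)
  new("MetricsReport", f1 = f1, sensitivity = sens, specificity = spec,
      precision = prec, accuracy = acc, bac = bac, auc = auc,
      confusion = c(TP = as.integer(tp), FP = as.integer(fp),
                    TN = as.integer(tn), FN = as.integer(fn)),
      roc = .roc_points(labels, scores))
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes (negative first), each divided by its row total;
#' an empty row is reported as NA.
#'
#' @param report a [MetricsReport-class].
#' @return 2 x 2 numeric matrix with dimnames `true_0/true_1` x
#'   `pred_0/pred_1`.
#' @export
confusionMatrixNormalized <- function(report) {
  cf <- report@confusion
  m <- rbind(c(cf["TN"], cf["FP"]), c(cf["FN"], cf["TP"]))
  rs <- rowSums(m)
  out <- m / rs
  out[rs == 0, ] <- NA_real_
  dimnames(out) <- list(c("true_0", "true_1"), c("pred_0", "pred_1"))
  out
}
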