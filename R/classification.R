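#' @include AllClasses.R engine.R preprocess.R ensemble.R
NULL

#' Binary label for a grade under a task
#'
#' Detection separates grade 0 from grades 1-3; severity scoring separates
#' grades 0-1 from grades 2-3.
#'
#' @param grade integer grade in 0..3.
#' @param task a [TaskSpec-class].
#' @return 1 if the grade belongs to the task's positive class, else 0.
#' @examples
#' assignTaskLabel(1, TaskSpec("detection"))  # 1
#' assignTaskLabel(1, TaskSpec("severity"))   # 0
#' @export
assignTaskLabel <- function(grade, task) {
  stopifnot(is(task, "TaskSpec"))
  if (!all(grade %in% 0:3)) stop("grade must be in 0..3")
  as.integer(grade %in% task@positiveGrades)
}

#' Patient-wise cross-validation folds
#'
#' Randomly partitions patients (not acquisitions) into `k` folds of
#' near-equal size, so that every image of a patient shares that patient's
#' fold and each fold serves once as the held-out test set.
#'
#' @param cases list of [LabeledCase-class] objects, or a character vector
#'   of patient ids (repeats allowed).
#' @param k number of folds (default 3).
#' @param seed RNG seed.
#' @return named integer vector mapping each distinct patient id to its
#'   fold in 1..k.
#' @export
patientwiseFolds <- function(cases, k = 3L, seed = 1L) {
  ids <- if (is.character(cases)) cases else {
    vapply(cases, patientId, character(1))
  }
  patients <- unique(ids)
  if (length(patients) < k)
    stop("need at least ", k, " distinct patients, got ", length(patients))
  with_seed(seed, {
    shuffled <- sample(patients)
    folds <- rep(seq_len(k), length.out = length(shuffled))
    stats::setNames(folds[match(patients, shuffled)], patients)
  })
}

# Epoch ordering that interleaves classes proportionally (shuffle within
# class, then merge by evenly spaced virtual positions). On small data sets
# plain shuffling can produce runs of single-class batches whose full-step
# adaptive-gradient updates keep the head oscillating between the two
# constant predictions; stratified interleaving keeps every batch mixed.
.stratified_order <- function(labels) {
  pos <- numeric(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    pos[idx] <- (seq_along(idx) - runif(1)) / length(idx)
  }
  order(pos)
}

.prepare_cls <- function(img, cfg) {
  if (identical(dim(pixels(img)), as.integer(cfg@inputHw))) return(img)
  prepareClassifierInput(img, cfg@inputHw, cfg@inputSpacingMm)
}

#' Train a binary crop classifier
#'
#' Trains the compact CNN backbone with cross-entropy loss (Adam, piecewise
#' learning-rate decay) on prepared crops. After every epoch the validation
#' F1, sensitivity, AUC, specificity and accuracy are recorded and the
#' checkpoint maximizing their unweighted mean is kept (ties resolved to the
#' earlier epoch).
#'
#' @param train,val lists of `list(image = PlanarImage, label = 0/1)`; both
#'   sets must contain both classes. Images are letterboxed/normalized
#'   automatically if not already at the network input size.
#' @param task a [TaskSpec-class] (recorded on the model).
#' @param cfg a [ClsTrainConfig-class].
#' @param fold,crop,view provenance stamped on every prediction.
#' @return list with `model` (best checkpoint for [predictProba()]) and
#'   `history` (per-epoch loss and validation metrics).
#' @export
trainClassifier <- function(train, val, task = TaskSpec("detection"),
                            cfg = ClsTrainConfig(), fold = NA,
                            crop = NA_character_, view = NA_character_) {
  stopifnot(length(train) > 0, length(val) > 0, is(cfg, "ClsTrainConfig"))
  ytr <- vapply(train, function(s) as.integer(s$label), integer(1))
  yva <- vapply(val, function(s) as.integer(s$label), integer(1))
  if (length(unique(ytr)) < 2L)
    stop("single-class training set; balance classes first")
  if (length(unique(yva)) < 2L)
    stop("single-class validation set; balance classes first")

  xtr <- lapply(train, function(s) pixels(.prepare_cls(s$image, cfg)))
  xva <- lapply(val, function(s) pixels(.prepare_cls(s$image, cfg)))

  net <- nn_init_cls(1L, c(8L, 16L, 16L), 2L, seed = cfg@seed)
  opt <- adam_init(net)
  metric_names <- c("f1", "sensitivity", "auc", "specificity", "accuracy")
  history <- NULL
  best <- list(score = -Inf, net = net, epoch = 0L)

  with_seed(cfg@seed + 1L, {
    for (epoch in seq_len(cfg@epochs)) {
      lr <- lr_at_epoch(cfg@lr0, cfg@lrDecay, cfg@lrStep, epoch)
      ord <- .stratified_order(ytr)
      acc <- NULL; nacc <- 0L; epoch_loss <- 0
      for (k in seq_along(ord)) {
        i <- ord[k]
        x <- array(xtr[[i]], c(dim(xtr[[i]]), 1L))
        cache <- nn_cls_forward(net, x, keep = TRUE)
        p <- softmax_vec(cache$logits)
        y1 <- ytr[i] + 1L
        epoch_loss <- epoch_loss - log(p[y1] + 1e-12)
        dlogits <- p
        dlogits[y1] <- dlogits[y1] - 1
        acc <- grad_accumulate(acc, nn_cls_backward(net, cache, dlogits))
        nacc <- nacc + 1L
        if (nacc >= cfg@batchSize || k == length(ord)) {
          st <- adam_step(net, opt, grad_scale(acc, 1 / nacc), lr)
          net <- st$net; opt <- st$opt
          acc <- NULL; nacc <- 0L
        }
      }
      vp <- lapply(xva, function(px) {
        softmax_vec(nn_cls_forward(net,
                                   array(px, c(dim(px), 1L)))$logits)
      })
      probs <- lapply(vp, ClassProbabilities)
      rep_ <- computeMetrics(yva, probs)
      mv <- metricValues(rep_)[metric_names]
      score <- mean(mv, na.rm = TRUE)
      history <- rbind(history, data.frame(
        epoch = epoch, loss = epoch_loss / length(xtr), t(mv),
        mean_metric = score))
      if (score > best$score) best <- list(score = score, net = net,
                                           epoch = epoch)
    }
  })

  model <- list(kind = "classifier", net = best$net, task = task@name,
                inputHw = cfg@inputHw, inputSpacingMm = cfg@inputSpacingMm,
                backbone = cfg@backbone, bestEpoch = best$epoch,
                bestScore = best$score,
                provenance = list(fold = fold, crop = crop, view = view))
  class(model) <- "scintModel"
  list(model = model, history = history)
}

#' Class probabilities for one image
#'
#' Runs the classifier (softmax output) on a crop. Crops that are not yet
#' at the network input size are letterboxed automatically; inputs whose
#' dynamic range suggests unnormalized counts trigger a warning and are
#' normalized on the fly.
#'
#' @param model a trained classifier from [trainClassifier()] (or a mock
#'   with a `probFn`).
#' @param img a [PlanarImage-class] crop.
#' @return a [ClassProbabilities-class] with the model's provenance.
#' @export
predictProba <- function(model, img) {
  stopifnot(is(img, "PlanarImage"))
  if (!is.null(model$probFn)) {
    p <- model$probFn(pixels(img))
    pr <- model$provenance %||% list(fold = NA, crop = NA, view = NA)
    return(ClassProbabilities(p, pr$fold, pr$crop, pr$view))
  }
  stopifnot(identical(model$kind, "classifier"))
  if (identical(dim(pixels(img)), as.integer(model$inputHw))) {
    if (max(pixels(img)) > 1.5) {
      warning("input dynamic range exceeds [0, 1]; normalizing on the fly")
      img <- percentileNormalize(img)
    }
  } else {
    # raw crop: letterbox + normalize through the standard preparation
    img <- prepareClassifierInput(img, model$inputHw, model$inputSpacingMm)
  }
  x <- array(pixels(img), c(dim(pixels(img)), 1L))
  p <- softmax_vec(nn_cls_forward(model$net, x)$logits)
  pr <- model$provenance
  ClassProbabilities(p, pr$fold, pr$crop, pr$view)
}
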