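#' @include AllClasses.R engine.R classification.R
NULL

# Bilinear upsample of a small map to (nr, nc).
.upsample_bilinear <- function(m, nr, nc) {
  sr <- (seq_len(nr) - 0.5) * nrow(m) / nr + 0.5
  sc <- (seq_len(nc) - 0.5) * ncol(m) / nc + 0.5
  matrix(bilinear_at(m, rep(sr, times = nc), rep(sc, each = nr)), nr, nc)
}

# Min-max rescale to [0,1]; a flat map rescales to all zeros.
.rescale01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

# Last convolutional stage activations and the dense head of a model.
# Real classifiers use the engine's third conv stage; mocks supply
# `convForward` (input matrix -> (Ha, Wa, C) activation array) plus `denseW`.
.conv_stage <- function(model, px) {
  if (!is.null(model$convForward)) {
    list(A = model$convForward(px), W = model$denseW)
  } else if (identical(model$kind, "classifier")) {
    x <- array(px, c(dim(px), 1L))
    cache <- nn_cls_forward(model$net, x, keep = TRUE)
    list(A = cache$a3, W = model$net$Wd)
  } else {
    stop("model has no spatial activations; GradCAM requires a ",
         "convolutional classifier")
  }
}

#' GradCAM saliency map
#'
#' Gradient-weighted class activation map at the last convolutional stage:
#' channel weights are the spatially pooled gradients of the target-class
#' score with respect to the stage activations; the weighted activation sum
#' is rectified, bilinearly upsampled to the input size and min-max rescaled
#' to `[0, 1]`. For the package's global-average-pool + dense head the
#' pooled gradient of class `c` w.r.t. channel `ch` is the dense weight
#' `W[c, ch]` divided by the activation grid size, so the map is computed
#' analytically.
#'
#' @param model a trained classifier from [trainClassifier()], or a mock
#'   exposing `convForward` and `denseW`.
#' @param img the preprocessed input crop ([PlanarImage-class]).
#' @param targetClass class index (0-based) to explain.
#' @return a [SaliencyMap-class] aligned with the input.
#' @export
gradCAM <- function(model, img, targetClass = 1L) {
  stopifnot(is(img, "PlanarImage"))
  px <- pixels(img)
  if (identical(model$kind, "classifier") &&
      !identical(dim(px), as.integer(model$inputHw))) {
    px <- pixels(prepareClassifierInput(img, model$inputHw,
                                        model$inputSpacingMm))
  }
  st <- .conv_stage(model, px)
  A <- st$A
  dA <- dim(A)
  w <- st$W[targetClass + 1L, ] / (dA[1] * dA[2])
  cam <- matrix(0, dA[1], dA[2])
  for (ch in seq_len(dA[3])) cam <- cam + w[ch] * A[, , ch]
  cam <- relu(cam)
  up <- .upsample_bilinear(cam, nrow(px), ncol(px))
  new("SaliencyMap", values = .rescale01(up), method = "gradcam",
      targetClass = as.integer(targetClass), threshold = NA_real_)
}

#' Occlusion-sensitivity saliency map
#'
#' Slides a zero patch over the input and records, at every covered pixel,
#' the drop in the target-class probability relative to the unoccluded
#' prediction; overlapping windows are averaged and the map min-max
#' rescaled to `[0, 1]`.
#'
#' @param model a classifier usable with [predictProba()].
#' @param img the preprocessed input crop ([PlanarImage-class]).
#' @param targetClass class index (0-based).
#' @param patchHw occlusion patch size (default 16 x 16 px).
#' @param stride window stride in px (default 8).
#' @return a [SaliencyMap-class].
#' @export
occlusionSensitivity <- function(model, img, targetClass = 1L,
                                 patchHw = c(16L, 16L), stride = 8L) {
  stopifnot(is(img, "PlanarImage"), stride >= 1)
  if (identical(model$kind, "classifier") &&
      !identical(dim(pixels(img)), as.integer(model$inputHw))) {
    img <- prepareClassifierInput(img, model$inputHw, model$inputSpacingMm)
  }
  px <- pixels(img)
  if (any(patchHw >= dim(px)))
    stop("occlusion patch must be smaller than the image")
  base <- probs(predictProba(model, img))[targetClass + 1L]
  acc <- cnt <- matrix(0, nrow(px), ncol(px))
  r_starts <- unique(c(seq(0L, nrow(px) - patchHw[1], by = stride),
                       nrow(px) - patchHw[1]))
  c_starts <- unique(c(seq(0L, ncol(px) - patchHw[2], by = stride),
                       ncol(px) - patchHw[2]))
  for (r0 in r_starts) {
    for (c0 in c_starts) {
      rows <- r0 + seq_len(patchHw[1]); cols <- c0 + seq_len(patchHw[2])
      occ <- px
      occ[rows, cols] <- 0
      p <- probs(predictProba(model, PlanarImage(occ, img@spacingMm,
                                                 img@view)))[targetClass + 1L]
      acc[rows, cols] <- acc[rows, cols] + (base - p)
      cnt[rows, cols] <- cnt[rows, cols] + 1
    }
  }
  new("SaliencyMap", values = .rescale01(acc / pmax(cnt, 1)),
      method = "occlusion", targetClass = as.integer(targetClass),
      threshold = NA_real_)
}

#' Threshold a saliency map into an overlay mask
#'
#' @param map a [SaliencyMap-class].
#' @param threshold scalar in `[0, 1]`; pixels with saliency `>= threshold`
#'   become foreground.
#' @return a binary 2D [LabelMask-class] (structure `"saliency"`, pixel
#'   units).
#' @export
thresholdOverlay <- function(map, threshold = 0.5) {
  stopifnot(is(map, "SaliencyMap"), threshold >= 0, threshold <= 1)
  LabelMask((map@values >= threshold) * 1, "saliency", c(1, 1))
}
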