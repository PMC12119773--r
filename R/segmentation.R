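#' @include AllClasses.R engine.R preprocess.R
NULL

# Coordinate channels: absolute normalized row/col position of each patch
# pixel within its source image. The segmentation net input is
# (intensity, row, col); local convolutions alone cannot encode anatomical
# position on a whole-body field of view, the coordinate channels can.
.coord_channels <- function(src_dim, r0, c0, nr, nc) {
  rows <- (r0 + seq_len(nr) - 0.5) / src_dim[1]
  cols <- (c0 + seq_len(nc) - 0.5) / src_dim[2]
  list(r = matrix(rows, nr, nc), c = matrix(cols, nr, nc, byrow = TRUE))
}

.seg_input <- function(patch, coords) {
  array(c(patch, coords$r, coords$c), c(dim(patch), 3L))
}

.seg_patch_logits <- function(model, patch, coords) {
  if (identical(model$kind, "segmenter")) {
    nn_fcn_forward(model$net, .seg_input(patch, coords))$logit
  } else if (!is.null(model$logitFn)) {
    model$logitFn(patch)
  } else {
    stop("not a segmentation model")
  }
}

# Pad a matrix symmetrically with zeros up to at least (nr, nc); returns the
# padded matrix and the offset of the original content.
.pad_to <- function(m, nr, nc) {
  pr <- max(0L, nr - nrow(m)); pc <- max(0L, nc - ncol(m))
  r0 <- pr %/% 2L; c0 <- pc %/% 2L
  out <- matrix(0, nrow(m) + pr, ncol(m) + pc)
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  list(m = out, r0 = r0, c0 = c0)
}

# Sliding-window start positions (0-based) for extent W and patch p at a
# fractional overlap o: ceil((W - p) / (p (1 - o))) + 1 windows, evenly
# spaced so the last is flush with the border.
.window_starts <- function(W, p, overlap) {
  if (W <= p) return(0L)
  n <- ceiling((W - p) / (p * (1 - overlap))) + 1L
  unique(round(seq(0L, W - p, length.out = n)))
}

#' Train a single-structure 2D segmenter
#'
#' Trains the compact fully-convolutional backbone to segment one structure
#' on (pseudo-)planar images, minimizing a Dice + binary cross-entropy loss
#' with Adam and a piecewise learning-rate decay. Images are normalized to
#' their 99th percentile; each optimization step sees one random patch of
#' `cfg@patchHw` (images smaller than the patch are zero-padded). After each
#' epoch the model is scored by mean validation Dice (via
#' [slidingWindowSegment()]) and the best-scoring weights are kept.
#'
#' @param train,val lists of `list(image = PlanarImage, mask = LabelMask)`
#'   pairs; all masks must be 2D and share one structure.
#' @param cfg a [SegTrainConfig-class].
#' @return list with `model` (the best checkpoint, usable with
#'   [slidingWindowSegment()]) and `history` (data.frame: epoch, loss,
#'   val_dice).
#' @export
trainSegmenter <- function(train, val, cfg = SegTrainConfig()) {
  stopifnot(length(train) > 0, length(val) > 0, is(cfg, "SegTrainConfig"))
  structures <- unique(vapply(c(train, val),
                              function(p) p$mask@structure, character(1)))
  if (length(structures) != 1L)
    stop("all pairs in one training run must target a single structure, got: ",
         paste(structures, collapse = ", "))

  prep <- function(pairs) lapply(pairs, function(p) {
    list(img = pixels(percentileNormalize(p$image)),
         mask = p$mask@data)
  })
  tr <- prep(train)
  net <- nn_init_fcn(3L, c(8L, 8L), seed = cfg@seed)
  opt <- adam_init(net)
  model <- list(kind = "segmenter", net = net, structure = structures,
                patchHw = cfg@patchHw, backbone = cfg@backbone)
  class(model) <- "scintModel"

  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_dice = numeric())
  best <- list(dice = -Inf, net = net, epoch = 0L)
  ph <- cfg@patchHw
  with_seed(cfg@seed + 1L, {
    for (epoch in seq_len(cfg@epochs)) {
      lr <- lr_at_epoch(cfg@lr0, cfg@lrDecay, cfg@lrStep, epoch)
      ord <- rep(sample(seq_along(tr)), cfg@patchesPerImage)
      acc <- NULL; nacc <- 0L; epoch_loss <- 0
      for (k in seq_along(ord)) {
        i <- ord[k]
        img <- tr[[i]]$img; msk <- tr[[i]]$mask
        if (nrow(img) < ph[1] || ncol(img) < ph[2]) {
          pi_ <- .pad_to(img, ph[1], ph[2]); pm <- .pad_to(msk, ph[1], ph[2])
          img <- pi_$m; msk <- pm$m
        }
        r0 <- if (nrow(img) > ph[1]) sample.int(nrow(img) - ph[1], 1) else 0L
        c0 <- if (ncol(img) > ph[2]) sample.int(ncol(img) - ph[2], 1) else 0L
        patch <- img[r0 + seq_len(ph[1]), c0 + seq_len(ph[2]), drop = FALSE]
        target <- msk[r0 + seq_len(ph[1]), c0 + seq_len(ph[2]), drop = FALSE]
        coords <- .coord_channels(dim(img), r0, c0, ph[1], ph[2])
        cache <- nn_fcn_forward(net, .seg_input(patch, coords), keep = TRUE)
        lg <- seg_loss_grad(cache$logit, target)
        epoch_loss <- epoch_loss + lg$loss
        acc <- grad_accumulate(acc, nn_fcn_backward(net, cache, lg$dlogit))
        nacc <- nacc + 1L
        if (nacc >= cfg@batchSize || k == length(ord)) {
          st <- adam_step(net, opt, grad_scale(acc, 1 / nacc), lr)
          net <- st$net; opt <- st$opt
          acc <- NULL; nacc <- 0L
        }
      }
      model$net <- net
      dices <- vapply(val, function(p) {
        pred <- slidingWindowSegment(model, p$image, cfg@patchHw)
        diceScore(pred, p$mask)
      }, numeric(1))
      vd <- mean(dices)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  loss = epoch_loss / length(ord),
                                  val_dice = vd))
      if (vd > best$dice) best <- list(dice = vd, net = net, epoch = epoch)
    }
  })
  model$net <- best$net
  model$bestEpoch <- best$epoch
  model$bestValDice <- best$dice
  list(model = model, history = history)
}

#' Sliding-window segmentation inference
#'
#' Tiles the image with `patchHw` windows at the given fractional overlap,
#' averages the per-pixel logits of overlapping windows, and thresholds the
#' fused probability at 0.5. Images smaller than the patch are padded
#' symmetrically with zeros and the prediction cropped back.
#'
#' @param model a trained segmenter from [trainSegmenter()].
#' @param img a [PlanarImage-class] (normalized internally).
#' @param patchHw window size (rows, cols); defaults to the model's.
#' @param overlap fractional overlap between adjacent windows (default 0.5).
#' @return a binary 2D [LabelMask-class] of the image shape.
#' @export
slidingWindowSegment <- function(model, img, patchHw = model$patchHw,
                                 overlap = 0.5) {
  stopifnot(is(img, "PlanarImage"), overlap >= 0, overlap < 1)
  m <- pixels(img)
  if (identical(model$kind, "segmenter") && max(m) > 0) {
    m <- pixels(percentileNormalize(img))
  }
  pad <- .pad_to(m, patchHw[1], patchHw[2])
  mp <- pad$m
  acc <- matrix(0, nrow(mp), ncol(mp))
  cnt <- matrix(0, nrow(mp), ncol(mp))
  for (r0 in .window_starts(nrow(mp), patchHw[1], overlap)) {
    for (c0 in .window_starts(ncol(mp), patchHw[2], overlap)) {
      rows <- r0 + seq_len(patchHw[1]); cols <- c0 + seq_len(patchHw[2])
      patch <- mp[rows, cols, drop = FALSE]
      coords <- .coord_channels(dim(mp), r0, c0, patchHw[1], patchHw[2])
      lg <- .seg_patch_logits(model, patch, coords)
      acc[rows, cols] <- acc[rows, cols] + lg
      cnt[rows, cols] <- cnt[rows, cols] + 1
    }
  }
  fused <- acc / pmax(cnt, 1)
  # threshold 0.5 on the fused probability == sign of the mean logit
  pred <- (fused > 0) * 1
  pred <- pred[pad$r0 + seq_len(nrow(pixels(img))),
               pad$c0 + seq_len(ncol(pixels(img))), drop = FALSE]
  LabelMask(pred, model$structure %||% "whole_heart", img@spacingMm)
}

#' Dice overlap score
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param a,b binary [LabelMask-class] objects (or plain binary matrices) of
#'   equal shape.
#' @return scalar in `[0, 1]`.
#' @examples
#' m1 <- matrix(c(1, 1, 0, 0), 2); m2 <- matrix(c(1, 0, 1, 0), 2)
#' diceScore(LabelMask(m1, "lv"), LabelMask(m2, "lv"))
#' @export
diceScore <- function(a, b) {
  da <- if (is(a, "LabelMask")) a@data else a
  db <- if (is(b, "LabelMask")) b@data else b
  if (!identical(dim(da), dim(db))) stop("masks must have the same shape")
  if (!is_binary(da) || !is_binary(db)) stop("masks must be binary")
  sa <- sum(da); sb <- sum(db)
  if (sa + sb == 0) return(1)
  2 * sum(da * db) / (sa + sb)
}

#' Ground-truth segmentation pairs from a synthetic cohort
#'
#' Collects (image, mask) training pairs for one structure from labelled
#' cases carrying ground-truth masks. Posterior views are paired with the
#' left-right mirrored mask.
#'
#' @param cases list of [LabeledCase-class] with attached masks.
#' @param structure `"lv"`, `"whole_heart"` or `"ribcage"`.
#' @param views views to include (default anterior and posterior).
#' @return list of `list(image, mask)` pairs.
#' @export
segmentationPairs <- function(cases, structure,
                              views = c("anterior", "posterior")) {
  out <- list()
  for (cs in cases) {
    m <- caseMasks(cs)[[structure]]
    if (is.null(m)) stop("case ", patientId(cs), " has no '", structure,
                         "' mask")
    for (v in intersect(views, names(caseImages(cs)))) {
      msk <- if (v == "posterior") {
        LabelMask(mirror_lr(m@data), m@structure, m@spacingMm)
      } else m
      out[[length(out) + 1L]] <- list(image = caseImages(cs)[[v]], mask = msk)
    }
  }
  out
}
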