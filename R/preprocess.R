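#' @include AllClasses.R utils.R
NULL

#' Percentile intensity normalization
#'
#' Clips pixel values between zero and the image's own `percentile`-th
#' percentile (99 by default) and divides by that percentile, mapping the
#' image into `[0, 1]`. Normalizing to P99 rather than the maximum makes the
#' scale robust to isolated hot noise pixels; scintigraphy counts are not
#' quantitative, so each image is normalized to itself. The percentile is
#' the linear-interpolation (type 7) quantile over all pixels.
#'
#' @param img a [PlanarImage-class] with at least one positive pixel.
#' @param spec a [NormalizationSpec-class].
#' @return the normalized [PlanarImage-class]; its `percentile`-th
#'   percentile equals 1.
#' @examples
#' img <- PlanarImage(matrix(0:99, 10, 10))
#' range(pixels(percentileNormalize(img)))
#' @export
percentileNormalize <- function(img, spec = NormalizationSpec()) {
  stopifnot(is(img, "PlanarImage"), is(spec, "NormalizationSpec"))
  p <- img@pixels
  ceiling_ <- pctl(p, spec@percentile)
  if (ceiling_ <= 0)
    stop("cannot normalize: the ", spec@percentile,
         "th percentile is zero (all-zero image?)")
  out <- pmin(pmax(p, spec@clipLow), ceiling_) / ceiling_
  PlanarImage(matrix(out, nrow(p)), img@spacingMm, img@view, img@patientId,
              img@acquisitionId)
}

#' Summation image from anterior and posterior views
#'
#' Adds the anterior view and the left-right mirrored posterior view,
#' yielding an image with better counting statistics that is geometrically
#' comparable to a pseudo-planar projection.
#'
#' @param anterior,posterior [PlanarImage-class] views of the same
#'   acquisition (equal shape and spacing).
#' @return a [PlanarImage-class] with view `"summation"`.
#' @export
makeSummation <- function(anterior, posterior) {
  stopifnot(is(anterior, "PlanarImage"), is(posterior, "PlanarImage"))
  if (!identical(dim(anterior@pixels), dim(posterior@pixels)))
    stop("anterior and posterior views must have the same shape")
  if (!isTRUE(all.equal(anterior@spacingMm, posterior@spacingMm,
                        tolerance = 1e-9)))
    stop("anterior and posterior views must have the same spacing")
  out <- anterior@pixels + mirror_lr(posterior@pixels)
  PlanarImage(out, anterior@spacingMm, "summation", anterior@patientId,
              anterior@acquisitionId)
}

#' Prepare a crop as classifier input
#'
#' Resamples a cropped planar image to the network's input spacing,
#' normalizes it to its 99th percentile, and letterboxes it (uniform
#' downscale if needed, then symmetric zero padding) into a fixed
#' `inputHw` grid.
#'
#' @param img a cropped [PlanarImage-class].
#' @param inputHw target (rows, cols).
#' @param inputSpacingMm resampling target spacing (mm).
#' @param normalize normalize to P99 before letterboxing (default TRUE).
#' @return a [PlanarImage-class] of size `inputHw`.
#' @export
prepareClassifierInput <- function(img, inputHw = c(64L, 64L),
                                   inputSpacingMm = 2.8, normalize = TRUE) {
  x <- resamplePlanar(img, inputSpacingMm, "linear")
  if (normalize) x <- percentileNormalize(x)
  p <- x@pixels
  sc <- min(inputHw / dim(p), 1)
  if (sc < 1) {
    x <- resamplePlanar(x, inputSpacingMm / sc, "linear")
    p <- x@pixels
    # guard against rounding overshoot
    p <- p[seq_len(min(nrow(p), inputHw[1])),
           seq_len(min(ncol(p), inputHw[2])), drop = FALSE]
  }
  out <- matrix(0, inputHw[1], inputHw[2])
  r0 <- (inputHw[1] - nrow(p)) %/% 2
  c0 <- (inputHw[2] - ncol(p)) %/% 2
  out[r0 + seq_len(nrow(p)), c0 + seq_len(ncol(p))] <- p
  PlanarImage(out, rep(inputSpacingMm, 2) / sc, img@view, img@patientId,
              img@acquisitionId)
}
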