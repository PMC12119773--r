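#' @include AllClasses.R
NULL

# Condition signalled when a mask has no foreground; localizeAll catches it
# and applies the thorax-band fallback.
.empty_mask_error <- function(structure) {
  structure(class = c("emptyMaskError", "error", "condition"),
            list(message = paste0("mask '", structure, "' is empty"),
                 call = sys.call(-1)))
}

#' Tight bounding box of a mask
#'
#' Returns the smallest 0-based, half-open box containing all foreground
#' pixels. An empty mask signals an `emptyMaskError` condition so callers
#' can apply a fallback.
#'
#' @param mask a binary 2D [LabelMask-class].
#' @return a [CropRegion-class] with zero margin.
#' @export
maskBbox <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  d <- mask@data
  if (length(dim(d)) != 2L) stop("maskBbox expects a 2D mask")
  idx <- which(d == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop(.empty_mask_error(mask@structure))
  CropRegion(min(idx[, 1]) - 1L, max(idx[, 1]), min(idx[, 2]) - 1L,
             max(idx[, 2]), strategy = mask@structure, marginMm = 0)
}

#' Crop an image around a region with a physical margin
#'
#' Expands the box by `round(marginMm / spacing)` pixels per axis, clamps it
#' to the image bounds, and returns the cropped pixels together with the
#' realized region. At the default 2.8 mm spacing a 70 mm margin expands the
#' box by 25 pixels on each side.
#'
#' @param img a [PlanarImage-class].
#' @param box a [CropRegion-class] within the image.
#' @param marginMm margin in mm (>= 0).
#' @return list with `image` (cropped [PlanarImage-class]) and `region`
#'   (the realized, clamped [CropRegion-class]).
#' @export
cropWithMargin <- function(img, box, marginMm = 0) {
  stopifnot(is(img, "PlanarImage"), is(box, "CropRegion"), marginMm >= 0)
  p <- img@pixels
  mr <- round(marginMm / img@spacingMm[1])
  mc <- round(marginMm / img@spacingMm[2])
  r0 <- max(0L, box@rowMin - mr); r1 <- min(nrow(p), box@rowMax + mr)
  c0 <- max(0L, box@colMin - mc); c1 <- min(ncol(p), box@colMax + mc)
  region <- CropRegion(r0, r1, c0, c1, box@strategy, marginMm)
  crop <- p[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  list(image = PlanarImage(crop, img@spacingMm, img@view, img@patientId,
                           img@acquisitionId),
       region = region)
}

.fallback_region <- function(img, strategy) {
  nr <- nrow(img@pixels); nc <- ncol(img@pixels)
  # central 50%-height thorax band, full width
  CropRegion(0L, nr, as.integer(floor(nc * 0.25)),
             as.integer(ceiling(nc * 0.75)), strategy, 0)
}

#' Produce the three per-strategy classification crops
#'
#' Crops the image around each predicted structure with the corresponding
#' physical margin: 70 mm around the LV, 50 mm around the whole heart and
#' 1 mm around the ribcage. An empty predicted mask for a structure falls
#' back to a central thorax band (with a warning); if all three masks are
#' empty the full image is returned for every strategy.
#'
#' @param img a [PlanarImage-class].
#' @param masks named list of predicted 2D [LabelMask-class]s (`lv`,
#'   `whole_heart`, `ribcage`).
#' @param marginsMm named numeric margins per strategy (defaults 70/50/1 mm).
#' @return named list (per strategy) of `list(image, region)`.
#' @export
localizeAll <- function(img, masks, marginsMm = .DEFAULT_MARGINS_MM) {
  stopifnot(is(img, "PlanarImage"))
  all_empty <- all(vapply(.CROP_STRATEGIES, function(s) {
    is.null(masks[[s]]) || sum(masks[[s]]@data) == 0
  }, logical(1)))
  if (all_empty) {
    warning("all structure masks are empty; returning the full image for ",
            "every crop strategy")
    full <- CropRegion(0L, nrow(img@pixels), 0L, ncol(img@pixels))
    return(stats::setNames(lapply(.CROP_STRATEGIES, function(s) {
      r <- full; r@strategy <- s
      list(image = img, region = r)
    }), .CROP_STRATEGIES))
  }
  out <- list()
  for (s in .CROP_STRATEGIES) {
    box <- tryCatch(maskBbox(masks[[s]]), emptyMaskError = function(e) NULL,
                    error = function(e) {
                      if (is.null(masks[[s]])) NULL else stop(e)
                    })
    if (is.null(box)) {
      warning("empty '", s, "' mask; using central thorax-band fallback")
      box <- .fallback_region(img, s)
    }
    out[[s]] <- cropWithMargin(img, box, marginsMm[[s]])
  }
  out
}
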