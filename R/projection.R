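#' @include AllClasses.R utils.R
NULL

# Sum a 3D array along one axis, returning the matrix of the two kept axes.
.sum_along <- function(v, axis) {
  d <- dim(v)
  if (axis != 3L) v <- aperm(v, c(setdiff(1:3, axis), axis))
  dk <- dim(v)[1:2]
  dim(v) <- c(prod(dk), dim(v)[3])
  matrix(rowSums(v), dk[1], dk[2])
}

#' Pseudo-planar projection of an activity volume
#'
#' Sums the volume along its declared anterior-posterior axis, producing a
#' 2D pseudo-planar image in the plane of the two retained axes. Total
#' counts are conserved exactly; the retained axes keep their spacing.
#'
#' @param vol an [ActivityVolume-class] with a declared `apAxis`.
#' @return a [PlanarImage-class] with view `"pseudo"`.
#' @examples
#' v <- ActivityVolume(array(1, c(3, 3, 3)))
#' sum(pixels(projectVolume(v)))  # 27, equal to the volume total
#' @export
projectVolume <- function(vol) {
  stopifnot(is(vol, "ActivityVolume"))
  ap <- vol@apAxis
  if (is.na(ap)) stop("volume has no declared anterior-posterior axis")
  keep <- setdiff(1:3, ap)
  px <- .sum_along(vol@voxels, ap)
  PlanarImage(px, spacingMm = vol@spacingMm[keep], view = "pseudo")
}

#' Union projection of a 3D mask
#'
#' A 2D pixel is foreground iff any voxel along the anterior-posterior ray
#' is foreground (logical OR along the third mask axis). The structure tag
#' and in-plane spacing are preserved.
#'
#' @param mask3d a binary 3D [LabelMask-class].
#' @return a 2D [LabelMask-class].
#' @export
projectMask <- function(mask3d) {
  stopifnot(is(mask3d, "LabelMask"))
  d <- mask3d@data
  if (length(dim(d)) != 3L) stop("projectMask expects a 3D mask")
  if (!is_binary(d)) stop("mask must be binary")
  px <- (.sum_along(d, 3L) > 0) * 1
  LabelMask(px, mask3d@structure, mask3d@spacingMm[1:2])
}

# Structuring-element voxel offsets for a physical radius: per-axis voxel
# radius is round(radius / spacing), at least 1 when radius > 0; offsets
# satisfy sum((d_i / r_i)^2) <= 1 (anisotropy-aware ball).
.ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(1L, round(radius_mm / spacing))
  grids <- lapply(r, function(ri) -ri:ri)
  offs <- as.matrix(expand.grid(grids))
  q <- rowSums(sweep(offs, 2, r, "/")^2)
  offs[q <= 1 + 1e-12, , drop = FALSE]
}

.shift_or <- function(acc, m, off) {
  d <- dim(m)
  nd <- length(d)
  src <- dst <- vector("list", nd)
  for (i in seq_len(nd)) {
    o <- off[i]
    if (o >= 0) {
      src[[i]] <- seq_len(d[i] - o)
      dst[[i]] <- seq_len(d[i] - o) + o
    } else {
      src[[i]] <- seq_len(d[i] + o) - o
      dst[[i]] <- seq_len(d[i] + o)
    }
    if (length(src[[i]]) == 0L) return(acc)
  }
  if (nd == 2L) {
    acc[dst[[1]], dst[[2]]] <- acc[dst[[1]], dst[[2]]] | m[src[[1]], src[[2]]]
  } else {
    acc[dst[[1]], dst[[2]], dst[[3]]] <-
      acc[dst[[1]], dst[[2]], dst[[3]]] | m[src[[1]], src[[2]], src[[3]]]
  }
  acc
}

#' Morphological dilation of a mask by a physical radius
#'
#' Dilates a binary 2D or 3D mask with a ball (disk) structuring element of
#' physical radius `radiusMm`. The radius is converted to voxels per axis
#' via the mask spacing and rounded to the nearest integer, never below one
#' voxel when the radius is positive. `radiusMm = 0` is the identity.
#'
#' @param mask a [LabelMask-class].
#' @param radiusMm dilation radius in mm (>= 0).
#' @return the dilated [LabelMask-class] (always a superset of the input).
#' @export
dilateMask <- function(mask, radiusMm) {
  stopifnot(is(mask, "LabelMask"))
  if (radiusMm < 0) stop("radius must be >= 0")
  if (radiusMm == 0) return(mask)
  m <- mask@data > 0
  offs <- .ball_offsets(radiusMm, mask@spacingMm)
  acc <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) acc <- .shift_or(acc, m, offs[i, ])
  LabelMask(array(as.numeric(acc), dim(m)), mask@structure, mask@spacingMm)
}

#' Resample a planar image to a target pixel spacing
#'
#' The output grid spans the same physical extent at the requested spacing;
#' the number of pixels per axis is `round(extent / target)`. Images use
#' bilinear interpolation (`"linear"`), masks nearest-neighbour
#' (`"nearest"`) to stay binary. Requesting the source spacing returns the
#' input pixels unchanged.
#'
#' @param img a [PlanarImage-class].
#' @param targetSpacingMm positive pair (scalar recycled), mm.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return a resampled [PlanarImage-class].
#' @export
resamplePlanar <- function(img, targetSpacingMm,
                           interpolation = c("linear", "nearest")) {
  stopifnot(is(img, "PlanarImage"))
  interpolation <- match.arg(interpolation)
  if (length(targetSpacingMm) == 1L)
    targetSpacingMm <- rep(targetSpacingMm, 2L)
  if (any(!is.finite(targetSpacingMm)) || any(targetSpacingMm <= 0))
    stop("target spacing must be positive")
  sp <- img@spacingMm
  if (isTRUE(all.equal(sp, targetSpacingMm, tolerance = 1e-12))) return(img)
  p <- img@pixels
  extent <- dim(p) * sp
  nd <- pmax(1L, round(extent / targetSpacingMm))
  # map output pixel centers into continuous input pixel index space
  ctr_out_r <- (seq_len(nd[1]) - 0.5) * targetSpacingMm[1]
  ctr_out_c <- (seq_len(nd[2]) - 0.5) * targetSpacingMm[2]
  ri <- ctr_out_r / sp[1] + 0.5
  ci <- ctr_out_c / sp[2] + 0.5
  if (interpolation == "nearest") {
    rr <- pmin(pmax(round(ri), 1), nrow(p))
    cc <- pmin(pmax(round(ci), 1), ncol(p))
    out <- p[rr, cc, drop = FALSE]
  } else {
    grid_r <- rep(ri, times = nd[2])
    grid_c <- rep(ci, each = nd[1])
    out <- matrix(bilinear_at(p, grid_r, grid_c), nd[1], nd[2])
  }
  PlanarImage(out, targetSpacingMm, img@view, img@patientId,
              img@acquisitionId)
}
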