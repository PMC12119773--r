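#' @include AllClasses.R utils.R
NULL

#' One uptake-augmented image
#'
#' @slot base the unaugmented [PlanarImage-class].
#' @slot lvMask 2D LV [LabelMask-class] in the base frame.
#' @slot fraction uptake level as a fraction of the base image's P99.
#' @slot image the augmented [PlanarImage-class] (equals `base` at
#'   fraction 0; elsewhere `image >= base` with the difference supported
#'   only on the LV mask).
#' @export
setClass("AugmentedCase",
  representation(base = "PlanarImage", lvMask = "LabelMask",
                 fraction = "numeric", image = "PlanarImage"))

setValidity("AugmentedCase", function(object) {
  if (object@fraction < 0) return("fraction must be >= 0")
  d <- object@image@pixels - object@base@pixels
  if (any(d < -1e-9)) return("image must dominate base")
  if (any(d[object@lvMask@data == 0] > 1e-9))
    return("added uptake must be supported on the LV mask")
  TRUE
})

#' @rdname AugmentedCase-class
#' @param x an `AugmentedCase`.
#' @export
setMethod("pixels", "AugmentedCase", function(x) x@image@pixels)

setMethod("show", "AugmentedCase", function(object) {
  cat(sprintf("AugmentedCase: fraction %.2f of base P99, %d x %d px\n",
              object@fraction, nrow(object@image@pixels),
              ncol(object@image@pixels)))
})

#' Simulate graded cardiac uptake inside the LV mask
#'
#' Draws an i.i.d. uniform random texture on the LV support and rescales it
#' so its mean equals `fraction` times the 99th percentile of the *base*
#' image, then adds it to the base. Coupling the level to the base image's
#' P99 (never the augmented image's) keeps levels comparable across
#' fractions. Fraction 0 returns the base unchanged.
#'
#' @param base a [PlanarImage-class].
#' @param lvMask non-empty 2D LV [LabelMask-class] aligned with `base`.
#' @param fraction uptake level (fraction of base P99, >= 0).
#' @param seed RNG seed for the texture.
#' @return an [AugmentedCase-class].
#' @examples
#' img <- PlanarImage(matrix(runif(64 * 64), 64))
#' m <- matrix(0, 64, 64); m[28:36, 28:36] <- 1
#' aug <- simulateUptake(img, LabelMask(m, "lv"), fraction = 1.5, seed = 1)
#' @export
simulateUptake <- function(base, lvMask, fraction, seed = 1L) {
  stopifnot(is(base, "PlanarImage"), is(lvMask, "LabelMask"))
  if (length(dim(lvMask@data)) != 2L ||
      !identical(dim(lvMask@data), dim(base@pixels)))
    stop("LV mask must be 2D and aligned with the base image")
  if (sum(lvMask@data) == 0) stop("LV mask is empty")
  if (fraction < 0) stop("fraction must be >= 0")
  if (fraction == 0) {
    return(new("AugmentedCase", base = base, lvMask = lvMask, fraction = 0,
               image = base))
  }
  support <- which(lvMask@data == 1)
  target_mean <- fraction * pctl(base@pixels, 99)
  u <- with_seed(seed, runif(length(support)))
  texture <- u * (target_mean / mean(u))
  px <- base@pixels
  px[support] <- px[support] + texture
  img <- PlanarImage(px, base@spacingMm, base@view, base@patientId,
                     base@acquisitionId)
  new("AugmentedCase", base = base, lvMask = lvMask, fraction = fraction,
      image = img)
}

#' Uptake levels used by a scheme
#'
#' The candidate grid runs from `minFraction` to `maxFraction` in steps of
#' `step`; the `nAugmentedPerCase` lowest levels are used.
#'
#' @param scheme an [UptakeLevelScheme-class].
#' @return numeric vector of uptake fractions (length `nAugmentedPerCase`).
#' @export
schemeLevels <- function(scheme) {
  grid <- seq(scheme@minFraction, scheme@maxFraction, by = scheme@step)
  if (scheme@nAugmentedPerCase > length(grid))
    stop("scheme asks for more levels than the grid provides")
  grid[seq_len(scheme@nAugmentedPerCase)]
}

#' Expand one case into a graded uptake series
#'
#' Produces the original image (fraction 0) plus `nAugmentedPerCase`
#' uptake-augmented copies at the scheme's levels, spanning normal to severe
#' cardiac uptake. With the default scheme each case yields 29 images.
#'
#' @param base a [PlanarImage-class].
#' @param lvMask 2D LV [LabelMask-class] aligned with `base`.
#' @param scheme an [UptakeLevelScheme-class].
#' @param seed RNG seed; each level gets an independent texture.
#' @return list of [AugmentedCase-class], the original first.
#' @export
expandCase <- function(base, lvMask, scheme = UptakeLevelScheme(),
                       seed = 1L) {
  stopifnot(is(scheme, "UptakeLevelScheme"))
  levels_ <- schemeLevels(scheme)
  subseeds <- with_seed(seed,
                        sample.int(.Machine$integer.max - 1L,
                                   length(levels_) + 1L))
  out <- vector("list", length(levels_) + 1L)
  out[[1]] <- simulateUptake(base, lvMask, 0, subseeds[1])
  for (i in seq_along(levels_)) {
    out[[i + 1L]] <- simulateUptake(base, lvMask, levels_[i],
                                    subseeds[i + 1L])
  }
  out
}

# Random in-plane rotation about the image center (bilinear, zero fill).
.rotate_image <- function(m, theta_deg) {
  th <- theta_deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  gr <- rep(seq_len(nr), times = nc) - cr
  gc <- rep(seq_len(nc), each = nr) - cc
  # sample source position by inverse rotation
  sr <- cos(th) * gr - sin(th) * gc + cr
  sc <- sin(th) * gr + cos(th) * gc + cc
  inside <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  vals <- numeric(nr * nc)
  vals[inside] <- bilinear_at(m, sr[inside], sc[inside])
  matrix(vals, nr, nc)
}

#' Class-balancing photometric/geometric augmentation
#'
#' Brings every class up to `targetPerClass` images by randomly composing
#' small rotations, additive Gaussian noise and horizontal flips of
#' resampled originals. Originals are always retained; augmentation is
#' deterministic for a fixed seed.
#'
#' @param cases list of `list(image = PlanarImage, label = <class>)`.
#' @param targetPerClass target count per class (>= the largest class).
#' @param seed RNG seed.
#' @param thetaMaxDeg rotation range, degrees (default 10).
#' @param noiseSd additive Gaussian noise, as a fraction of the image P99
#'   (default 0.02).
#' @return list of `list(image, label)` with `targetPerClass` per class.
#' @export
balanceClasses <- function(cases, targetPerClass, seed = 1L,
                           thetaMaxDeg = 10, noiseSd = 0.02) {
  labels <- vapply(cases, function(x) as.character(x$label), character(1))
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts == 0)) stop("every class must have at least one case")
  if (targetPerClass < max(counts))
    stop("targetPerClass must be >= the largest class size")
  out <- cases
  with_seed(seed, {
    for (cl in classes) {
      members <- which(labels == cl)
      n_extra <- targetPerClass - length(members)
      if (n_extra <= 0) next
      picks <- sample(members, n_extra, replace = TRUE)
      for (p in picks) {
        img <- cases[[p]]$image
        m <- img@pixels
        m <- .rotate_image(m, runif(1, -thetaMaxDeg, thetaMaxDeg))
        if (runif(1) < 0.5) m <- mirror_lr(m)
        m <- m + rnorm(length(m), 0, noiseSd * pctl(img@pixels, 99))
        m <- pmax(m, 0)
        out[[length(out) + 1L]] <- list(
          image = PlanarImage(matrix(m, nrow(m)), img@spacingMm, img@view,
                              img@patientId, img@acquisitionId),
          label = cases[[p]]$label)
      }
    }
  })
  out
}
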