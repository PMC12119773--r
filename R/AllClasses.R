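#' @include scintigrade-package.R
NULL

## ---------------------------------------------------------------- images ----

#' Planar scintigraphy image
#'
#' A single 2D planar view with physical pixel spacing. By convention the
#' first matrix dimension is the patient left-right axis and the second the
#' cranio-caudal axis; a left-right mirror therefore reverses rows.
#'
#' @slot pixels numeric matrix of nonnegative counts (or normalized values).
#' @slot spacingMm positive numeric pair, pixel spacing in mm per axis.
#' @slot view one of `"anterior"`, `"posterior"`, `"summation"`, `"pseudo"`.
#' @slot patientId,acquisitionId identifier strings (may be empty).
#' @export
setClass("PlanarImage",
  representation(pixels = "matrix", spacingMm = "numeric", view = "character",
                 patientId = "character", acquisitionId = "character"))

setValidity("PlanarImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (!all(is.finite(p))) return("pixels must be finite")
  if (any(p < 0)) return("pixels must be nonnegative")
  if (length(object@spacingMm) != 2L || any(!is.finite(object@spacingMm)) ||
      any(object@spacingMm <= 0)) return("spacingMm must be two positive values")
  if (length(object@view) != 1L || !object@view %in% .VIEWS)
    return(sprintf("view must be one of: %s", paste(.VIEWS, collapse = ", ")))
  TRUE
})

#' Construct a [PlanarImage-class]
#'
#' @param pixels numeric matrix of nonnegative pixel values.
#' @param spacingMm pixel spacing in mm (length-2, recycled from length 1).
#' @param view view tag.
#' @param patientId,acquisitionId identifier strings.
#' @return a `PlanarImage`.
#' @examples
#' img <- PlanarImage(matrix(1, 4, 4), spacingMm = 2.8)
#' @export
PlanarImage <- function(pixels, spacingMm = c(2.8, 2.8), view = "pseudo",
                        patientId = "", acquisitionId = "") {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 2L)
  new("PlanarImage", pixels = pixels, spacingMm = as.numeric(spacingMm),
      view = view, patientId = patientId, acquisitionId = acquisitionId)
}

#' 3D activity volume
#'
#' Voxelized tracer count distribution with physical spacing. Grid axes are
#' (left-right, cranio-caudal, anterior-posterior); `apAxis` records which
#' array dimension is the anterior-posterior direction used for pseudo-planar
#' projection.
#'
#' @slot voxels nonnegative numeric 3D array.
#' @slot spacingMm positive numeric triple (mm).
#' @slot apAxis integer in 1..3 (NA if undeclared).
#' @export
setClass("ActivityVolume",
  representation(voxels = "array", spacingMm = "numeric", apAxis = "integer"))

setValidity("ActivityVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (!all(is.finite(v))) return("voxels must be finite")
  if (any(v < 0)) return("voxels must be nonnegative")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    return("spacingMm must be three positive values")
  if (length(object@apAxis) != 1L ||
      (!is.na(object@apAxis) && !object@apAxis %in% 1:3))
    return("apAxis must be 1, 2, 3 or NA")
  TRUE
})

#' Construct an [ActivityVolume-class]
#' @param voxels nonnegative numeric 3D array.
#' @param spacingMm voxel spacing in mm (length-3, recycled from length 1).
#' @param apAxis which array dimension is anterior-posterior (default 3).
#' @return an `ActivityVolume`.
#' @export
ActivityVolume <- function(voxels, spacingMm = c(2.8, 2.8, 2.8), apAxis = 3L) {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  new("ActivityVolume", voxels = voxels, spacingMm = as.numeric(spacingMm),
      apAxis = as.integer(apAxis))
}

#' Binary structure mask (2D or 3D)
#'
#' @slot data binary numeric array (matrix for 2D masks).
#' @slot structure the labelled structure: `"lv"`, `"whole_heart"`,
#'   `"ribcage"`, or `"saliency"` for thresholded saliency overlays.
#' @slot spacingMm positive spacing matching the array dimensionality.
#' @export
setClass("LabelMask",
  representation(data = "array", structure = "character", spacingMm = "numeric"))

setValidity("LabelMask", function(object) {
  d <- object@data
  nd <- length(dim(d))
  if (!nd %in% 2:3) return("mask must be 2D or 3D")
  if (!is_binary(d)) return("mask values must be 0 or 1")
  if (length(object@spacingMm) != nd || any(object@spacingMm <= 0))
    return("spacingMm must match mask dimensionality and be positive")
  if (!object@structure %in% c(.STRUCTURES, "saliency"))
    return("unknown structure tag")
  TRUE
})

#' Construct a [LabelMask-class]
#' @param data binary matrix (2D) or array (3D); logical input is accepted.
#' @param structure structure tag (`"lv"`, `"whole_heart"`, `"ribcage"`).
#' @param spacingMm spacing in mm, one value per mask dimension (a scalar is
#'   recycled).
#' @return a `LabelMask`.
#' @export
LabelMask <- function(data, structure, spacingMm = 2.8) {
  if (is.logical(data)) {
    dd <- dim(data)
    data <- array(as.numeric(data), dd)
  }
  if (is.matrix(data)) data <- as.matrix(data)
  nd <- length(dim(data))
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, nd)
  new("LabelMask", data = data, structure = structure,
      spacingMm = as.numeric(spacingMm))
}

#' Aligned set of 3D anatomy masks for one phantom
#'
#' Holds the `lv`, `whole_heart` and `ribcage` masks on the same grid as the
#' companion [ActivityVolume-class]. Validity enforces that the LV is a
#' strict, non-empty subset of the whole heart.
#'
#' @slot masks named list of 3D [LabelMask-class] objects.
#' @export
setClass("AnatomySet", representation(masks = "list"))

setValidity("AnatomySet", function(object) {
  m <- object@masks
  if (!all(.STRUCTURES %in% names(m)))
    return("masks must include lv, whole_heart and ribcage")
  if (!all(vapply(m, function(x) is(x, "LabelMask"), logical(1))))
    return("all masks must be LabelMask objects")
  dims <- lapply(m, function(x) dim(x@data))
  if (length(unique(dims)) != 1L) return("masks must share one grid")
  if (length(dims[[1]]) != 3L) return("anatomy masks must be 3D")
  for (s in .STRUCTURES) if (sum(m[[s]]@data) == 0) {
    return(sprintf("mask '%s' is empty", s))
  }
  lv <- m$lv@data; wh <- m$whole_heart@data
  if (any(lv == 1 & wh == 0)) return("lv must be contained in whole_heart")
  if (sum(lv) >= sum(wh)) return("lv must be a strict subset of whole_heart")
  TRUE
})

#' Construct an [AnatomySet-class]
#' @param masks named list with elements `lv`, `whole_heart`, `ribcage`.
#' @return an `AnatomySet`.
#' @export
AnatomySet <- function(masks) new("AnatomySet", masks = masks)

#' One labelled acquisition of a (synthetic) patient
#'
#' @slot patientId,acquisitionId identifier strings.
#' @slot grade integer Perugini-style grade in 0..3 (-1 allowed for unlabelled
#'   screening cases).
#' @slot uptakeFraction simulated LV uptake level as a fraction of the
#'   baseline image's 99th percentile (NA for real data).
#' @slot images named list of [PlanarImage-class] views (at least `anterior`).
#' @slot masks named list of 2D ground-truth [LabelMask-class]s in the
#'   anterior frame (may be empty for non-synthetic data).
#' @export
setClass("LabeledCase",
  representation(patientId = "character", acquisitionId = "character",
                 grade = "integer", uptakeFraction = "numeric",
                 images = "list", masks = "list"))

setValidity("LabeledCase", function(object) {
  if (!object@grade %in% c(-1L, 0L, 1L, 2L, 3L))
    return("grade must be in {0,1,2,3} (-1 = unlabelled)")
  if (!"anterior" %in% names(object@images))
    return("at least the anterior view must be present")
  if (!all(vapply(object@images, function(x) is(x, "PlanarImage"), logical(1))))
    return("images must be PlanarImage objects")
  TRUE
})

#' Construct a [LabeledCase-class]
#' @param patientId,acquisitionId identifier strings.
#' @param grade integer grade 0..3 (-1 for unlabelled).
#' @param images named list of [PlanarImage-class] views.
#' @param uptakeFraction simulated uptake fraction (NA for real data).
#' @param masks optional named list of 2D ground-truth masks.
#' @return a `LabeledCase`.
#' @export
LabeledCase <- function(patientId, acquisitionId, grade, images,
                        uptakeFraction = NA_real_, masks = list()) {
  new("LabeledCase", patientId = patientId, acquisitionId = acquisitionId,
      grade = as.integer(grade), uptakeFraction = as.numeric(uptakeFraction),
      images = images, masks = masks)
}

## ------------------------------------------------- probabilities, metrics ----

#' Per-class probability vector with model provenance
#'
#' @slot p numeric probability vector (two classes), summing to 1.
#' @slot provenance list with elements `fold`, `crop`, `view` describing the
#'   model that produced the prediction (NA where not applicable).
#' @export
setClass("ClassProbabilities",
  representation(p = "numeric", provenance = "list"))

setValidity("ClassProbabilities", function(object) {
  p <- object@p
  if (length(p) < 2L) return("need at least two class probabilities")
  if (any(!is.finite(p)) || any(p < 0)) return("probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1 (1e-9)")
  TRUE
})

#' Construct a [ClassProbabilities-class]
#' @param p probability vector summing to 1.
#' @param fold,crop,view provenance of the producing model.
#' @return a `ClassProbabilities`.
#' @examples
#' ClassProbabilities(c(0.45, 0.55), fold = 1, crop = "whole_heart")
#' @export
ClassProbabilities <- function(p, fold = NA, crop = NA_character_,
                               view = NA_character_) {
  new("ClassProbabilities", p = as.numeric(p),
      provenance = list(fold = fold, crop = crop, view = view))
}

#' Two-stage ensemble output
#'
#' @slot averagedP final averaged [ClassProbabilities-class].
#' @slot decision predicted class index (0-based).
#' @slot members the input per-model probabilities.
#' @slot stage1 per-(crop,view) group means from the first averaging stage.
#' @export
setClass("EnsembleResult",
  representation(averagedP = "ClassProbabilities", decision = "integer",
                 members = "list", stage1 = "list"))

setValidity("EnsembleResult", function(object) {
  if (length(object@members) == 0L) return("members must be non-empty")
  if (object@decision != (which.max(object@averagedP@p) - 1L))
    return("decision must equal argmax of averagedP")
  TRUE
})

#' Classification metrics report
#'
#' Binary-classification summary: F1, sensitivity, specificity, precision,
#' accuracy, balanced accuracy (BAC, the mean of sensitivity and
#' specificity), AUC (Mann-Whitney statistic), confusion counts and a ROC
#' curve. Undefined quantities (e.g. AUC on a single-class label set) are NA.
#'
#' @slot f1,sensitivity,specificity,precision,accuracy,bac,auc scalars in
#'   `[0,1]` or NA.
#' @slot confusion named integer vector `TP`, `FP`, `TN`, `FN`.
#' @slot roc data.frame with columns `fpr`, `tpr`.
#' @export
setClass("MetricsReport",
  representation(f1 = "numeric", sensitivity = "numeric",
                 specificity = "numeric", precision = "numeric",
                 accuracy = "numeric", bac = "numeric", auc = "numeric",
                 confusion = "integer", roc = "data.frame"))

setValidity("MetricsReport", function(object) {
  cf <- object@confusion
  if (!all(c("TP", "FP", "TN", "FN") %in% names(cf)))
    return("confusion must have TP, FP, TN, FN")
  se <- object@sensitivity; sp <- object@specificity; bac <- object@bac
  if (is.finite(se) && is.finite(sp) && is.finite(bac) &&
      abs(bac - (se + sp) / 2) > 1e-12)
    return("bac must equal (sensitivity + specificity) / 2")
  TRUE
})

#' Saliency map
#'
#' @slot values 2D map rescaled to `[0,1]`, aligned with the classifier input.
#' @slot method `"gradcam"` or `"occlusion"`.
#' @slot targetClass class index (0-based) the map explains.
#' @slot threshold optional overlay threshold (NA when unset).
#' @export
setClass("SaliencyMap",
  representation(values = "matrix", method = "character",
                 targetClass = "integer", threshold = "numeric"))

setValidity("SaliencyMap", function(object) {
  v <- object@values
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    return("values must lie in [0,1]")
  if (!object@method %in% c("gradcam", "occlusion"))
    return("method must be gradcam or occlusion")
  TRUE
})

#' Crop region in pixel coordinates
#'
#' Bounds are 0-based, half-open (`rowMin <= r < rowMax`), recorded together
#' with the cropping strategy and the physical margin that produced them.
#'
#' @slot rowMin,rowMax,colMin,colMax integer pixel bounds.
#' @slot strategy `"lv"`, `"whole_heart"` or `"ribcage"`.
#' @slot marginMm margin in mm applied around the tight bounding box.
#' @export
setClass("CropRegion",
  representation(rowMin = "integer", rowMax = "integer", colMin = "integer",
                 colMax = "integer", strategy = "character",
                 marginMm = "numeric"))

setValidity("CropRegion", function(object) {
  if (object@rowMin < 0L || object@colMin < 0L) return("bounds must be >= 0")
  if (object@rowMax <= object@rowMin || object@colMax <= object@colMin)
    return("region must be non-empty")
  if (object@marginMm < 0) return("margin must be >= 0")
  TRUE
})

#' Construct a [CropRegion-class]
#' @param rowMin,rowMax,colMin,colMax 0-based half-open pixel bounds.
#' @param strategy crop strategy tag.
#' @param marginMm margin (mm) already applied.
#' @return a `CropRegion`.
#' @export
CropRegion <- function(rowMin, rowMax, colMin, colMax,
                       strategy = "whole_heart", marginMm = 0) {
  new("CropRegion", rowMin = as.integer(rowMin), rowMax = as.integer(rowMax),
      colMin = as.integer(colMin), colMax = as.integer(colMax),
      strategy = strategy, marginMm = as.numeric(marginMm))
}

## ------------------------------------------------------------- specs/cfgs ----

#' Digital phantom specification
#'
#' Describes one synthetic thorax-abdomen-pelvis phantom: grid geometry,
#' per-organ mean count rates and the simulated cardiac uptake level.
#' `cardiacUptakeFraction` is the fraction `f` of the baseline (f = 0)
#' pseudo-planar image's 99th percentile contributed, on average over the
#' projected LV support, by LV uptake; 0 reproduces a normal (grade 0) study.
#'
#' @slot gridShape integer triple (default 128 x 128 x 128).
#' @slot spacingMm positive triple, default 2.8 mm isotropic.
#' @slot organIntensities named nonnegative rates for `soft_tissue`,
#'   `ribcage`, `kidneys`, `bladder`, `heart_blood`.
#' @slot cardiacUptakeFraction nonnegative scalar `f`.
#' @slot seed integer RNG seed for the per-phantom anatomy jitter.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacingMm = "numeric",
                 organIntensities = "numeric",
                 cardiacUptakeFraction = "numeric", seed = "integer"))

.DEFAULT_ORGAN_INTENSITIES <- c(soft_tissue = 1, ribcage = 8, kidneys = 6,
                                bladder = 12, heart_blood = 3)

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("gridShape must be three integers >= 8")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    return("spacingMm must be three positive values")
  oi <- object@organIntensities
  if (!all(names(.DEFAULT_ORGAN_INTENSITIES) %in% names(oi)))
    return(sprintf("organIntensities must name: %s",
                   paste(names(.DEFAULT_ORGAN_INTENSITIES), collapse = ", ")))
  if (any(!is.finite(oi)) || any(oi < 0))
    return("organIntensities must be nonnegative")
  if (object@cardiacUptakeFraction < 0)
    return("cardiacUptakeFraction must be >= 0")
  TRUE
})

#' Construct a [PhantomSpec-class]
#' @param gridShape grid size per axis (scalar recycled to 3).
#' @param spacingMm voxel spacing in mm (scalar recycled to 3).
#' @param organIntensities named mean count rates; missing names take the
#'   package defaults.
#' @param cardiacUptakeFraction LV uptake fraction `f` (0 = grade 0).
#' @param seed integer seed controlling anatomy jitter.
#' @return a `PhantomSpec`.
#' @examples
#' spec <- PhantomSpec(gridShape = 64, cardiacUptakeFraction = 1.2, seed = 7)
#' @export
PhantomSpec <- function(gridShape = c(128L, 128L, 128L),
                        spacingMm = c(2.8, 2.8, 2.8),
                        organIntensities = .DEFAULT_ORGAN_INTENSITIES,
                        cardiacUptakeFraction = 0, seed = 1L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  oi <- .DEFAULT_ORGAN_INTENSITIES
  oi[names(organIntensities)] <- organIntensities
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMm = as.numeric(spacingMm), organIntensities = oi,
      cardiacUptakeFraction = as.numeric(cardiacUptakeFraction),
      seed = as.integer(seed))
}

#' Uptake-level expansion scheme
#'
#' The offline "explainable augmentation" grid: candidate LV uptake levels
#' from `minFraction` to `maxFraction` of the base image's 99th percentile in
#' steps of `step`, of which the `nAugmentedPerCase` lowest are used per
#' case. With the defaults (5\% to 150\% in 5\% steps, 28 levels per case)
#' each input image expands to 29 images: the original plus levels
#' 5\%..140\%.
#'
#' @slot minFraction,maxFraction,step grid parameters (fractions of P99).
#' @slot nAugmentedPerCase number of augmented copies per case.
#' @export
setClass("UptakeLevelScheme",
  representation(minFraction = "numeric", maxFraction = "numeric",
                 step = "numeric", nAugmentedPerCase = "integer"))

setValidity("UptakeLevelScheme", function(object) {
  if (object@minFraction >= object@maxFraction) return("min must be < max")
  if (object@step <= 0) return("step must be > 0")
  n_levels <- length(seq(object@minFraction, object@maxFraction,
                         by = object@step))
  if (object@nAugmentedPerCase < 0L) return("nAugmentedPerCase must be >= 0")
  if (object@nAugmentedPerCase > n_levels)
    return(sprintf("scheme asks for %d levels but the grid provides %d",
                   object@nAugmentedPerCase, n_levels))
  TRUE
})

#' Construct an [UptakeLevelScheme-class]
#' @param minFraction,maxFraction,step uptake-level grid (fractions of P99).
#' @param nAugmentedPerCase augmented copies per case (default 28).
#' @return an `UptakeLevelScheme`.
#' @export
UptakeLevelScheme <- function(minFraction = 0.05, maxFraction = 1.50,
                              step = 0.05, nAugmentedPerCase = 28L) {
  new("UptakeLevelScheme", minFraction = minFraction,
      maxFraction = maxFraction, step = step,
      nAugmentedPerCase = as.integer(nAugmentedPerCase))
}

#' Percentile normalization specification
#' @slot percentile percentile in (0, 100] used as the clip ceiling.
#' @slot clipLow lower clip bound (0).
#' @export
setClass("NormalizationSpec",
  representation(percentile = "numeric", clipLow = "numeric"))

setValidity("NormalizationSpec", function(object) {
  if (object@percentile <= 0 || object@percentile > 100)
    return("percentile must be in (0, 100]")
  TRUE
})

#' Construct a [NormalizationSpec-class]
#' @param percentile clip percentile (default 99).
#' @param clipLow lower clip bound (default 0).
#' @return a `NormalizationSpec`.
#' @export
NormalizationSpec <- function(percentile = 99, clipLow = 0) {
  new("NormalizationSpec", percentile = percentile, clipLow = clipLow)
}

#' Binary task specification
#'
#' `detection` separates grade 0 from grades 1-3; `severity` separates
#' grades 0-1 from grades 2-3.
#'
#' @slot name task name.
#' @slot positiveGrades grades mapped to the positive class.
#' @export
setClass("TaskSpec",
  representation(name = "character", positiveGrades = "integer"))

setValidity("TaskSpec", function(object) {
  pg <- object@positiveGrades
  if (length(pg) == 0L || !all(pg %in% 0:3))
    return("positiveGrades must be a nonempty subset of 0..3")
  TRUE
})

#' Construct a [TaskSpec-class]
#' @param name `"detection"` or `"severity"` (fills `positiveGrades`), or any
#'   name with explicit `positiveGrades`.
#' @param positiveGrades grades assigned label 1; defaults by task name.
#' @return a `TaskSpec`.
#' @examples
#' TaskSpec("detection")  # positive grades 1, 2, 3
#' TaskSpec("severity")   # positive grades 2, 3
#' @export
TaskSpec <- function(name, positiveGrades = NULL) {
  if (is.null(positiveGrades)) {
    positiveGrades <- switch(name,
      detection = 1:3,
      severity = 2:3,
      stop("positiveGrades required for custom task '", name, "'"))
  }
  new("TaskSpec", name = name, positiveGrades = as.integer(positiveGrades))
}

#' Segmentation training configuration
#'
#' Desk-scale defaults train the package's compact fully-convolutional
#' network; the full-scale transformer backbone from the original large-GPU
#' setting is not provided here.
#'
#' @slot backbone `"unet_small"`.
#' @slot patchHw training/inference patch (rows, cols), default 256 x 704.
#' @slot epochs,batchSize,lr0,lrDecay,lrStep optimizer schedule (Adam; lr
#'   multiplied by `lrDecay` every `lrStep` epochs).
#' @slot seed RNG seed for init and shuffling.
#' @export
setClass("SegTrainConfig",
  representation(backbone = "character", patchHw = "integer",
                 epochs = "integer", batchSize = "integer", lr0 = "numeric",
                 lrDecay = "numeric", lrStep = "integer",
                 patchesPerImage = "integer", seed = "integer"))

setValidity("SegTrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (length(object@patchHw) != 2L || any(object@patchHw < 8L))
    return("patchHw must be two integers >= 8")
  TRUE
})

#' Construct a [SegTrainConfig-class]
#' @param backbone `"unet_small"` (the in-package compact FCN).
#' @param patchHw patch size in pixels (rows, cols).
#' @param epochs,batchSize,lr0,lrDecay,lrStep training schedule.
#' @param patchesPerImage random patches drawn per image per epoch.
#' @param seed RNG seed.
#' @return a `SegTrainConfig`.
#' @export
SegTrainConfig <- function(backbone = "unet_small", patchHw = c(256L, 704L),
                           epochs = 10L, batchSize = 2L, lr0 = 1e-2,
                           lrDecay = 0.95, lrStep = 5L,
                           patchesPerImage = 8L, seed = 1L) {
  if (!identical(backbone, "unet_small"))
    stop("only the compact in-package backbone 'unet_small' is available")
  new("SegTrainConfig", backbone = backbone, patchHw = as.integer(patchHw),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      lr0 = lr0, lrDecay = lrDecay, lrStep = as.integer(lrStep),
      patchesPerImage = as.integer(patchesPerImage),
      seed = as.integer(seed))
}

#' Classification training configuration
#'
#' @slot backbone `"cnn_small"`.
#' @slot epochs,batchSize,lr0,lrDecay,lrStep optimizer schedule.
#' @slot inputSpacingMm pixel spacing crops are resampled to before entering
#'   the network (default 2.8 mm).
#' @slot inputHw fixed letterboxed network input size.
#' @slot valSplit patient-wise validation fraction inside a training fold.
#' @slot seed RNG seed.
#' @export
setClass("ClsTrainConfig",
  representation(backbone = "character", epochs = "integer",
                 batchSize = "integer", lr0 = "numeric", lrDecay = "numeric",
                 lrStep = "integer", inputSpacingMm = "numeric",
                 inputHw = "integer", valSplit = "numeric", seed = "integer"))

setValidity("ClsTrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    return("lrDecay must be in (0, 1]")
  if (length(object@inputHw) != 2L || any(object@inputHw < 8L) ||
      any(object@inputHw %% 4L != 0L))
    return("inputHw must be two integers >= 8, divisible by 4")
  TRUE
})

#' Construct a [ClsTrainConfig-class]
#' @param backbone `"cnn_small"` (the in-package compact CNN).
#' @param epochs,batchSize,lr0,lrDecay,lrStep training schedule.
#' @param inputSpacingMm resampling target for crops (mm).
#' @param inputHw letterboxed network input size (rows, cols).
#' @param valSplit patient-wise validation fraction (default 0.2).
#' @param seed RNG seed.
#' @return a `ClsTrainConfig`.
#' @export
ClsTrainConfig <- function(backbone = "cnn_small", epochs = 15L,
                           batchSize = 2L, lr0 = 3e-3, lrDecay = 0.95,
                           lrStep = 5L, inputSpacingMm = 2.8,
                           inputHw = c(64L, 64L), valSplit = 0.2, seed = 1L) {
  if (!identical(backbone, "cnn_small"))
    stop("only the compact in-package backbone 'cnn_small' is available")
  new("ClsTrainConfig", backbone = backbone, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), lr0 = lr0, lrDecay = lrDecay,
      lrStep = as.integer(lrStep), inputSpacingMm = inputSpacingMm,
      inputHw = as.integer(inputHw), valSplit = valSplit,
      seed = as.integer(seed))
}
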