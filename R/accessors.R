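#' @include AllClasses.R
NULL

## generics ------------------------------------------------------------------

#' Accessors for scintigrade containers
#'
#' Small read-only accessors for the S4 containers; user code should prefer
#' these over direct slot access.
#'
#' @param x an object.
#' @return the slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setGeneric("viewTag", function(x) standardGeneric("viewTag"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("acquisitionId", function(x) standardGeneric("acquisitionId"))
#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))
#' @rdname accessors
#' @export
setGeneric("anatomyMasks", function(x) standardGeneric("anatomyMasks"))
#' @rdname accessors
#' @export
setGeneric("caseGrade", function(x) standardGeneric("caseGrade"))
#' @rdname accessors
#' @export
setGeneric("caseImages", function(x) standardGeneric("caseImages"))
#' @rdname accessors
#' @export
setGeneric("caseMasks", function(x) standardGeneric("caseMasks"))
#' @rdname accessors
#' @export
setGeneric("uptakeFraction", function(x) standardGeneric("uptakeFraction"))
#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("averagedProbs", function(x) standardGeneric("averagedProbs"))
#' @rdname accessors
#' @export
setGeneric("ensembleDecision", function(x) standardGeneric("ensembleDecision"))
#' @rdname accessors
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))
#' @rdname accessors
#' @export
setGeneric("ensembleStage1", function(x) standardGeneric("ensembleStage1"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("saliencyValues", function(x) standardGeneric("saliencyValues"))
#' @rdname accessors
#' @export
setGeneric("regionBounds", function(x) standardGeneric("regionBounds"))

## methods -------------------------------------------------------------------

#' @rdname accessors
setMethod("pixels", "PlanarImage", function(x) x@pixels)
#' @rdname accessors
setMethod("voxels", "ActivityVolume", function(x) x@voxels)
#' @rdname accessors
setMethod("spacingMm", "PlanarImage", function(x) x@spacingMm)
#' @rdname accessors
setMethod("spacingMm", "ActivityVolume", function(x) x@spacingMm)
#' @rdname accessors
setMethod("spacingMm", "LabelMask", function(x) x@spacingMm)
#' @rdname accessors
setMethod("viewTag", "PlanarImage", function(x) x@view)
#' @rdname accessors
setMethod("patientId", "PlanarImage", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "LabeledCase", function(x) x@patientId)
#' @rdname accessors
setMethod("acquisitionId", "PlanarImage", function(x) x@acquisitionId)
#' @rdname accessors
setMethod("acquisitionId", "LabeledCase", function(x) x@acquisitionId)
#' @rdname accessors
setMethod("maskData", "LabelMask", function(x) x@data)
#' @rdname accessors
setMethod("structureName", "LabelMask", function(x) x@structure)
#' @rdname accessors
setMethod("anatomyMasks", "AnatomySet", function(x) x@masks)
#' @rdname accessors
setMethod("caseGrade", "LabeledCase", function(x) x@grade)
#' @rdname accessors
setMethod("caseImages", "LabeledCase", function(x) x@images)
#' @rdname accessors
setMethod("caseMasks", "LabeledCase", function(x) x@masks)
#' @rdname accessors
setMethod("uptakeFraction", "LabeledCase", function(x) x@uptakeFraction)
#' @rdname accessors
setMethod("probs", "ClassProbabilities", function(x) x@p)
#' @rdname accessors
setMethod("provenance", "ClassProbabilities", function(x) x@provenance)
#' @rdname accessors
setMethod("averagedProbs", "EnsembleResult", function(x) x@averagedP)
#' @rdname accessors
setMethod("ensembleDecision", "EnsembleResult", function(x) x@decision)
#' @rdname accessors
setMethod("ensembleMembers", "EnsembleResult", function(x) x@members)
#' @rdname accessors
setMethod("ensembleStage1", "EnsembleResult", function(x) x@stage1)
#' @rdname accessors
setMethod("metricValues", "MetricsReport", function(x) {
  c(f1 = x@f1, sensitivity = x@sensitivity, specificity = x@specificity,
    precision = x@precision, accuracy = x@accuracy, bac = x@bac, auc = x@auc)
})
#' @rdname accessors
setMethod("confusionCounts", "MetricsReport", function(x) x@confusion)
#' @rdname accessors
setMethod("rocPoints", "MetricsReport", function(x) x@roc)
#' @rdname accessors
setMethod("saliencyValues", "SaliencyMap", function(x) x@values)
#' @rdname accessors
setMethod("regionBounds", "CropRegion", function(x) {
  c(rowMin = x@rowMin, rowMax = x@rowMax,
    colMin = x@colMin, colMax = x@colMax)
})

## show ----------------------------------------------------------------------

setMethod("show", "PlanarImage", function(object) {
  p <- object@pixels
  cat(sprintf("PlanarImage [%s] %d x %d px @ %.2f x %.2f mm", object@view,
              nrow(p), ncol(p), object@spacingMm[1], object@spacingMm[2]))
  if (nzchar(object@patientId))
    cat(sprintf("  (%s / %s)", object@patientId, object@acquisitionId))
  cat(sprintf("\n  range [%.3g, %.3g], total %.4g\n", min(p), max(p), sum(p)))
})

setMethod("show", "ActivityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "ActivityVolume %d x %d x %d vox @ %.2f mm, AP axis %s, total %.4g\n",
    d[1], d[2], d[3], object@spacingMm[1],
    ifelse(is.na(object@apAxis), "?", object@apAxis), sum(object@voxels)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMask '%s' (%s), %d foreground of %d\n", object@structure,
              paste(d, collapse = " x "), sum(object@data),
              length(object@data)))
})

setMethod("show", "AnatomySet", function(object) {
  cat("AnatomySet:\n")
  for (s in names(object@masks))
    cat(sprintf("  %-12s %d voxels\n", s, sum(object@masks[[s]]@data)))
})

setMethod("show", "LabeledCase", function(object) {
  cat(sprintf("LabeledCase %s/%s grade %d (f = %.3g), views: %s\n",
              object@patientId, object@acquisitionId, object@grade,
              object@uptakeFraction,
              paste(names(object@images), collapse = ", ")))
})

setMethod("show", "ClassProbabilities", function(object) {
  pr <- object@provenance
  cat(sprintf("ClassProbabilities (%s) [fold %s, crop %s, view %s]\n",
              paste(sprintf("%.3f", object@p), collapse = ", "),
              pr$fold, pr$crop, pr$view))
})

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: decision class %d, averaged p = (%s), %d members\n",
              object@decision,
              paste(sprintf("%.3f", object@averagedP@p), collapse = ", "),
              length(object@members)))
})

setMethod("show", "MetricsReport", function(object) {
  m <- metricValues(object)
  cat("MetricsReport:\n ")
  cat(sprintf(" %s=%.3f", names(m), m), sep = "")
  cf <- object@confusion
  cat(sprintf("\n  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cf["TP"], cf["FP"], cf["TN"], cf["FN"]))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap [%s] %d x %d, target class %d\n", object@method,
              nrow(object@values), ncol(object@values), object@targetClass))
})

setMethod("show", "CropRegion", function(object) {
  cat(sprintf("CropRegion '%s' rows [%d,%d) cols [%d,%d), margin %.1f mm\n",
              object@strategy, object@rowMin, object@rowMax, object@colMin,
              object@colMax, object@marginMm))
})
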