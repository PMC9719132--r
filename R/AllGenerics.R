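#' @include AllClasses.R
NULL

#' Accessors for pipeline result objects
#'
#' Slot access for the S4 containers in viascreen. `sceneImage`, `sceneLabel`,
#' `cervixMask`, `specularMask` and `lesionMask` read a
#' [SyntheticScene-class]; `specularMask` also applies to a
#' [SpecularResult-class]; `featureImage` and `cleanedImage` read a
#' [SpecularResult-class]; `roiMask`, `roiCrop`, `roiCropMask`, `roiCenter`
#' and `roiRadius` read a [RoiResult-class]; `keptFeatures` and
#' `droppedFeatures` read a [SelectionState-class]; `cvScores` and `cvRanking`
#' read a [CvReport-class]; `decisionThreshold` reads a [TrainedModel-class];
#' `confusionCounts`, `evalMetrics`, `rocPoints`, `auc` and `aucCi` read an
#' [EvalReport-class].
#'
#' @param object an object of the matching class.
#' @return the slot contents (mask matrices as logical, images as 0-255
#'   arrays, metrics as named numerics).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setGeneric("sceneLabel", function(object) standardGeneric("sceneLabel"))
#' @rdname accessors
#' @export
setGeneric("cervixMask", function(object) standardGeneric("cervixMask"))
#' @rdname accessors
#' @export
setGeneric("specularMask", function(object) standardGeneric("specularMask"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("featureImage", function(object) standardGeneric("featureImage"))
#' @rdname accessors
#' @export
setGeneric("cleanedImage", function(object) standardGeneric("cleanedImage"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("roiCrop", function(object) standardGeneric("roiCrop"))
#' @rdname accessors
#' @export
setGeneric("roiCropMask", function(object) standardGeneric("roiCropMask"))
#' @rdname accessors
#' @export
setGeneric("roiCenter", function(object) standardGeneric("roiCenter"))
#' @rdname accessors
#' @export
setGeneric("roiRadius", function(object) standardGeneric("roiRadius"))
#' @rdname accessors
#' @export
setGeneric("keptFeatures", function(object) standardGeneric("keptFeatures"))
#' @rdname accessors
#' @export
setGeneric("droppedFeatures", function(object) standardGeneric("droppedFeatures"))
#' @rdname accessors
#' @export
setGeneric("cvScores", function(object) standardGeneric("cvScores"))
#' @rdname accessors
#' @export
setGeneric("cvRanking", function(object) standardGeneric("cvRanking"))
#' @rdname accessors
#' @export
setGeneric("decisionThreshold", function(object) standardGeneric("decisionThreshold"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("evalMetrics", function(object) standardGeneric("evalMetrics"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("aucCi", function(object) standardGeneric("aucCi"))

#' @rdname accessors
setMethod("sceneImage", "SyntheticScene", function(object) object@image)
#' @rdname accessors
setMethod("sceneLabel", "SyntheticScene", function(object) object@label)
#' @rdname accessors
setMethod("cervixMask", "SyntheticScene", function(object) object@cervixMask)
#' @rdname accessors
setMethod("specularMask", "SyntheticScene", function(object) object@specularMask)
#' @rdname accessors
setMethod("lesionMask", "SyntheticScene", function(object) object@lesionMask)
#' @rdname accessors
setMethod("specularMask", "SpecularResult", function(object) object@specularMask)
#' @rdname accessors
setMethod("featureImage", "SpecularResult", function(object) object@featureImage)
#' @rdname accessors
setMethod("cleanedImage", "SpecularResult", function(object) object@cleaned)
#' @rdname accessors
setMethod("roiMask", "RoiResult", function(object) object@mask)
#' @rdname accessors
setMethod("roiCrop", "RoiResult", function(object) object@crop)
#' @rdname accessors
setMethod("roiCropMask", "RoiResult", function(object) object@cropMask)
#' @rdname accessors
setMethod("roiCenter", "RoiResult", function(object) object@center)
#' @rdname accessors
setMethod("roiRadius", "RoiResult", function(object) object@radius)
#' @rdname accessors
setMethod("keptFeatures", "SelectionState", function(object) object@keptFeatures)
#' @rdname accessors
setMethod("droppedFeatures", "SelectionState", function(object) object@dropped)
#' @rdname accessors
setMethod("cvScores", "CvReport", function(object) object@scores)
#' @rdname accessors
setMethod("cvRanking", "CvReport", function(object) names(object@scores))
#' @rdname accessors
setMethod("decisionThreshold", "TrainedModel", function(object) object@threshold)
#' @rdname accessors
setMethod("confusionCounts", "EvalReport", function(object) object@confusion)
#' @rdname accessors
setMethod("evalMetrics", "EvalReport", function(object) object@metrics)
#' @rdname accessors
setMethod("rocPoints", "EvalReport", function(object) object@rocPoints)
#' @rdname accessors
setMethod("auc", "EvalReport", function(object) object@auc)
#' @rdname accessors
setMethod("aucCi", "EvalReport", function(object) object@aucCi)

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticScene '%s': %d x %d, label=%d (seed %d)\n",
              object@id, d[1], d[2], object@label, object@seed))
  cat(sprintf("  cervix %d px, specular %d px, lesion %d px\n",
              sum(object@cervixMask), sum(object@specularMask), sum(object@lesionMask)))
})

setMethod("show", "SpecularResult", function(object) {
  cat(sprintf("SpecularResult: %d specular pixels detected (%.2f%% of image)\n",
              sum(object@specularMask),
              100 * mean(object@specularMask)))
})

setMethod("show", "RoiResult", function(object) {
  cat(sprintf("RoiResult: mask %d px, center (%.1f, %.1f), radius %.1f, crop %d x %d\n",
              sum(object@mask), object@center[1], object@center[2], object@radius,
              nrow(object@crop), ncol(object@crop)))
})

setMethod("show", "SelectionState", function(object) {
  cat(sprintf("SelectionState: kept %d features, dropped %d (|r| > %.2f)\n",
              length(object@keptFeatures), nrow(object@dropped), object@threshold))
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport: %d-fold CV, PrecisionAtRecall(%.2f)\n",
              object@folds, object@minRecall))
  print(round(object@scores, 4))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s, threshold %.2f, %d features (seed %d)\n",
              object@algorithmId, object@threshold,
              length(object@selection@keptFeatures), object@seed))
})

setMethod("show", "EvalReport", function(object) {
  cm <- object@confusion
  cat(sprintf("EvalReport: tp=%d fp=%d tn=%d fn=%d\n",
              cm["tp"], cm["fp"], cm["tn"], cm["fn"]))
  print(round(object@metrics, 3))
  cat(sprintf("AUC %.3f (95%% CI %.2f-%.2f)\n",
              object@auc, object@aucCi[1], object@aucCi[2]))
})
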