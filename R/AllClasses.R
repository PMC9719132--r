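#' @import methods
NULL

#' Synthetic cervix scene with ground truth
#'
#' Container for one generated post-acetic-acid cervix image together with the
#' ground-truth rasters that make every downstream stage testable: the cervix
#' disk, the planted specular highlights, and (for positive scenes) the
#' acetowhite lesion patch.
#'
#' @slot image H x W x 3 numeric array on the 0-255 scale.
#' @slot label integer, 1 = VIA positive, 0 = negative.
#' @slot cervixMask logical H x W matrix, the ground-truth cervix disk.
#' @slot specularMask logical H x W matrix of planted highlight cores.
#' @slot lesionMask logical H x W matrix; empty when `label == 0`.
#' @slot seed integer seed the scene was drawn from.
#' @slot id character scene identifier.
#' @export
setClass("SyntheticScene",
  representation(image = "array", label = "integer", cervixMask = "matrix",
                 specularMask = "matrix", lesionMask = "matrix",
                 seed = "integer", id = "character"))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "image must be H x W x 3")
  if (!object@label %in% c(0L, 1L)) msg <- c(msg, "label must be 0 or 1")
  for (nm in c("cervixMask", "specularMask", "lesionMask")) {
    m <- slot(object, nm)
    if (!is.logical(m) || !identical(dim(m), d[1:2]))
      msg <- c(msg, paste(nm, "must be a logical H x W matrix"))
  }
  if (length(msg) == 0) {
    if (any(object@lesionMask & !object@cervixMask))
      msg <- c(msg, "lesionMask must lie inside cervixMask")
    if (object@label == 0L && any(object@lesionMask))
      msg <- c(msg, "negative scenes must have an empty lesionMask")
    if (any(object@specularMask)) {
      sel <- which(object@specularMask)
      n <- prod(d[1:2])
      if (min(object@image[c(sel, sel + n, sel + 2 * n)]) < 240)
        msg <- c(msg, "specular pixels must have all channels >= 240")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Specular-reflection removal result
#'
#' @slot featureImage H x W matrix in \[0, 1\]: the normalized std-dev-filtered
#'   combination of the HSV saturation (inverted), RGB green and CIE-Lab
#'   lightness channels.
#' @slot specularMask logical H x W matrix of detected highlight pixels
#'   (threshold exceedances dilated by one pixel).
#' @slot cleaned RGB image array with the masked pixels inpainted; equal to the
#'   input everywhere outside the mask.
#' @export
setClass("SpecularResult",
  representation(featureImage = "matrix", specularMask = "matrix",
                 cleaned = "array"))

setValidity("SpecularResult", function(object) {
  msg <- character()
  if (min(object@featureImage) < 0 || max(object@featureImage) > 1)
    msg <- c(msg, "featureImage values must lie in [0, 1]")
  if (!is.logical(object@specularMask)) msg <- c(msg, "specularMask must be logical")
  if (length(msg)) msg else TRUE
})

#' Cervix region-of-interest detection result
#'
#' @slot mask logical H x W matrix at the pre-crop resolution: the selected
#'   mixture component, largest connected component, holes filled.
#' @slot center numeric pair, centroid of the mask (row, col), 0-based.
#' @slot radius numeric, radius of the disk with the same area as the mask.
#' @slot crop RGB image array, the zoomed ROI (by default 200 x 200).
#' @slot cropMask logical matrix, the mask carried through the identical
#'   crop-and-zoom (nearest neighbour), for masked feature extraction.
#' @export
setClass("RoiResult",
  representation(mask = "matrix", center = "numeric", radius = "numeric",
                 crop = "array", cropMask = "matrix"))

setValidity("RoiResult", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || !any(object@mask))
    msg <- c(msg, "mask must be a non-empty logical matrix")
  if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
  if (length(msg)) msg else TRUE
})

#' Fitted feature-selection state
#'
#' Multicollinearity pruning plus z-score parameters, fitted on training rows
#' only so the identical transform can be replayed on held-out data.
#'
#' @slot keptFeatures character, retained feature names in panel order.
#' @slot dropped data.frame with columns `feature`, `partner`, `reason`
#'   (`"collinear"` with the retained partner, or `"zero-variance"`).
#' @slot center named numeric, per-kept-feature training means.
#' @slot scale named numeric, per-kept-feature training standard deviations
#'   (population), all strictly positive.
#' @slot threshold numeric, the absolute-correlation drop threshold.
#' @export
setClass("SelectionState",
  representation(keptFeatures = "character", dropped = "data.frame",
                 center = "numeric", scale = "numeric", threshold = "numeric"))

setValidity("SelectionState", function(object) {
  msg <- character()
  if (length(object@keptFeatures) == 0) msg <- c(msg, "no features kept")
  if (any(object@scale <= 0)) msg <- c(msg, "all z-score scales must be > 0")
  if (length(intersect(object@keptFeatures, object@dropped$feature)))
    msg <- c(msg, "kept and dropped feature sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Cross-validation report
#'
#' @slot scores named numeric, mean precision-at-recall per algorithm,
#'   sorted decreasing.
#' @slot perFold numeric matrix, algorithms x folds.
#' @slot folds integer fold count.
#' @slot minRecall numeric recall floor of the objective.
#' @slot seed integer seed used for fold assignment and learners.
#' @export
setClass("CvReport",
  representation(scores = "numeric", perFold = "matrix", folds = "integer",
                 minRecall = "numeric", seed = "integer"))

setValidity("CvReport", function(object) {
  if (is.unsorted(rev(object@scores))) "scores must be sorted decreasing" else TRUE
})

#' Trained VIA classification model
#'
#' Bundles the fitted estimator with everything needed to replay the identical
#' pipeline at prediction time: the selection state fitted on the training
#' table, the decision threshold, and the pipeline configuration.
#'
#' @slot algorithmId one of the ids in [listAlgorithms()].
#' @slot fit opaque fitted-estimator object from the algorithm adapter.
#' @slot selection [SelectionState-class] fitted on the training table.
#' @slot threshold numeric decision threshold in (0, 1); scores at or above it
#'   predict positive.
#' @slot config pipeline configuration list (see [pipelineConfig()]).
#' @slot seed integer training seed.
#' @export
setClass("TrainedModel",
  representation(algorithmId = "character", fit = "ANY",
                 selection = "SelectionState", threshold = "numeric",
                 config = "list", seed = "integer"))

setValidity("TrainedModel", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    "threshold must lie strictly inside (0, 1)" else TRUE
})

#' Test-set evaluation report
#'
#' @slot confusion named integer vector `tp`, `fp`, `tn`, `fn` at the model's
#'   stored decision threshold.
#' @slot metrics named numeric: sensitivity, specificity, accuracy, precision
#'   (fractions; NA where the defining ratio is undefined).
#' @slot rocPoints data.frame with columns `fpr`, `tpr`, `threshold`.
#' @slot auc numeric area under the ROC curve (trapezoid rule).
#' @slot aucCi numeric pair, percentile-bootstrap 95% confidence bounds.
#' @slot scores numeric model scores on the evaluated samples.
#' @slot labels integer true labels.
#' @export
setClass("EvalReport",
  representation(confusion = "integer", metrics = "numeric",
                 rocPoints = "data.frame", auc = "numeric", aucCi = "numeric",
                 scores = "numeric", labels = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (length(object@aucCi) != 2L ||
      object@aucCi[1] > object@auc + 1e-12 || object@aucCi[2] < object@auc - 1e-12)
    msg <- c(msg, "aucCi must bracket auc")
  if (length(msg)) msg else TRUE
})
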