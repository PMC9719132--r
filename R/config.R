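#' Pipeline configuration
#'
#' Aggregates the tunable constants of the screening pipeline. Defaults are
#' the working values of the method: 200 x 200 working resolution, specular
#' detection threshold 0.5 on the normalized feature image, 2 GMM components,
#' 16 gray levels, Haar wavelet, collinearity threshold 0.9, 25 CV folds,
#' recall floor 0.8, decision threshold 0.29.
#'
#' @param resize working image size (height, width).
#' @param specularThreshold specular detection threshold in (0, 1).
#' @param gmmComponents mixture size for ROI detection (>= 2).
#' @param quantizationLevels gray levels for the texture families (>= 2).
#' @param wavelet `"haar"` or `"db2"`.
#' @param collinearityThreshold feature-pruning threshold in (0, 1].
#' @param cvFolds cross-validation fold count.
#' @param minRecall recall floor of the precision-at-recall objective.
#' @param decisionThreshold score threshold for positive prediction, in (0, 1).
#' @param seed integer seed used by seeded pipeline stages.
#' @return validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(resize = c(200L, 200L), specularThreshold = 0.5,
                           gmmComponents = 2L, quantizationLevels = 16L,
                           wavelet = "haar", collinearityThreshold = 0.9,
                           cvFolds = 25L, minRecall = 0.8,
                           decisionThreshold = 0.29, seed = 1L) {
  cfg <- list(resize = as.integer(resize),
              specularThreshold = as.numeric(specularThreshold),
              gmmComponents = as.integer(gmmComponents),
              quantizationLevels = as.integer(quantizationLevels),
              wavelet = as.character(wavelet),
              collinearityThreshold = as.numeric(collinearityThreshold),
              cvFolds = as.integer(cvFolds),
              minRecall = as.numeric(minRecall),
              decisionThreshold = as.numeric(decisionThreshold),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  bad <- function(field, why) stop("invalid PipelineConfig field '", field,
                                   "': ", why, call. = FALSE)
  if (length(cfg$resize) != 2L || any(is.na(cfg$resize)) || any(cfg$resize < 3L))
    bad("resize", "must be two integers >= 3")
  if (cfg$specularThreshold <= 0 || cfg$specularThreshold >= 1)
    bad("specularThreshold", "must lie in (0, 1)")
  if (cfg$gmmComponents < 2L) bad("gmmComponents", "must be >= 2")
  if (cfg$quantizationLevels < 2L) bad("quantizationLevels", "must be >= 2")
  if (!cfg$wavelet %in% c("haar", "db2")) bad("wavelet", "must be haar or db2")
  if (cfg$collinearityThreshold <= 0 || cfg$collinearityThreshold > 1)
    bad("collinearityThreshold", "must lie in (0, 1]")
  if (cfg$cvFolds < 2L) bad("cvFolds", "must be >= 2")
  if (cfg$minRecall <= 0 || cfg$minRecall > 1) bad("minRecall", "must lie in (0, 1]")
  if (cfg$decisionThreshold <= 0 || cfg$decisionThreshold >= 1)
    bad("decisionThreshold", "must lie in (0, 1)")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(cfg)
}

#' Load a pipeline configuration from JSON, rejecting unknown keys
#'
#' @param path JSON file with a subset of the [pipelineConfig()] fields.
#' @return validated `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(j), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, j)
}

#' Write the effective configuration snapshot next to a run's outputs
#' @param cfg a `"PipelineConfig"` list.
#' @param path output JSON path.
#' @export
writePipelineConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
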