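#' Names of the 75-feature panel
#'
#' Fixed, documented panel order: 12 colour features, 28 GLCM, 5 NGTDM,
#' 14 GLSZM, 6 DWT, 10 LBP.
#'
#' @param wavelet wavelet name used in the DWT family names' documentation
#'   (does not change the names).
#' @return character vector of length 75 with a `families` attribute giving
#'   the per-family counts.
#' @export
viaFeatureNames <- function(wavelet = "haar") {
  color <- paste0(rep(c("color_mean_", "color_std_"), 6),
                  rep(c("R", "G", "B", "GR", "BR", "V"), each = 2))
  glcm <- paste0("glcm_", rep(haralickNames, each = 2), c("_mean", "_range"))
  ngtdm <- paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                              "complexity", "strength"))
  glszm <- paste0("glszm_", c("sze", "lze", "gln", "glnn", "zsn", "zp",
                              "lglze", "hglze", "szlge", "szhge", "lzlge",
                              "lzhge", "glv", "zsv"))
  dwt <- paste0("dwt_", rep(c("LH", "HL", "HH"), each = 2), c("_mean", "_std"))
  lbp <- c(paste0("lbp_u", 0:8), "lbp_nonuniform")
  out <- c(color, glcm, ngtdm, glszm, dwt, lbp)
  attr(out, "families") <- c(color = length(color), glcm = length(glcm),
                             ngtdm = length(ngtdm), glszm = length(glszm),
                             dwt = length(dwt), lbp = length(lbp))
  out
}

#' Extract the full 75-feature panel from a masked crop
#'
#' Concatenates the six families in fixed order: colour statistics on the RGB
#' crop, then GLCM, NGTDM and GLSZM on the luma grayscale quantized to
#' `levels` equal-width bins over the masked range, then wavelet detail
#' statistics, then the uniform-LBP histogram. All families are restricted to
#' the masked pixels.
#'
#' @param crop RGB image array (0-255), typically the 200 x 200 zoomed ROI.
#' @param mask logical matrix; defaults to the full frame.
#' @param levels gray-quantization depth, default 16.
#' @param wavelet DWT wavelet, default `"haar"`.
#' @param minPixels minimum masked-pixel count, default 64.
#' @return named numeric of length 75 in [viaFeatureNames()] order.
#' @examples
#' sc <- generateScene(generatorConfig(imageSize = c(96, 96)), 0, seed = 1)
#' fv <- extractFeatures(sceneImage(sc), cervixMask(sc))
#' length(fv)
#' @export
extractFeatures <- function(crop, mask = NULL, levels = 16L, wavelet = "haar",
                            minPixels = 64L) {
  assertRgbImage(crop)
  if (is.null(mask)) mask <- matrix(TRUE, dim(crop)[1], dim(crop)[2])
  mask <- assertBinaryMask(mask)
  if (sum(mask) < minPixels)
    stop("mask must contain at least ", minPixels, " pixels", call. = FALSE)
  gray <- rgbToGray(crop)
  q <- quantizeGray(gray, mask, levels)
  out <- c(colorFeatures(crop, mask, minPixels = minPixels),
           glcmFeatures(q, levels = levels),
           ngtdmFeatures(q, levels = levels),
           glszmFeatures(q),
           dwtFeatures(gray, mask, wavelet = wavelet),
           lbpFeatures(gray, mask))
  stopifnot(identical(names(out), as.vector(viaFeatureNames())))
  out
}

#' Run preprocessing, ROI detection and feature extraction over scenes
#'
#' For each scene (or image): resize to the working size, remove specular
#' reflections, detect the cervix ROI, crop/zoom, and extract the 75-feature
#' panel from the cleaned crop restricted to the ROI mask. If ROI detection
#' fails on an image the whole frame is used as the ROI and a warning is
#' recorded.
#'
#' @param scenes list of [SyntheticScene-class] objects (or a `generateDataset()`
#'   result), or a character vector of PNG paths.
#' @param labels optional integer labels; defaults to the scene labels.
#' @param config pipeline configuration from [pipelineConfig()].
#' @return data.frame: `id`, `label`, then the 75 feature columns.
#' @export
extractDataset <- function(scenes, labels = NULL, config = pipelineConfig()) {
  if (!is.null(scenes$scenes)) {
    if (is.null(labels)) labels <- scenes$labels$label
    scenes <- scenes$scenes
  }
  if (is.character(scenes)) {
    paths <- scenes
    ids <- sub("\\.png$", "", basename(paths))
    imgs <- lapply(paths, readImageFile)
  } else {
    ids <- vapply(scenes, function(s) s@id, character(1))
    if (is.null(labels)) labels <- vapply(scenes, function(s) s@label, integer(1))
    imgs <- lapply(scenes, function(s) s@image)
  }
  rows <- lapply(seq_along(imgs), function(k) {
    imageFeatures(imgs[[k]], config)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(id = ids,
             label = if (is.null(labels)) NA_integer_ else as.integer(labels),
             tab, stringsAsFactors = FALSE, check.names = FALSE)
}

# One image through the full preprocessing + ROI + feature path.
imageFeatures <- function(img, config = pipelineConfig()) {
  img <- resizeImage(img, config$resize)
  sp <- removeSpecular(img, threshold = config$specularThreshold)
  clean <- cleanedImage(sp)
  roi <- tryCatch(
    detectRoi(clean, nComponents = config$gmmComponents, seed = config$seed,
              size = config$resize),
    error = function(e) {
      warning("ROI detection failed (", conditionMessage(e),
              "); falling back to the whole image", call. = FALSE)
      full <- matrix(TRUE, dim(clean)[1], dim(clean)[2])
      cz <- cropAndZoom(clean, full, size = config$resize)
      methods::new("RoiResult", mask = full, center = maskCentroid(full),
                   radius = sqrt(sum(full) / pi), crop = cz$crop,
                   cropMask = cz$cropMask)
    })
  extractFeatures(roiCrop(roi), roiCropMask(roi),
                  levels = config$quantizationLevels, wavelet = config$wavelet)
}

featureColumns <- function(table) {
  setdiff(names(table), c("id", "label"))
}

#' Write / read a feature table as CSV
#'
#' Column layout: `id`, `label`, then the named feature columns.
#'
#' @param table feature data.frame.
#' @param path CSV path.
#' @return `readFeatureTable` returns the data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
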