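#' Specular-reflection feature image
#'
#' Specular highlights on the wet cervix are saturated and nearly white: low
#' HSV saturation, high green intensity, high CIE-Lab lightness. The three
#' channels — S inverted (1 - S), G, and L — are each min-max normalized to
#' \[0, 1\], averaged into one raster, passed through a 3 x 3
#' standard-deviation filter, and the filter output is min-max normalized to
#' \[0, 1\]. A constant input (no contrast anywhere) maps to an all-zero
#' raster rather than dividing by a zero range.
#'
#' @param img RGB image array (0-255).
#' @param window std-dev filter window, default 3.
#' @return H x W matrix in \[0, 1\].
#' @export
specularFeatureImage <- function(img, window = 3L) {
  assertRgbImage(img)
  ch <- colorChannels(img)
  combined <- (minMaxNormalize(1 - ch$s) + minMaxNormalize(img[, , 2]) +
                 minMaxNormalize(ch$L)) / 3
  minMaxNormalize(stddevFilter(combined, window))
}

#' Detect and inpaint specular reflections
#'
#' Thresholds the [specularFeatureImage()] response, dilates the detection by
#' one pixel, fills fully enclosed holes (the flat saturated core of a
#' highlight produces no std-dev response of its own), and fills the masked
#' pixels by iterative boundary-mean
#' inpainting: each pass replaces masked pixels that touch at least one
#' unmasked 8-neighbour with the mean of those neighbours, marching inwards
#' until the mask is consumed. Pixels outside the (dilated) mask are returned
#' untouched.
#'
#' @param img RGB image array (0-255).
#' @param threshold detection threshold in (0, 1) on the normalized feature
#'   image, default 0.5.
#' @param window std-dev filter window passed through, default 3.
#' @return a [SpecularResult-class].
#' @examples
#' img <- array(120, dim = c(16, 16, 3))
#' res <- removeSpecular(img)           # uniform: nothing detected
#' sum(specularMask(res)) == 0
#' @export
removeSpecular <- function(img, threshold = 0.5, window = 3L) {
  assertRgbImage(img)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  feat <- specularFeatureImage(img, window)
  mask <- dilate3(feat > threshold)
  # the std-dev filter fires on highlight boundaries; filling enclosed holes
  # recovers the flat saturated cores
  if (any(mask) && !all(mask)) mask <- EBImage::fillHull(mask * 1) > 0
  cleaned <- inpaintMask(img, mask)
  methods::new("SpecularResult", featureImage = feat, specularMask = mask,
               cleaned = cleaned)
}

# Iterative boundary-mean inpainting of `mask` pixels in an RGB array.
inpaintMask <- function(img, mask) {
  if (!any(mask)) return(img)
  if (all(mask)) return(img)  # nothing known to inpaint from
  known <- !mask
  out <- img
  while (any(!known)) {
    cnt <- boxSum(known * 1, 3L) - known  # unmasked 8-neighbour count
    frontier <- !known & cnt > 0
    if (!any(frontier)) break             # isolated region (cannot happen on full grids)
    for (ch in 1:3) {
      plane <- out[, , ch]
      s <- boxSum(plane * known, 3L) - plane * known
      plane[frontier] <- s[frontier] / cnt[frontier]
      out[, , ch] <- plane
    }
    known <- known | frontier
  }
  out
}
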