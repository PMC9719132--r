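# Population standard deviation (divide by n), used throughout the panel.
popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Colour statistics over the masked ROI
#'
#' Mean and population standard deviation of six per-pixel channels computed
#' over masked pixels only: R, G, B (0-255), the ratios G/(R+1) and B/(R+1)
#' (the +1 denominator guard avoids division by zero on 8-bit values), and the
#' HSV value component V in \[0, 1\].
#'
#' @param crop RGB image array (0-255).
#' @param mask logical matrix; at least `minPixels` pixels must be set.
#' @param minPixels minimum masked-pixel count, default 64.
#' @return named numeric of length 12 in panel order.
#' @examples
#' img <- array(128, dim = c(16, 16, 3))
#' colorFeatures(img, matrix(TRUE, 16, 16))[["color_mean_GR"]]  # 128/129
#' @export
colorFeatures <- function(crop, mask, minPixels = 64L) {
  assertRgbImage(crop)
  mask <- assertBinaryMask(mask)
  if (sum(mask) < minPixels)
    stop("mask must contain at least ", minPixels, " pixels", call. = FALSE)
  sel <- which(mask)
  n <- prod(dim(crop)[1:2])
  r <- crop[sel]; g <- crop[sel + n]; b <- crop[sel + 2 * n]
  chans <- list(R = r, G = g, B = b,
                GR = g / (r + 1), BR = b / (r + 1),
                V = pmax(r, g, b) / 255)
  out <- numeric(0)
  for (nm in names(chans)) {
    out[paste0("color_mean_", nm)] <- mean(chans[[nm]])
    out[paste0("color_std_", nm)] <- popSd(chans[[nm]])
  }
  out
}

#' Quantize a grayscale raster over the masked range
#'
#' Equal-width binning of the masked gray values into `levels` levels
#' (1 .. levels). A constant masked region maps entirely to level 1.
#' Unmasked pixels get NA.
#'
#' @param gray numeric matrix.
#' @param mask logical matrix.
#' @param levels number of gray levels, default 16.
#' @return integer matrix of levels with NA outside the mask.
#' @export
quantizeGray <- function(gray, mask, levels = 16L) {
  mask <- assertBinaryMask(mask)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  vals <- gray[mask]
  if (length(vals) == 0L) stop("empty mask", call. = FALSE)
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(gray), ncol(gray))
  if (rng[2] - rng[1] < 1e-12) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(floor((gray[mask] - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
                    levels)
  }
  q
}
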