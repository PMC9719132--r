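# Low-level raster helpers. Images are base-R numeric arrays H x W x 3 with
# values on the 8-bit scale 0..255, row-major, origin top-left, channels R,G,B
# (the layout png::readPNG delivers, times 255).

#' Validate an RGB image array
#'
#' @param img candidate object.
#' @param what label used in error messages.
#' @return the image, invisibly, after validation.
#' @keywords internal
assertRgbImage <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 array", call. = FALSE)
  d <- dim(img)
  if (d[1] < 3L || d[2] < 3L)
    stop(what, " must be at least 3 x 3 pixels", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(what, " must hold finite values in [0, 255]", call. = FALSE)
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Convert an 8-bit RGB image to channel matrices in other colour spaces
#'
#' HSV follows the standard hexcone model with S and V in \[0, 1\]
#' (via [grDevices::rgb2hsv()]); CIE-Lab assumes sRGB input under the D65
#' white point with L in \[0, 100\] (via [grDevices::convertColor()]).
#'
#' @param img RGB image array (0-255).
#' @return list of H x W matrices: `s`, `v` (HSV), `L`, `a`, `b` (CIE-Lab).
#' @keywords internal
colorChannels <- function(img) {
  d <- dim(img)
  r <- as.vector(img[, , 1]); g <- as.vector(img[, , 2]); b <- as.vector(img[, , 3])
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
  lab <- grDevices::convertColor(cbind(r, g, b) / 255, from = "sRGB", to = "Lab")
  shape <- function(x) matrix(x, nrow = d[1], ncol = d[2])
  list(s = shape(hsv[2, ]), v = shape(hsv[3, ]),
       L = shape(lab[, 1]), a = shape(lab[, 2]), b = shape(lab[, 3]))
}

#' CIE-Lab a* channel of an image
#' @param img RGB image array.
#' @return H x W numeric matrix of a* values.
#' @keywords internal
labAChannel <- function(img) colorChannels(img)$a

#' Convert an RGB image to a grayscale matrix
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img RGB image array (0-255).
#' @return H x W numeric matrix on the 0-255 scale.
#' @export
rgbToGray <- function(img) {
  assertRgbImage(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear sampling of a single-channel matrix at fractional (row, col)
# positions. Center-aligned convention: output pixel i (0-based) samples input
# coordinate (i + 0.5) * scale - 0.5, so equal sizes give the identity map.
bilinearMatrix <- function(m, outH, outW) {
  inH <- nrow(m); inW <- ncol(m)
  rs <- ((seq_len(outH) - 0.5) * inH / outH) - 0.5
  cs <- ((seq_len(outW) - 0.5) * inW / outW) - 0.5
  rs <- pmin(pmax(rs, 0), inH - 1)
  cs <- pmin(pmax(cs, 0), inW - 1)
  r0 <- floor(rs); c0 <- floor(cs)
  r1 <- pmin(r0 + 1, inH - 1); c1 <- pmin(c0 + 1, inW - 1)
  fr <- rs - r0; fc <- cs - c0
  # gather the four corners via outer index arithmetic (1-based)
  idx <- function(rr, cc) m[cbind(rep(rr + 1, times = outW),
                                  rep(cc + 1, each = outH))]
  v00 <- idx(r0, c0); v01 <- idx(r0, c1); v10 <- idx(r1, c0); v11 <- idx(r1, c1)
  wfr <- rep(fr, times = outW); wfc <- rep(fc, each = outH)
  out <- v00 * (1 - wfr) * (1 - wfc) + v01 * (1 - wfr) * wfc +
    v10 * wfr * (1 - wfc) + v11 * wfr * wfc
  matrix(out, nrow = outH, ncol = outW)
}

nearestMatrix <- function(m, outH, outW) {
  inH <- nrow(m); inW <- ncol(m)
  rs <- pmin(pmax(floor((seq_len(outH) - 0.5) * inH / outH), 0), inH - 1) + 1
  cs <- pmin(pmax(floor((seq_len(outW) - 0.5) * inW / outW), 0), inW - 1) + 1
  m[rs, cs, drop = FALSE]
}

#' Resize an RGB image by bilinear interpolation
#'
#' Output pixel centres are mapped back into the source grid (centre-aligned),
#' so resizing to the input size returns the input unchanged and a uniform
#' image stays uniform.
#'
#' @param img RGB image array (0-255).
#' @param size integer pair `c(height, width)`, each at least 3.
#' @return resized RGB image array.
#' @examples
#' img <- array(128, dim = c(8, 8, 3))
#' dim(resizeImage(img, c(4, 4)))
#' @export
resizeImage <- function(img, size = c(200L, 200L)) {
  assertRgbImage(img)
  size <- as.integer(size)
  if (length(size) != 2L || anyNA(size) || any(size < 3L))
    stop("size must be two integers, each >= 3", call. = FALSE)
  out <- array(0, dim = c(size[1], size[2], 3L))
  for (ch in 1:3) out[, , ch] <- bilinearMatrix(img[, , ch], size[1], size[2])
  clip255(out)
}

# Replicate-pad a matrix by `k` pixels on every side.
padReplicate <- function(m, k) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

# Sum of each w x w neighbourhood (w odd) with replicate padding, via shifted
# adds on the padded matrix.
boxSum <- function(m, w) {
  k <- (w - 1L) %/% 2L
  p <- padReplicate(m, k)
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in seq(-k, k)) for (dc in seq(-k, k))
    out <- out + p[seq_len(nrow(m)) + k + dr, seq_len(ncol(m)) + k + dc, drop = FALSE]
  out
}

#' Moving-window standard-deviation filter
#'
#' Each output pixel is the population standard deviation of the
#' `window` x `window` neighbourhood around the corresponding input pixel,
#' with edge replication at the borders.
#'
#' @param raster numeric matrix.
#' @param window odd integer window size, default 3.
#' @return numeric matrix of the same dimensions.
#' @examples
#' stddevFilter(matrix(0, 5, 5))          # all zeros
#' @export
stddevFilter <- function(raster, window = 3L) {
  if (!is.matrix(raster) || !is.numeric(raster))
    stop("raster must be a numeric matrix", call. = FALSE)
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  n <- window^2
  mu <- boxSum(raster, window) / n
  m2 <- boxSum(raster^2, window) / n
  sqrt(pmax(m2 - mu^2, 0))
}

# Min-max normalize a matrix to [0, 1]; a constant matrix maps to all zeros.
minMaxNormalize <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2])))
    return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

# Binary dilation of a logical matrix with a 3x3 structuring element.
dilate3 <- function(mask) boxSum(mask * 1, 3L) > 0

assertBinaryMask <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stop(what, " must be a matrix", call. = FALSE)
  if (is.logical(mask)) return(mask)
  if (!all(mask %in% c(0, 1))) stop(what, " must be binary", call. = FALSE)
  mask > 0
}
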