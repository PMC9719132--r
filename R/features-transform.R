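# DWT and LBP feature families.

waveletFilters <- function(wavelet) {
  lo <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.836516303737469,
            0.22414386804185735, -0.12940952255092145),
    stop("unsupported wavelet '", wavelet, "' (use 'haar' or 'db2')",
         call. = FALSE))
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(lo = lo, hi = hi)
}

# One-dimensional periodized analysis filter + dyadic downsample, applied to
# the columns of a matrix.
dwtCols <- function(m, filt) {
  n <- nrow(m)
  L <- length(filt)
  # circular convolution: output k uses rows 2k-1 .. 2k-1+L-1 (periodized)
  idx <- outer(seq(1, n, by = 2), seq_len(L) - 1L, "+")
  idx <- (idx - 1L) %% n + 1L
  out <- matrix(0, n / 2, ncol(m))
  for (l in seq_len(L))
    out <- out + filt[l] * m[idx[, l], , drop = FALSE]
  out
}

# Single-level 2-D DWT of a matrix (even dimensions enforced by replicate
# padding of the last row/column). Returns the three detail subbands:
# HL responds to change along columns (vertical edges), LH to change along
# rows (horizontal edges), HH to diagonal detail.
dwt2 <- function(m, wavelet = "haar") {
  if (nrow(m) %% 2L) m <- rbind(m, m[nrow(m), ])
  if (ncol(m) %% 2L) m <- cbind(m, m[, ncol(m)])
  f <- waveletFilters(wavelet)
  loC <- dwtCols(m, f$lo); hiC <- dwtCols(m, f$hi)       # along rows (y)
  ll <- t(dwtCols(t(loC), f$lo)); hl <- t(dwtCols(t(loC), f$hi))
  lh <- t(dwtCols(t(hiC), f$lo)); hh <- t(dwtCols(t(hiC), f$hi))
  list(LL = ll, LH = lh, HL = hl, HH = hh)
}

#' Wavelet detail-energy features
#'
#' Single-level 2-D discrete wavelet transform (Haar by default) of the crop
#' with pixels outside the mask replaced by the masked mean, so background
#' content does not leak detail energy into the panel. Features are the mean
#' and population standard deviation of the absolute coefficients in the
#' three detail subbands LH, HL and HH.
#'
#' @param gray numeric matrix (grayscale crop, 0-255).
#' @param mask logical matrix; unmasked pixels are filled with the masked mean.
#' @param wavelet `"haar"` (default) or `"db2"`.
#' @return named numeric of length 6.
#' @export
dwtFeatures <- function(gray, mask = NULL, wavelet = "haar") {
  if (nrow(gray) < 2L || ncol(gray) < 2L)
    stop("crop must be at least 2 x 2 for the wavelet transform", call. = FALSE)
  if (!is.null(mask)) {
    mask <- assertBinaryMask(mask)
    if (!any(mask)) stop("empty mask", call. = FALSE)
    gray[!mask] <- mean(gray[mask])
  }
  bands <- dwt2(gray, wavelet)
  out <- numeric(0)
  for (nm in c("LH", "HL", "HH")) {
    a <- abs(bands[[nm]])
    out[paste0("dwt_", nm, "_mean")] <- mean(a)
    out[paste0("dwt_", nm, "_std")] <- popSd(a)
  }
  out
}

# Uniform LBP code table: P = 8 integer-ring neighbours at radius 1, sign
# convention neighbour >= centre. Bin 1..9 = uniform patterns with 0..8 ones,
# bin 10 = non-uniform.
lbpOffsets <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                    c(0, -1), c(1, -1), c(1, 0), c(1, 1))

lbpBinOfBits <- function(bits) {
  trans <- sum(bits != bits[c(2:8, 1)])
  if (trans <= 2) sum(bits) + 1L else 10L
}

#' Uniform local binary pattern histogram
#'
#' Classic 8-neighbour radius-1 LBP with the uniform-pattern mapping: codes
#' with at most two circular 0/1 transitions fall into nine bins indexed by
#' their number of ones (0 through 8); everything else lands in a tenth
#' non-uniform bin. Codes are computed only for masked pixels whose full
#' 8-neighbourhood is masked and inside the image; the histogram is
#' normalized to sum to one.
#'
#' @param gray numeric matrix.
#' @param mask logical matrix.
#' @return named numeric of length 10 summing to 1.
#' @export
lbpFeatures <- function(gray, mask = NULL) {
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  mask <- assertBinaryMask(mask)
  interior <- matrix(FALSE, h, w)
  interior[2:(h - 1), 2:(w - 1)] <- TRUE
  valid <- mask & interior
  for (k in seq_len(8)) {
    d <- lbpOffsets[k, ]
    shifted <- matrix(FALSE, h, w)
    shifted[pmax(1, 1 + d[1]):pmin(h, h + d[1]),
            pmax(1, 1 + d[2]):pmin(w, w + d[2])] <-
      mask[pmax(1, 1 - d[1]):pmin(h, h - d[1]),
           pmax(1, 1 - d[2]):pmin(w, w - d[2])]
    valid <- valid & shifted
  }
  sel <- which(valid)
  if (length(sel) == 0L)
    stop("mask has no pixel with a fully masked 8-neighbourhood", call. = FALSE)
  pos <- arrayInd(sel, dim(gray))
  bits <- matrix(0L, length(sel), 8)
  for (k in seq_len(8)) {
    d <- lbpOffsets[k, ]
    nb <- gray[cbind(pos[, 1] + d[1], pos[, 2] + d[2])]
    bits[, k] <- as.integer(nb >= gray[sel])
  }
  ones <- rowSums(bits)
  trans <- rowSums(bits != bits[, c(2:8, 1), drop = FALSE])
  bin <- ifelse(trans <= 2, ones + 1L, 10L)
  histo <- tabulate(bin, 10L) / length(bin)
  names(histo) <- c(paste0("lbp_u", 0:8), "lbp_nonuniform")
  histo
}
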