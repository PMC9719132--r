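# Gray-level co-occurrence matrix features: 14 Haralick statistics summarised
# by their mean and range over the four distance-1 directions, giving 28
# values. Co-occurrence pairs are restricted to pixel pairs that are both
# inside the mask; matrices are symmetrised and normalized. Natural logs;
# 0 log 0 = 0 throughout.

glcmDirections <- list(d0 = c(0L, 1L), d45 = c(-1L, 1L),
                       d90 = c(-1L, 0L), d135 = c(-1L, -1L))

haralickNames <- c("energy", "contrast", "correlation", "variance",
                   "homogeneity", "sum_average", "sum_variance", "sum_entropy",
                   "entropy", "difference_variance", "difference_entropy",
                   "imc1", "imc2", "mcc")

# Normalized symmetric co-occurrence matrix for one direction offset.
coocMatrix <- function(q, dr, dc, levels) {
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1L, 1L - dr):min(h, h - dr)
  c1 <- max(1L, 1L - dc):min(w, w - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  idx <- (a[ok] - 1L) * levels + b[ok]
  tab <- matrix(tabulate(idx, levels * levels), levels, levels, byrow = TRUE)
  counts <- tab + t(tab)
  counts / sum(counts)
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

# The 14 Haralick statistics of one normalized symmetric GLCM.
haralickStats <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)         # equals px for a symmetric matrix
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  # p_{x+y}(k), k = 2..2L and p_{x-y}(k), k = 0..L-1
  sums <- seq(2, 2 * L)
  pxy_sum <- vapply(sums, function(k) sum(P[i + j == k]), numeric(1))
  diffs <- seq(0, L - 1)
  pxy_diff <- vapply(diffs, function(k) sum(P[abs(i - j) == k]), numeric(1))

  energy <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx * sy < 1e-12) 0 else
    (sum(i * j * P) - mux * muy) / (sx * sy)
  variance <- sum((i - mux)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))
  sumAverage <- sum(sums * pxy_sum)
  sumVariance <- sum((sums - sumAverage)^2 * pxy_sum)
  sumEntropy <- -sum(xlogx(pxy_sum))
  entropy <- -sum(xlogx(P))
  mud <- sum(diffs * pxy_diff)
  diffVariance <- sum((diffs - mud)^2 * pxy_diff)
  diffEntropy <- -sum(xlogx(pxy_diff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * ifelse(pxpy > 0, log(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (max(hx, hy) < 1e-12) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  # maximal correlation coefficient: sqrt of second-largest eigenvalue of Q
  keep <- px > 0
  mcc <- if (sum(keep) < 2) 0 else {
    Pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    Q <- (Pk / pxk) %*% t(Pk / matrix(pyk, nrow(Pk), ncol(Pk), byrow = TRUE))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(min(ev[2], 1), 0))
  }
  c(energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, homogeneity = homogeneity, sum_average = sumAverage,
    sum_variance = sumVariance, sum_entropy = sumEntropy, entropy = entropy,
    difference_variance = diffVariance, difference_entropy = diffEntropy,
    imc1 = imc1, imc2 = imc2, mcc = mcc)
}

#' GLCM (Haralick) texture features over a masked quantized raster
#'
#' Builds symmetric normalized co-occurrence matrices at distance 1 in the
#' four standard directions (0, 45, 90, 135 degrees), restricted to pixel
#' pairs lying wholly inside the mask, computes 14 Haralick statistics per
#' direction, and reports the mean and the range (max - min) of each statistic
#' over the four directions.
#'
#' @param q integer matrix of quantized gray levels (NA outside the mask), as
#'   from [quantizeGray()], or a raw integer matrix (then `mask` applies).
#' @param mask optional logical matrix applied to `q`.
#' @param levels number of gray levels; defaults to `max(q, na.rm = TRUE)`.
#' @return named numeric of length 28 (`glcm_<stat>_mean`, `glcm_<stat>_range`).
#' @export
glcmFeatures <- function(q, mask = NULL, levels = NULL) {
  if (!is.null(mask)) {
    mask <- assertBinaryMask(mask)
    q[!mask] <- NA_integer_
  }
  if (is.null(levels)) levels <- max(q, na.rm = TRUE)
  if (levels < 2L && max(q, na.rm = TRUE) < 2L) levels <- max(levels, 2L)
  stats <- vapply(glcmDirections, function(d) {
    P <- coocMatrix(q, d[1], d[2], levels)
    if (is.null(P)) stop("mask contains no valid pixel pair", call. = FALSE)
    haralickStats(P)
  }, numeric(14L))
  out <- numeric(0)
  for (nm in haralickNames) {
    v <- stats[nm, ]
    out[paste0("glcm_", nm, "_mean")] <- mean(v)
    out[paste0("glcm_", nm, "_range")] <- max(v) - min(v)
  }
  out
}
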