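#' Compute the Ra space of an image
#'
#' The cervix sits near the frame centre and is redder than the surround, so
#' segmentation runs on the per-pixel pair (R, a): R is the Euclidean distance
#' of the pixel from the image centre `((H-1)/2, (W-1)/2)` in pixels, and a is
#' the CIE-Lab a* chromatic channel (D65).
#'
#' @param img RGB image array (0-255).
#' @return list with matrices `R` and `a` plus the `center` pair.
#' @examples
#' ra <- toRaSpace(array(128, dim = c(5, 5, 3)))
#' ra$R[3, 3]   # centre pixel: 0
#' @export
toRaSpace <- function(img) {
  assertRgbImage(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  center <- c((h - 1) / 2, (w - 1) / 2)
  list(R = distanceRaster(h, w, center), a = labAChannel(img), center = center)
}

# Spherical-covariance EM for a small number of components on an n x p matrix.
# K-means initialization (nstart restarts under the given seed). Returns hard
# assignments plus the fitted parameters.
sphericalGmm <- function(x, k, seed, maxIter = 500L, tol = 1e-6, nstart = 10L) {
  n <- nrow(x); p <- ncol(x)
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50L)
  mu <- km$centers
  sig2 <- pmax(vapply(seq_len(k), function(j) {
    d <- x - matrix(mu[j, ], n, p, byrow = TRUE)
    mean(rowSums(d^2)[km$cluster == j]) / p
  }, numeric(1)), 1e-6)
  prop <- tabulate(km$cluster, k) / n
  logDens <- function() {
    ll <- matrix(0, n, k)
    for (j in seq_len(k)) {
      d2 <- rowSums((x - matrix(mu[j, ], n, p, byrow = TRUE))^2)
      ll[, j] <- log(prop[j]) - 0.5 * p * log(2 * pi * sig2[j]) - d2 / (2 * sig2[j])
    }
    ll
  }
  prev <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(maxIter)) {
    ll <- logDens()
    m <- apply(ll, 1, max)
    lse <- m + log(rowSums(exp(ll - m)))
    loglik <- sum(lse)
    resp <- exp(ll - lse)
    nk <- pmax(colSums(resp), 1e-10)
    prop <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      d2 <- rowSums((x - matrix(mu[j, ], n, p, byrow = TRUE))^2)
      sig2[j] <- max(sum(resp[, j] * d2) / (p * nk[j]), 1e-8)
    }
    if (is.finite(prev) && abs(loglik - prev) < tol * (1 + abs(loglik))) {
      converged <- TRUE
      break
    }
    prev <- loglik
  }
  if (!converged)
    stop("GMM failed to converge after ", it, " iterations", call. = FALSE)
  list(mu = mu, sig2 = sig2, prop = prop, resp = resp,
       cluster = max.col(resp), iterations = it)
}

#' Detect the cervix ROI with a spherical GMM on the Ra space
#'
#' Standardizes (R, a) jointly, fits a Gaussian mixture with spherical
#' covariances (EM, K-means initialization with 10 restarts under `seed`),
#' assigns every pixel to its most probable component, and takes as cervix the
#' component whose pixels have the smallest mean R (ties broken by larger mean
#' a*). The binary mask is cleaned up by keeping the largest connected
#' component and filling holes — specular or lesion pixels misassigned inside
#' the disk are recovered here.
#'
#' @param ra result of [toRaSpace()].
#' @param img the RGB image the crop will be taken from (used by
#'   [detectRoi()]; not needed for the mask itself).
#' @param nComponents mixture size, default 2 (cervix vs everything else).
#' @param seed integer seed for the K-means initialization.
#' @param maxFit at most this many pixels (deterministic subsample) are used
#'   to fit the EM; all pixels are assigned from the fitted parameters.
#' @return list with `mask` (logical matrix), `center` (mask centroid,
#'   0-based), `radius` (equal-area disk radius), and `iterations`.
#' @export
fitRoiGmm <- function(ra, nComponents = 2L, seed = 1L, maxFit = 20000L) {
  if (!is.list(ra) || is.null(ra$R) || is.null(ra$a))
    stop("ra must come from toRaSpace()", call. = FALSE)
  if (nComponents < 2L) stop("nComponents must be >= 2", call. = FALSE)
  x <- cbind(R = as.vector(ra$R), a = as.vector(ra$a))
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  n <- nrow(xs)
  fitIdx <- if (n > maxFit) {
    set.seed(as.integer(seed))
    sort(sample.int(n, maxFit))
  } else seq_len(n)
  fit <- sphericalGmm(xs[fitIdx, , drop = FALSE], nComponents, seed)
  # assign every pixel from the fitted parameters
  k <- nComponents
  ll <- matrix(0, n, k)
  for (j in seq_len(k)) {
    d2 <- rowSums((xs - matrix(fit$mu[j, ], n, 2, byrow = TRUE))^2)
    ll[, j] <- log(fit$prop[j]) - log(fit$sig2[j]) - d2 / (2 * fit$sig2[j])
  }
  cl <- max.col(ll, ties.method = "first")
  meanR <- vapply(seq_len(k), function(j)
    if (any(cl == j)) mean(x[cl == j, 1]) else Inf, numeric(1))
  meanA <- vapply(seq_len(k), function(j)
    if (any(cl == j)) mean(x[cl == j, 2]) else -Inf, numeric(1))
  ord <- order(meanR, -meanA)
  pick <- ord[1]
  mask <- matrix(cl == pick, nrow(ra$R), ncol(ra$R))
  if (!any(mask)) mask <- matrix(cl == ord[2], nrow(ra$R), ncol(ra$R))
  mask <- tidyMask(mask)
  cent <- maskCentroid(mask)
  list(mask = mask, center = cent, radius = sqrt(sum(mask) / pi),
       iterations = fit$iterations)
}

# Largest connected component + hole fill (EBImage).
tidyMask <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  EBImage::fillHull(mask * 1) > 0
}

maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
}

#' Crop the ROI and zoom it to a fixed size
#'
#' Takes the tight bounding box of the mask, expands it by 5% of the box
#' height/width per side (rounded), clips to the image bounds, crops, and
#' resizes to `size` with bilinear interpolation. The mask is cropped and
#' resized identically with nearest-neighbour interpolation and carried
#' forward for masked feature extraction.
#'
#' @param img RGB image array.
#' @param mask logical matrix of the same height/width; must be non-empty.
#' @param size output side length pair, default `c(200, 200)`.
#' @param pad padding fraction per side, default 0.05.
#' @return list with `crop` (RGB array) and `cropMask` (logical matrix).
#' @export
cropAndZoom <- function(img, mask, size = c(200L, 200L), pad = 0.05) {
  assertRgbImage(img)
  mask <- assertBinaryMask(mask)
  if (!any(mask))
    stop("empty ROI mask: fall back to a whole-image ROI", call. = FALSE)
  if (!identical(dim(mask), dim(img)[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  padR <- round(pad * (r1 - r0 + 1)); padC <- round(pad * (c1 - c0 + 1))
  r0 <- max(r0 - padR, 1L); r1 <- min(r1 + padR, nrow(mask))
  c0 <- max(c0 - padC, 1L); c1 <- min(c1 + padC, ncol(mask))
  sub <- img[r0:r1, c0:c1, , drop = FALSE]
  subMask <- mask[r0:r1, c0:c1, drop = FALSE]
  list(crop = resizeImage(sub, size),
       cropMask = nearestMatrix(subMask, size[1], size[2]) > 0,
       bounds = c(r0, r1, c0, c1))
}

#' Full ROI detection on one image
#'
#' Convenience wrapper: [toRaSpace()] then [fitRoiGmm()] then [cropAndZoom()],
#' returning a [RoiResult-class].
#'
#' @inheritParams fitRoiGmm
#' @param img RGB image array.
#' @param size crop size, default 200 x 200.
#' @return a [RoiResult-class].
#' @export
detectRoi <- function(img, nComponents = 2L, seed = 1L, size = c(200L, 200L)) {
  ra <- toRaSpace(img)
  g <- fitRoiGmm(ra, nComponents = nComponents, seed = seed)
  cz <- cropAndZoom(img, g$mask, size = size)
  methods::new("RoiResult", mask = g$mask, center = g$center, radius = g$radius,
               crop = cz$crop, cropMask = cz$cropMask)
}
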