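# NGTDM (Amadasun-King) and GLSZM feature families.

#' NGTDM texture features (coarseness, contrast, busyness, complexity, strength)
#'
#' Amadasun-King neighbourhood gray-tone difference features. For every
#' masked pixel with at least one masked 8-neighbour, the absolute difference
#' between its gray level and the mean of its masked neighbours is
#' accumulated per level (`s_i`); `p_i` is the fraction of such pixels at
#' level i. Guards for degenerate regions: with a single occupied gray level
#' contrast and strength are 0 and coarseness hits its documented cap of 1e6
#' (the `sum(s_i) = 0` limit).
#'
#' @param q quantized raster with NA outside the mask (see [quantizeGray()]).
#' @param mask optional logical matrix applied to `q`.
#' @param levels number of gray levels; defaults to the maximum of `q`.
#' @return named numeric of length 5.
#' @export
ngtdmFeatures <- function(q, mask = NULL, levels = NULL) {
  if (!is.null(mask)) {
    mask <- assertBinaryMask(mask)
    q[!mask] <- NA_integer_
  }
  if (is.null(levels)) levels <- max(q, na.rm = TRUE)
  inMask <- !is.na(q)
  vals <- ifelse(inMask, q, 0)
  nbSum <- boxSumZero(vals) - vals
  nbCnt <- boxSumZero(inMask * 1) - inMask
  valid <- inMask & nbCnt > 0
  if (!any(valid)) stop("mask contains no pixel with masked neighbours", call. = FALSE)
  A <- nbSum[valid] / nbCnt[valid]
  g <- q[valid]
  N <- length(g)
  s <- vapply(seq_len(levels), function(i) sum(abs(i - A)[g == i]), numeric(1))
  n_i <- tabulate(g, levels)
  p <- n_i / N
  occ <- which(p > 0)
  Ng <- length(occ)

  coarseness <- if (sum(p * s) < 1e-12) 1e6 else min(1 / sum(p * s), 1e6)
  contrast <- if (Ng < 2) 0 else {
    pd <- outer(p[occ], p[occ]) * outer(occ, occ, function(a, b) (a - b)^2)
    (sum(pd) / (Ng * (Ng - 1))) * (sum(s) / N)
  }
  busyness <- if (Ng < 2) 0 else {
    denom <- sum(abs(outer(occ * p[occ], occ * p[occ], "-")))
    if (denom < 1e-12) 0 else sum(p * s) / denom
  }
  complexity <- if (Ng < 2) 0 else {
    ii <- matrix(occ, Ng, Ng); jj <- t(ii)
    pi_ <- p[occ]; si <- s[occ]
    pim <- matrix(pi_, Ng, Ng); pjm <- t(pim)
    sim <- matrix(si, Ng, Ng); sjm <- t(sim)
    sum(abs(ii - jj) * (pim * sim + pjm * sjm) / (N * (pim + pjm)))
  }
  strength <- if (sum(s) < 1e-12) 0 else {
    ii <- matrix(occ, Ng, Ng); jj <- t(ii)
    pim <- matrix(p[occ], Ng, Ng); pjm <- t(pim)
    sum((pim + pjm) * (ii - jj)^2) / sum(s)
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

# 3x3 box sum with zero padding (not replicate: neighbours outside the image
# must not count).
boxSumZero <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[(1:h) + dr, (1:w) + dc, drop = FALSE]
  out
}

# Size-zone matrix: counts of zones by (gray level, zone size).
sizeZoneTable <- function(q) {
  inMask <- which(!is.na(q))
  if (length(inMask) == 0L) stop("empty mask", call. = FALSE)
  h <- nrow(q); w <- ncol(q)
  pos <- arrayInd(inMask, dim(q))
  vid <- integer(h * w); vid[inMask] <- seq_along(inMask)
  lev <- q[inMask]
  from <- integer(0); to <- integer(0)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (d in offs) {
    nr <- pos[, 1] + d[1]; nc <- pos[, 2] + d[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nIdx <- integer(length(ok)); nIdx[ok] <- (nc[ok] - 1L) * h + nr[ok]
    ok[ok] <- vid[nIdx[ok]] > 0L
    same <- ok
    same[ok] <- lev[vid[nIdx[ok]]] == lev[ok]
    if (any(same)) {
      from <- c(from, which(same))
      to <- c(to, vid[nIdx[same]])
    }
  }
  gr <- igraph::make_graph(edges = as.vector(rbind(from, to)),
                           n = length(inMask), directed = FALSE)
  comp <- igraph::components(gr)$membership
  zoneLevel <- lev[!duplicated(comp)]
  zoneSize <- as.integer(table(comp))
  data.frame(level = zoneLevel[order(unique(comp))], size = zoneSize)
}

#' GLSZM texture features over a masked quantized raster
#'
#' Zones are 8-connected components of equal quantized gray level inside the
#' mask. Fourteen statistics are reported: small/large zone emphasis,
#' gray-level non-uniformity (plus its normalized form), zone-size
#' non-uniformity, zone percentage, low/high gray-level zone emphasis, the
#' four small/large x low/high combinations, and gray-level / zone-size
#' variances.
#'
#' @inheritParams ngtdmFeatures
#' @return named numeric of length 14.
#' @export
glszmFeatures <- function(q, mask = NULL, levels = NULL) {
  if (!is.null(mask)) {
    mask <- assertBinaryMask(mask)
    q[!mask] <- NA_integer_
  }
  zt <- sizeZoneTable(q)
  Np <- sum(!is.na(q))
  Nz <- nrow(zt)
  i <- zt$level; s <- zt$size
  glnCounts <- tapply(rep(1, Nz), i, sum)          # zones per gray level
  zsnCounts <- tapply(rep(1, Nz), s, sum)          # zones per size
  p <- 1 / Nz                                       # each zone counts once
  mu_i <- sum(i) / Nz
  mu_s <- sum(s) / Nz
  c(glszm_sze = sum(1 / s^2) / Nz,
    glszm_lze = sum(s^2) / Nz,
    glszm_gln = sum(glnCounts^2) / Nz,
    glszm_glnn = sum(glnCounts^2) / Nz^2,
    glszm_zsn = sum(zsnCounts^2) / Nz,
    glszm_zp = Nz / Np,
    glszm_lglze = sum(1 / i^2) / Nz,
    glszm_hglze = sum(i^2) / Nz,
    glszm_szlge = sum(1 / (i^2 * s^2)) / Nz,
    glszm_szhge = sum(i^2 / s^2) / Nz,
    glszm_lzlge = sum(s^2 / i^2) / Nz,
    glszm_lzhge = sum(i^2 * s^2) / Nz,
    glszm_glv = sum((i - mu_i)^2) / Nz,
    glszm_zsv = sum((s - mu_s)^2) / Nz)
}
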