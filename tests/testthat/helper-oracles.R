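# Naive, loop-based reference implementations, kept deliberately independent
# of the package's vectorized code paths. Used on small rasters only.

# Co-occurrence counts for one direction by explicit pair enumeration.
oracleCooc <- function(q, dr, dc, levels) {
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
    a <- q[r, c]; b <- q[r2, c2]
    if (is.na(a) || is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P / sum(P)
}

# Literal-transcription Haralick statistics computed with explicit loops.
oracleHaralick <- function(P) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; for (i in 1:L) mux <- mux + i * px[i]
  muy <- 0; for (j in 1:L) muy <- muy + j * py[j]
  sx <- sqrt(sum((1:L - mux)^2 * px)); sy <- sqrt(sum((1:L - muy)^2 * py))
  psum <- rep(0, 2 * L); pdiff <- rep(0, L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  energy <- sum(P^2)
  contrast <- 0; for (i in 1:L) for (j in 1:L) contrast <- contrast + (i - j)^2 * P[i, j]
  correlation <- if (sx * sy < 1e-12) 0 else {
    s <- 0; for (i in 1:L) for (j in 1:L) s <- s + i * j * P[i, j]
    (s - mux * muy) / (sx * sy)
  }
  variance <- 0; for (i in 1:L) for (j in 1:L) variance <- variance + (i - mux)^2 * P[i, j]
  homogeneity <- 0
  for (i in 1:L) for (j in 1:L) homogeneity <- homogeneity + P[i, j] / (1 + (i - j)^2)
  sa <- sum((2:(2 * L)) * psum[2:(2 * L)])
  sv <- sum(((2:(2 * L)) - sa)^2 * psum[2:(2 * L)])
  se <- ent(psum)
  entropy <- ent(P)
  mud <- sum((0:(L - 1)) * pdiff)
  dv <- sum(((0:(L - 1)) - mud)^2 * pdiff)
  de <- ent(pdiff)
  hx <- ent(px); hy <- ent(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    if (px[i] * py[j] > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
    }
  }
  imc1 <- if (max(hx, hy) < 1e-12) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - entropy)), 0))
  keep <- which(px > 0)
  mcc <- if (length(keep) < 2) 0 else {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (k in seq_along(keep))
        s <- s + P[keep[a], keep[k]] * P[keep[b], keep[k]] /
          (px[keep[a]] * py[keep[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(min(ev[2], 1), 0))
  }
  c(energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, homogeneity = homogeneity, sum_average = sa,
    sum_variance = sv, sum_entropy = se, entropy = entropy,
    difference_variance = dv, difference_entropy = de,
    imc1 = imc1, imc2 = imc2, mcc = mcc)
}

oracleGlcmFeatures <- function(q, levels) {
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  stats <- sapply(dirs, function(d) oracleHaralick(oracleCooc(q, d[1], d[2], levels)))
  out <- numeric(0)
  for (nm in rownames(stats)) {
    out[paste0("glcm_", nm, "_mean")] <- mean(stats[nm, ])
    out[paste0("glcm_", nm, "_range")] <- max(stats[nm, ]) - min(stats[nm, ])
  }
  out
}

# Amadasun-King NGTDM by exhaustive loops.
oracleNgtdm <- function(q, levels) {
  h <- nrow(q); w <- ncol(q)
  s <- rep(0, levels); n_i <- rep(0, levels); N <- 0
  for (r in 1:h) for (c in 1:w) {
    if (is.na(q[r, c])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && !is.na(q[rr, cc]))
        nb <- c(nb, q[rr, cc])
    }
    if (length(nb) == 0) next
    i <- q[r, c]
    s[i] <- s[i] + abs(i - mean(nb))
    n_i[i] <- n_i[i] + 1
    N <- N + 1
  }
  p <- n_i / N
  occ <- which(p > 0); Ng <- length(occ)
  coarseness <- if (sum(p * s) < 1e-12) 1e6 else min(1 / sum(p * s), 1e6)
  contrast <- 0; busyden <- 0; complexity <- 0; strengthnum <- 0
  if (Ng >= 2) {
    for (i in occ) for (j in occ) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busyden <- busyden + abs(i * p[i] - j * p[j])
      complexity <- complexity + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
        (N * (p[i] + p[j]))
      strengthnum <- strengthnum + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (Ng * (Ng - 1)) * sum(s) / N
  }
  busyness <- if (Ng < 2 || busyden < 1e-12) 0 else sum(p * s) / busyden
  strength <- if (sum(s) < 1e-12) 0 else strengthnum / sum(s)
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = if (Ng < 2) 0 else complexity,
    ngtdm_strength = strength)
}

# 8-connected zones by explicit stack-based flood fill.
oracleZones <- function(q) {
  h <- nrow(q); w <- ncol(q)
  seen <- matrix(FALSE, h, w)
  zones <- data.frame(level = integer(0), size = integer(0))
  for (r in 1:h) for (c in 1:w) {
    if (is.na(q[r, c]) || seen[r, c]) next
    lev <- q[r, c]; size <- 0
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (!seen[rr, cc] && !is.na(q[rr, cc]) && q[rr, cc] == lev) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
    zones <- rbind(zones, data.frame(level = lev, size = size))
  }
  zones[order(zones$level, zones$size), , drop = FALSE]
}

oracleGlszm <- function(q) {
  zt <- oracleZones(q)
  Np <- sum(!is.na(q)); Nz <- nrow(zt)
  i <- zt$level; s <- zt$size
  gln <- sum(table(i)^2); zsn <- sum(table(s)^2)
  c(glszm_sze = sum(1 / s^2) / Nz, glszm_lze = sum(s^2) / Nz,
    glszm_gln = gln / Nz, glszm_glnn = gln / Nz^2, glszm_zsn = zsn / Nz,
    glszm_zp = Nz / Np, glszm_lglze = sum(1 / i^2) / Nz,
    glszm_hglze = sum(i^2) / Nz, glszm_szlge = sum(1 / (i^2 * s^2)) / Nz,
    glszm_szhge = sum(i^2 / s^2) / Nz, glszm_lzlge = sum(s^2 / i^2) / Nz,
    glszm_lzhge = sum(i^2 * s^2) / Nz,
    glszm_glv = sum((i - mean(i))^2) / Nz,
    glszm_zsv = sum((s - mean(s))^2) / Nz)
}

# Uniform LBP histogram by explicit per-pixel loops.
oracleLbp <- function(gray, mask) {
  h <- nrow(gray); w <- ncol(gray)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bins <- rep(0, 10)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    if (!mask[r, c]) next
    ok <- TRUE; bits <- integer(8)
    for (k in 1:8) {
      rr <- r + offs[[k]][1]; cc <- c + offs[[k]][2]
      if (!mask[rr, cc]) { ok <- FALSE; break }
      bits[k] <- as.integer(gray[rr, cc] >= gray[r, c])
    }
    if (!ok) next
    trans <- sum(bits != bits[c(2:8, 1)])
    b <- if (trans <= 2) sum(bits) + 1 else 10
    bins[b] <- bins[b] + 1
  }
  bins / sum(bins)
}

# Exhaustive threshold-sweep precision at a recall floor.
oraclePrecisionAtRecall <- function(scores, labels, minRecall = 0.8) {
  best <- -Inf
  for (t in c(scores, -Inf)) {
    tp <- 0; fp <- 0; fn <- 0
    for (k in seq_along(scores)) {
      if (scores[k] >= t) { if (labels[k] == 1) tp <- tp + 1 else fp <- fp + 1 }
      else if (labels[k] == 1) fn <- fn + 1
    }
    if (tp + fn > 0 && tp / (tp + fn) >= minRecall && tp + fp > 0)
      best <- max(best, tp / (tp + fp))
  }
  best
}

# AUC as the normalized Mann-Whitney U statistic (ties get half credit).
oracleAucU <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  u <- 0
  for (p in pos) for (n in neg) u <- u + (p > n) + 0.5 * (p == n)
  u / (length(pos) * length(neg))
}

# Random quantized raster with a fixed number of gray levels.
randomRaster <- function(h, w, levels) {
  matrix(sample(seq_len(levels), h * w, replace = TRUE), h, w)
}
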