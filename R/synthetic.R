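#' Configuration for the synthetic cervix scene generator
#'
#' Defines the study conditions the generator emulates: a roughly circular
#' pink cervix centred in frame, a darker low-chroma vaginal-wall surround,
#' small saturated specular highlights, and — for positive scenes — a single
#' matte whitish acetowhite patch with a soft (Gaussian-falloff) edge inside
#' the cervix disk. Colours are mean RGB triples; `noiseSd` is the per-channel
#' Gaussian pixel noise applied to the composed scene before clipping.
#'
#' @param imageSize integer pair (height, width), default 400 x 400.
#' @param cervixRadiusRange fraction of the smaller image dimension.
#' @param centerJitter maximum cervix-centre offset as a fraction of each
#'   dimension (kept within the 10% centring contract).
#' @param cervixColor,backgroundColor,lesionColor mean RGB triples (0-255).
#' @param noiseSd per-channel Gaussian noise standard deviation in 8-bit units.
#' @param nSpecularRange integer range of highlight count per scene.
#' @param specularRadiusRange highlight core radius range in pixels.
#' @param lesionRadiusRange lesion semi-axis range as a fraction of the cervix
#'   radius.
#' @param lesionContrast scalar in \[0, 1\] blending `lesionColor` towards
#'   `cervixColor`; 1 is full contrast, 0 makes lesions invisible (used to
#'   drive the pipeline down to chance as a negative control).
#' @param prevalence fraction of positive scenes in a generated dataset.
#' @return a validated list of class `"GeneratorConfig"`.
#' @examples
#' cfg <- generatorConfig(imageSize = c(120, 120))
#' @export
generatorConfig <- function(imageSize = c(400L, 400L),
                            cervixRadiusRange = c(0.28, 0.38),
                            centerJitter = 0.05,
                            cervixColor = c(205, 120, 130),
                            backgroundColor = c(70, 50, 55),
                            lesionColor = c(235, 205, 215),
                            noiseSd = 8,
                            nSpecularRange = c(3L, 8L),
                            specularRadiusRange = c(2, 6),
                            lesionRadiusRange = c(0.25, 0.45),
                            lesionContrast = 1,
                            prevalence = 0.181) {
  cfg <- list(imageSize = as.integer(imageSize),
              cervixRadiusRange = as.numeric(cervixRadiusRange),
              centerJitter = as.numeric(centerJitter),
              cervixColor = as.numeric(cervixColor),
              backgroundColor = as.numeric(backgroundColor),
              lesionColor = as.numeric(lesionColor),
              noiseSd = as.numeric(noiseSd),
              nSpecularRange = as.integer(nSpecularRange),
              specularRadiusRange = as.numeric(specularRadiusRange),
              lesionRadiusRange = as.numeric(lesionRadiusRange),
              lesionContrast = as.numeric(lesionContrast),
              prevalence = as.numeric(prevalence))
  class(cfg) <- "GeneratorConfig"
  validateGeneratorConfig(cfg)
  cfg
}

validateGeneratorConfig <- function(cfg) {
  bad <- function(field, why) stop("invalid GeneratorConfig field '", field, "': ",
                                   why, call. = FALSE)
  if (length(cfg$imageSize) != 2L || any(is.na(cfg$imageSize)) || any(cfg$imageSize < 32L))
    bad("imageSize", "must be two integers >= 32")
  rng <- function(field, lo, hi) {
    x <- cfg[[field]]
    if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < lo || x[2] > hi)
      bad(field, sprintf("must be a non-empty range within [%s, %s]", lo, hi))
  }
  rng("cervixRadiusRange", 0.05, 0.49)
  rng("nSpecularRange", 0, 64)
  rng("specularRadiusRange", 1, 32)
  rng("lesionRadiusRange", 0.05, 0.9)
  for (field in c("cervixColor", "backgroundColor", "lesionColor")) {
    x <- cfg[[field]]
    if (length(x) != 3L || anyNA(x) || any(x < 0) || any(x > 255))
      bad(field, "must be an RGB triple in [0, 255]")
  }
  if (length(cfg$prevalence) != 1L || is.na(cfg$prevalence) ||
      cfg$prevalence < 0 || cfg$prevalence > 1)
    bad("prevalence", "must lie in [0, 1]")
  if (cfg$centerJitter < 0 || cfg$centerJitter > 0.1)
    bad("centerJitter", "must lie in [0, 0.1]")
  if (cfg$noiseSd < 0) bad("noiseSd", "must be >= 0")
  if (cfg$lesionContrast < 0 || cfg$lesionContrast > 1)
    bad("lesionContrast", "must lie in [0, 1]")
  invisible(cfg)
}

# Distance-from-point rasters used by the painters.
distanceRaster <- function(h, w, center) {
  rr <- matrix(seq_len(h) - 1, h, w) - center[1]
  cc <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - center[2]
  sqrt(rr^2 + cc^2)
}

paintColor <- function(img, alpha, color) {
  for (ch in 1:3) img[, , ch] <- (1 - alpha) * img[, , ch] + alpha * color[ch]
  img
}

#' Generate one synthetic cervix scene
#'
#' Composes background, cervix disk (2 px soft rim), optional acetowhite
#' lesion (soft-edged rotated ellipse with Gaussian alpha falloff, so the
#' lesion contributes texture as well as colour contrast), adds Gaussian pixel
#' noise, clips to \[0, 255\], then paints the specular highlight cores last so
#' their pixels stay saturated (all channels >= 250, soft 1 px rim).
#' Identical `(config, label, seed)` always give a bit-identical scene.
#'
#' @param config a [generatorConfig()].
#' @param label 0 (negative) or 1 (positive: one lesion planted).
#' @param seed integer seed for this scene.
#' @param id optional scene identifier string.
#' @return a [SyntheticScene-class].
#' @examples
#' sc <- generateScene(generatorConfig(imageSize = c(96, 96)), label = 1, seed = 3)
#' sum(lesionMask(sc)) > 0
#' @export
generateScene <- function(config = generatorConfig(), label, seed, id = NULL) {
  validateGeneratorConfig(config)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  seed <- as.integer(seed)
  h <- config$imageSize[1]; w <- config$imageSize[2]

  set.seed(seed)
  ctr0 <- c((h - 1) / 2, (w - 1) / 2)
  jit <- c(stats::runif(1, -1, 1) * config$centerJitter * h,
           stats::runif(1, -1, 1) * config$centerJitter * w)
  center <- ctr0 + jit
  rc <- stats::runif(1, config$cervixRadiusRange[1], config$cervixRadiusRange[2]) *
    min(h, w)

  dc <- distanceRaster(h, w, center)
  cervixMask <- dc <= rc
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- config$backgroundColor[ch]
  # soft 2 px rim on the cervix disk
  rimAlpha <- pmin(pmax((rc - dc) / 2 + 0.5, 0), 1)
  img <- paintColor(img, rimAlpha, config$cervixColor)

  lesion <- matrix(FALSE, h, w)
  if (label == 1L) {
    # one rotated ellipse fully inside the disk, Gaussian alpha falloff
    a <- stats::runif(1, config$lesionRadiusRange[1], config$lesionRadiusRange[2]) * rc
    b <- stats::runif(1, config$lesionRadiusRange[1], config$lesionRadiusRange[2]) * rc
    maxOff <- max(rc - 1.45 * max(a, b), 0)
    phi <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, 0, maxOff)
    lc <- center + off * c(sin(phi), cos(phi))
    theta <- stats::runif(1, 0, pi)
    rr <- matrix(seq_len(h) - 1, h, w) - lc[1]
    cc <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - lc[2]
    u <- cos(theta) * cc + sin(theta) * rr
    v <- -sin(theta) * cc + cos(theta) * rr
    rho <- sqrt((u / b)^2 + (v / a)^2)
    alpha <- exp(-0.5 * (rho / 0.6)^2)
    img <- paintColor(img, alpha * config$lesionContrast, config$lesionColor)
    if (config$lesionContrast > 0) lesion <- alpha > 0.5 & cervixMask
  }

  if (config$noiseSd > 0)
    img <- img + array(stats::rnorm(h * w * 3, 0, config$noiseSd), dim = c(h, w, 3))
  img <- clip255(img)

  # specular highlights painted after the noise so cores stay saturated
  nSpec <- if (config$nSpecularRange[1] == config$nSpecularRange[2])
    config$nSpecularRange[1] else
    sample(seq(config$nSpecularRange[1], config$nSpecularRange[2]), 1)
  specular <- matrix(FALSE, h, w)
  if (nSpec > 0) {
    for (k in seq_len(nSpec)) {
      sr <- stats::runif(1, config$specularRadiusRange[1], config$specularRadiusRange[2])
      phi <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, 0, max(rc - sr - 2, 0))
      sc <- center + off * c(sin(phi), cos(phi))
      # paint only a local window around the highlight
      rws <- max(1, floor(sc[1] - sr - 2)):min(h, ceiling(sc[1] + sr + 2))
      cls <- max(1, floor(sc[2] - sr - 2)):min(w, ceiling(sc[2] + sr + 2))
      dr <- outer(rws - 1 - sc[1], rep(1, length(cls)))
      dc <- outer(rep(1, length(rws)), cls - 1 - sc[2])
      ds <- sqrt(dr^2 + dc^2)
      rim <- pmin(pmax(sr + 1 - ds, 0), 1)   # 1 px soft rim
      for (ch in 1:3)
        img[rws, cls, ch] <- (1 - rim) * img[rws, cls, ch] + rim * 253
      core <- matrix(FALSE, h, w)
      core[rws, cls] <- ds <= sr
      specular <- specular | core
    }
    # re-assert saturation on the cores (blending plus noise must not dim them)
    sel <- which(specular)
    n <- h * w
    for (ch in 0:2) img[sel + ch * n] <- pmax(img[sel + ch * n], 250)
  }

  img <- round(img)  # 8-bit raster; also makes PNG round-trips exact
  methods::new("SyntheticScene", image = img, label = label,
               cervixMask = cervixMask, specularMask = specular,
               lesionMask = lesion, seed = seed,
               id = if (is.null(id)) sprintf("scene_seed%d", seed) else id)
}

# Counter-based per-scene seed stream: scene k under master seed s is
# reproducible independently of batch size. Stays below 2^31 - 1.
sceneSeedStream <- function(masterSeed, k) {
  as.integer(((masterSeed %% 1000003L) * 2011 + k) %% 2147483647)
}

#' Generate a labelled dataset of synthetic scenes
#'
#' `round(n * prevalence)` scenes are positive; the label order is shuffled
#' deterministically under the master seed, and scene `k` is drawn from a
#' counter-based seed so it is reproducible regardless of `n`.
#'
#' @param config a [generatorConfig()].
#' @param n number of scenes (>= 1).
#' @param seed master seed.
#' @return list with `scenes` (list of [SyntheticScene-class]) and `labels`
#'   (data.frame with `id`, `label`, `seed`).
#' @examples
#' ds <- generateDataset(generatorConfig(imageSize = c(96, 96)), n = 4, seed = 1)
#' ds$labels
#' @export
generateDataset <- function(config = generatorConfig(), n, seed) {
  validateGeneratorConfig(config)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  nPos <- as.integer(round(n * config$prevalence))
  set.seed(as.integer(seed))
  labels <- sample(c(rep(1L, nPos), rep(0L, n - nPos)))
  scenes <- vector("list", n)
  for (k in seq_len(n)) {
    scenes[[k]] <- generateScene(config, labels[k], sceneSeedStream(seed, k),
                                 id = sprintf("scene_%04d", k))
  }
  labTab <- data.frame(id = vapply(scenes, function(s) s@id, character(1)),
                       label = labels,
                       seed = vapply(scenes, function(s) s@seed, integer(1)),
                       stringsAsFactors = FALSE)
  list(scenes = scenes, labels = labTab)
}

#' Write scenes to a directory as PNGs with a JSON sidecar
#'
#' Each scene is written as `<id>.png` plus single-channel 0/255 mask PNGs,
#' and `dataset.json` records id, label, seed and the file paths.
#'
#' @param dataset result of [generateDataset()], or a list of scenes.
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
writeDataset <- function(dataset, dir) {
  scenes <- if (!is.null(dataset$scenes)) dataset$scenes else dataset
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(scenes, function(s) {
    base <- s@id
    img <- file.path(dir, paste0(base, ".png"))
    png::writePNG(s@image / 255, img)
    maskFiles <- list()
    for (nm in c("cervixMask", "specularMask", "lesionMask")) {
      f <- file.path(dir, paste0(base, "_", sub("Mask", "", nm), "_mask.png"))
      png::writePNG(slot(s, nm) * 1, f)
      maskFiles[[nm]] <- basename(f)
    }
    list(id = base, label = s@label, seed = s@seed,
         image = basename(img), masks = maskFiles)
  })
  sidecar <- file.path(dir, "dataset.json")
  jsonlite::write_json(entries, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Read a scene dataset written by [writeDataset()]
#'
#' @param dir dataset directory containing `dataset.json`.
#' @return list with `scenes` and `labels`, as from [generateDataset()].
#' @export
readDataset <- function(dir) {
  sidecar <- file.path(dir, "dataset.json")
  if (!file.exists(sidecar)) stop("no dataset.json in ", dir, call. = FALSE)
  entries <- jsonlite::read_json(sidecar)
  scenes <- lapply(entries, function(e) {
    img <- readImageFile(file.path(dir, e$image))
    readMask <- function(f) png::readPNG(file.path(dir, f)) > 0.5
    methods::new("SyntheticScene", image = img, label = as.integer(e$label),
                 cervixMask = readMask(e$masks$cervixMask),
                 specularMask = readMask(e$masks$specularMask),
                 lesionMask = readMask(e$masks$lesionMask),
                 seed = as.integer(e$seed), id = e$id)
  })
  labTab <- data.frame(id = vapply(entries, function(e) e$id, character(1)),
                       label = vapply(entries, function(e) as.integer(e$label), integer(1)),
                       seed = vapply(entries, function(e) as.integer(e$seed), integer(1)),
                       stringsAsFactors = FALSE)
  list(scenes = scenes, labels = labTab)
}

#' Read an RGB image file (PNG) as a 0-255 array
#' @param path file path.
#' @return H x W x 3 numeric array.
#' @export
readImageFile <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}
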