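test_that("colour features match direct arithmetic", {
  gray <- array(128, dim = c(16, 16, 3))
  f <- colorFeatures(gray, matrix(TRUE, 16, 16))
  expect_equal(unname(f[c("color_mean_R", "color_mean_G", "color_mean_B")]),
               c(128, 128, 128))
  expect_equal(unname(f[grep("color_std", names(f))]), rep(0, 6))
  expect_equal(f[["color_mean_GR"]], 128 / 129)  # denominator guard R + 1
  expect_equal(f[["color_mean_V"]], 128 / 255)

  uni <- array(0, dim = c(16, 16, 3))
  uni[, , 1] <- 200; uni[, , 2] <- 100; uni[, , 3] <- 50
  f2 <- colorFeatures(uni, matrix(TRUE, 16, 16))
  expect_equal(f2[["color_mean_BR"]], 50 / 201)
  expect_equal(f2[["color_mean_GR"]], 100 / 201)

  onePx <- matrix(FALSE, 16, 16); onePx[3, 3] <- TRUE
  expect_error(colorFeatures(gray, onePx), "64")
})

test_that("GLCM features match the brute-force pair-enumeration oracle", {
  toy <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 3, 3),
                4, 4, byrow = TRUE) + 1L
  expect_equal(glcmFeatures(toy, levels = 4L),
               oracleGlcmFeatures(toy, levels = 4L), tolerance = 1e-12)
  # direction 0: co-occurrence counts equal the enumerated pair table
  P <- viascreen:::coocMatrix(toy, 0L, 1L, 4L)
  expect_equal(unclass(P), unclass(oracleCooc(toy, 0, 1, 4)))

  # constant region: energy 1, contrast 0
  const <- glcmFeatures(matrix(1L, 8, 8), levels = 16L)
  expect_equal(const[["glcm_energy_mean"]], 1)
  expect_equal(const[["glcm_contrast_mean"]], 0)

  # rotating the raster by 90 degrees leaves the direction means unchanged
  set.seed(3)
  q <- randomRaster(6, 6, 3)
  rot <- t(q[nrow(q):1, ])
  f1 <- glcmFeatures(q, levels = 3L); f2 <- glcmFeatures(rot, levels = 3L)
  means <- grep("_mean$", names(f1), value = TRUE)
  expect_equal(f1[means], f2[means], tolerance = 1e-10)
})

test_that("NGTDM features match the Amadasun-King loop oracle", {
  toy <- matrix(c(1, 1, 2, 2, 1, 2, 2, 1, 1, 1, 2, 1, 2, 2, 1, 1), 4, 4)
  expect_equal(ngtdmFeatures(toy, levels = 2L), oracleNgtdm(toy, 2L),
               tolerance = 1e-12)
  # constant region: coarseness capped, contrast zero
  const <- ngtdmFeatures(matrix(1L, 6, 6), levels = 16L)
  expect_equal(const[["ngtdm_coarseness"]], 1e6)
  expect_equal(const[["ngtdm_contrast"]], 0)
  # doubling gray-level contrast strictly increases NGTDM contrast
  low <- matrix(rep(c(1L, 2L), 18), 6, 6)
  high <- matrix(rep(c(1L, 3L), 18), 6, 6)
  expect_gt(ngtdmFeatures(high, levels = 3L)[["ngtdm_contrast"]],
            ngtdmFeatures(low, levels = 3L)[["ngtdm_contrast"]])
})

test_that("GLSZM zones and statistics match the flood-fill oracle", {
  toy <- matrix(c(0, 0, 1, 0, 1, 1, 2, 2, 2), 3, 3, byrow = TRUE) + 1L
  zt <- viascreen:::sizeZoneTable(toy)
  zt <- zt[order(zt$level, zt$size), ]
  rownames(zt) <- NULL
  oz <- oracleZones(toy); rownames(oz) <- NULL
  expect_equal(zt, oz)   # hand-countable: three zones of sizes 3, 3, 3
  expect_equal(nrow(zt), 3)
  expect_equal(glszmFeatures(toy), oracleGlszm(toy), tolerance = 1e-12)

  # constant 10 x 10 region is a single zone: zone percentage = 0.01
  const <- glszmFeatures(matrix(1L, 10, 10))
  expect_equal(const[["glszm_zp"]], 0.01)
  expect_equal(const[["glszm_glv"]], 0)
})

test_that("GLSZM zone structure is invariant to monotone gray relabeling", {
  set.seed(7)
  q <- randomRaster(6, 6, 3)
  relabeled <- matrix(c(2L, 5L, 9L)[q], 6, 6)   # strictly increasing map
  zt1 <- viascreen:::sizeZoneTable(q)
  zt2 <- viascreen:::sizeZoneTable(relabeled)
  expect_equal(sort(zt1$size), sort(zt2$size))
  expect_equal(table(zt1$level), table(c(1L, 2L, 3L)[match(zt2$level, c(2L, 5L, 9L))]),
               ignore_attr = TRUE)
})

test_that("wavelet detail features behave as Haar analysis predicts", {
  expect_equal(unname(dwtFeatures(matrix(100, 8, 8))), rep(0, 6))
  # vertical step edge: energy lands in the x-detail (HL) band
  step <- matrix(0, 8, 8); step[, c(2, 4, 6, 8)] <- 100
  f <- dwtFeatures(step)
  expect_gt(f[["dwt_HL_mean"]], 10 * max(f[["dwt_LH_mean"]], 1e-9))
  expect_length(dwtFeatures(matrix(rnorm(36), 6, 6)), 6)
  expect_error(dwtFeatures(matrix(1, 1, 4)), "2 x 2")
  # db2 path also runs and yields 6 finite values
  expect_true(all(is.finite(dwtFeatures(matrix(rnorm(64), 8, 8), wavelet = "db2"))))
})

test_that("uniform LBP histogram matches the per-pixel code oracle", {
  set.seed(9)
  gray <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
  mask <- matrix(TRUE, 7, 7)
  expect_equal(unname(lbpFeatures(gray, mask)), oracleLbp(gray, mask),
               tolerance = 1e-12)
  # one hand-checked 3 x 3 neighbourhood: centre 5, ring values force the code
  toy <- matrix(c(9, 1, 1, 9, 5, 1, 9, 1, 1), 3, 3, byrow = TRUE)
  f <- lbpFeatures(toy, matrix(TRUE, 3, 3))
  # ring (E,NE,N,NW,W,SW,S,SE) = (1,1,1,9,9,9,1,1) -> bits 00011100: 3 ones,
  # two circular transitions -> uniform bin "3"
  expect_equal(f[["lbp_u3"]], 1)
  expect_equal(sum(f), 1)
  expect_length(f, 10)
  # constant region: all codes identical, mass in a single uniform bin
  fc <- lbpFeatures(matrix(7, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(max(fc), 1)
  expect_equal(sum(fc > 0), 1)
  expect_lt(which.max(fc), 10)  # a uniform bin, not the non-uniform catch-all
})

test_that("the assembled panel has 75 stably named features", {
  nm <- viaFeatureNames()
  expect_length(nm, 75)
  expect_equal(unname(attr(nm, "families")), c(12, 28, 5, 14, 6, 10))
  sc <- generateScene(smallSceneConfig(), label = 1, seed = 2)
  fv <- extractFeatures(sceneImage(sc), cervixMask(sc))
  expect_length(fv, 75)
  expect_identical(names(fv), as.vector(nm))
  expect_false(anyNA(fv))
  # deterministic
  fv2 <- extractFeatures(sceneImage(sc), cervixMask(sc))
  expect_identical(fv, fv2)
  # lbp block sums to one
  expect_equal(sum(fv[grep("^lbp_", names(fv))]), 1)
})

test_that("panel extraction has no NaN on any >= 64 pixel mask, even constant", {
  uni <- array(77, dim = c(20, 20, 3))
  fv <- extractFeatures(uni, matrix(TRUE, 20, 20))
  expect_false(any(is.na(fv)))
  small <- matrix(FALSE, 20, 20); small[1:8, 1:7] <- TRUE  # 56 px < 64
  expect_error(extractFeatures(uni, small), "64")
})
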