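test_that("identical seed and config give bit-identical scenes", {
  cfg <- smallSceneConfig()
  a <- generateScene(cfg, label = 0, seed = 7)
  b <- generateScene(cfg, label = 0, seed = 7)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(cervixMask(a), cervixMask(b))
  expect_identical(specularMask(a), specularMask(b))
})

test_that("positive scenes plant exactly one lesion patch inside the cervix", {
  sc <- generateScene(smallSceneConfig(), label = 1, seed = 3)
  expect_gt(sum(lesionMask(sc)), 0)
  expect_true(all(cervixMask(sc)[lesionMask(sc)]))
  # the patch is one connected blob
  lab <- EBImage::bwlabel(lesionMask(sc) * 1)
  expect_equal(max(lab), 1)
  neg <- generateScene(smallSceneConfig(), label = 0, seed = 3)
  expect_equal(sum(lesionMask(neg)), 0)
})

test_that("cervix region is redder (higher a*) than the surround", {
  for (seed in c(2, 9, 21)) {
    sc <- generateScene(smallSceneConfig(), label = 0, seed = seed)
    a <- viascreen:::labAChannel(sceneImage(sc))
    expect_gt(mean(a[cervixMask(sc)]), mean(a[!cervixMask(sc)]))
  }
})

test_that("specular highlight cores are saturated in every channel", {
  sc <- generateScene(smallSceneConfig(), label = 1, seed = 5)
  sel <- which(specularMask(sc))
  expect_gt(length(sel), 0)
  img <- sceneImage(sc)
  n <- prod(dim(img)[1:2])
  expect_gte(min(img[c(sel, sel + n, sel + 2 * n)]), 240)
})

test_that("cervix disk stays centred within 10% of the frame centre", {
  cfg <- smallSceneConfig()
  for (seed in 1:5) {
    sc <- generateScene(cfg, label = 0, seed = seed)
    cen <- viascreen:::maskCentroid(cervixMask(sc))
    ctr <- (cfg$imageSize - 1) / 2
    expect_lte(abs(cen[1] - ctr[1]), 0.1 * cfg$imageSize[1])
    expect_lte(abs(cen[2] - ctr[2]), 0.1 * cfg$imageSize[2])
  }
})

test_that("dataset prevalence is rounded deterministically", {
  cfg <- smallSceneConfig(prevalence = 0.181)
  ds <- generateDataset(cfg, n = 199, seed = 1)
  expect_equal(sum(ds$labels$label == 1), 36)  # round(199 * 0.181)
  expect_equal(sum(ds$labels$label == 0), 163)

  ds2 <- generateDataset(smallSceneConfig(prevalence = 0.154), n = 65, seed = 2)
  expect_equal(sum(ds2$labels$label == 1), 10)

  ds0 <- generateDataset(smallSceneConfig(prevalence = 0), n = 10, seed = 1)
  expect_equal(sum(ds0$labels$label), 0)
})

test_that("scene k is reproducible independently of batch size", {
  cfg <- smallSceneConfig(prevalence = 0)
  small <- generateDataset(cfg, n = 3, seed = 11)
  large <- generateDataset(cfg, n = 6, seed = 11)
  expect_identical(sceneImage(small$scenes[[2]]), sceneImage(large$scenes[[2]]))
})

test_that("invalid generator configuration names the offending field", {
  expect_error(generatorConfig(prevalence = 1.5), "prevalence")
  expect_error(generatorConfig(cervixColor = c(300, 0, 0)), "cervixColor")
  expect_error(generatorConfig(lesionRadiusRange = c(0.5, 0.2)),
               "lesionRadiusRange")
  expect_error(generateDataset(generatorConfig(), n = 0, seed = 1), "positive")
})

test_that("a written dataset reads back identically", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(smallSceneConfig(), n = 3, seed = 4)
  writeDataset(ds, dir)
  back <- readDataset(dir)
  expect_equal(back$labels$label, ds$labels$label)
  expect_equal(sceneImage(back$scenes[[1]]), sceneImage(ds$scenes[[1]]))
  expect_identical(lesionMask(back$scenes[[2]]), lesionMask(ds$scenes[[2]]))
})
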