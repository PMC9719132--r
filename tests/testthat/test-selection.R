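test_that("a duplicated column is pruned, keeping the earlier-ordered one", {
  set.seed(1)
  tab <- data.frame(a = rnorm(10), b = rnorm(10), check.names = FALSE)
  tab$a_copy <- tab$a
  tab <- tab[, c("a", "b", "a_copy")]
  st <- fitSelection(tab)
  expect_equal(keptFeatures(st), c("a", "b"))
  dr <- droppedFeatures(st)
  expect_equal(dr$feature, "a_copy")
  expect_equal(dr$partner, "a")
})

test_that("pruning follows the pairwise correlation structure", {
  # build 4 columns with r(1,2) ~ 0.95 and r(3,4) ~ 0.2
  set.seed(2)
  n <- 400
  f1 <- rnorm(n)
  f2 <- 0.95 * f1 + sqrt(1 - 0.95^2) * rnorm(n)
  f3 <- rnorm(n)
  f4 <- 0.2 * f3 + sqrt(1 - 0.2^2) * rnorm(n)
  tab <- data.frame(f1 = f1, f2 = f2, f3 = f3, f4 = f4)
  r <- abs(cor(as.matrix(tab)))   # independent check of the premise
  expect_gt(r["f1", "f2"], 0.9)
  expect_lt(r["f3", "f4"], 0.9)
  st <- fitSelection(tab, threshold = 0.9)
  expect_equal(keptFeatures(st), c("f1", "f3", "f4"))
})

test_that("zero-variance features are dropped unconditionally", {
  set.seed(3)
  tab <- data.frame(flat = rep(4, 10), x = rnorm(10), y = rnorm(10))
  st <- fitSelection(tab)
  expect_false("flat" %in% keptFeatures(st))
  expect_equal(droppedFeatures(st)$reason[droppedFeatures(st)$feature == "flat"],
               "zero-variance")
  expect_error(fitSelection(tab[1:2, ]), "3 training rows")
  expect_error(fitSelection(data.frame(flat = rep(1, 5))), "zero variance")
})

test_that("z-scoring reproduces its identities on train and shifted test data", {
  set.seed(4)
  train <- as.data.frame(matrix(rnorm(200), 20, 10))
  names(train) <- paste0("f", 1:10)
  st <- fitSelection(train)
  norm <- applySelection(train, st)
  for (f in keptFeatures(st)) {
    expect_equal(mean(norm[[f]]), 0, tolerance = 1e-9)
    expect_equal(viascreen:::popSd(norm[[f]]), 1, tolerance = 1e-9)
  }
  # a row equal to the training mean maps to all zeros
  meanRow <- as.data.frame(as.list(colMeans(train)))
  names(meanRow) <- names(train)
  expect_equal(unname(unlist(applySelection(meanRow, st))), rep(0, 10),
               tolerance = 1e-12)
  # a shifted test set lands at delta / sd, not at zero
  delta <- 3
  test <- train + delta
  normTest <- applySelection(test, st)
  for (f in keptFeatures(st)[1:3]) {
    expect_equal(mean(normTest[[f]]), delta / st@scale[[f]], tolerance = 1e-9)
  }
  expect_error(applySelection(train[, 1:3], st), "missing")
})

test_that("raising the threshold never decreases the kept-feature count", {
  set.seed(5)
  n <- 60
  base <- matrix(rnorm(n * 4), n, 4)
  tab <- as.data.frame(cbind(base,
                             base %*% matrix(runif(16, 0.3, 1), 4, 4) +
                               0.3 * matrix(rnorm(n * 4), n, 4)))
  names(tab) <- paste0("f", seq_len(ncol(tab)))
  counts <- vapply(c(0.5, 0.7, 0.9, 1.0), function(th)
    length(keptFeatures(fitSelection(tab, threshold = th))), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("selection state survives a JSON round trip", {
  set.seed(6)
  tab <- as.data.frame(matrix(rnorm(100), 10, 10))
  names(tab) <- paste0("f", 1:10)
  tab$f10 <- tab$f1          # force one drop
  st <- fitSelection(tab)
  path <- withr::local_tempfile(fileext = ".json")
  selectionToJson(st, path)
  back <- selectionFromJson(path)
  expect_equal(keptFeatures(back), keptFeatures(st))
  expect_equal(back@center, st@center)
  expect_equal(back@scale, st@scale)
  expect_equal(applySelection(tab, back), applySelection(tab, st))
})
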