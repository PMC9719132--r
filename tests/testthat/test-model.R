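test_that("precision at a recall floor matches the exhaustive sweep", {
  expect_equal(precisionAtRecall(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(precisionAtRecall(c(0.9, 0.6, 0.5, 0.4), c(1, 0, 1, 1)), 0.75)
  expect_equal(precisionAtRecall(c(0.2, 0.7), c(1, 1)), 1.0)  # no negatives
  expect_error(precisionAtRecall(c(0.4, 0.6), c(0, 0)), "positive")
  # property: equality with the brute-force oracle on random score sets
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(3:50, 1)
    labels <- c(1, sample(0:1, n - 1, replace = TRUE))
    scores <- round(runif(n), 2)      # deliberately tie-heavy
    expect_equal(precisionAtRecall(scores, labels, 0.8),
                 oraclePrecisionAtRecall(scores, labels, 0.8))
  }
})

test_that("confusion-matrix metrics equal their defining formulas", {
  m <- computeMetrics(tp = 8, fp = 2, tn = 53, fn = 2)
  expect_equal(round(unname(m), 3), c(0.800, 0.964, 0.938, 0.800))
  perfect <- computeMetrics(tp = 10, fp = 0, tn = 55, fn = 0)
  expect_equal(unname(perfect), rep(1, 4))
  # random matrices against a literal recomputation
  set.seed(11)
  for (rep in 1:25) {
    cm <- sample(0:40, 4, replace = TRUE)
    if (cm[1] + cm[4] == 0 || cm[2] + cm[3] == 0) next
    m <- computeMetrics(cm[1], cm[2], cm[3], cm[4])
    expect_equal(m[["sensitivity"]], cm[1] / (cm[1] + cm[4]))
    expect_equal(m[["specificity"]], cm[3] / (cm[3] + cm[2]))
    expect_equal(m[["accuracy"]], (cm[1] + cm[3]) / sum(cm))
    expect_equal(m[["precision"]], cm[1] / (cm[1] + cm[2]))
  }
  # undefined ratios are flagged NA, not zero
  none <- computeMetrics(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(none[["sensitivity"]]))
  expect_true(is.na(none[["precision"]]))
  expect_error(computeMetrics(tp = -1, fp = 0, tn = 1, fn = 0), "non-negative")
})

test_that("trapezoid AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(6:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)      # many ties
    roc <- viascreen:::rocCurve(scores, labels)
    expect_equal(viascreen:::trapezoidAuc(roc), oracleAucU(scores, labels),
                 tolerance = 1e-12)
  }
  # independent cross-check against pROC on one continuous score set
  set.seed(13)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.6, 0.4))
  scores <- rnorm(60) + labels
  roc <- viascreen:::rocCurve(scores, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<", quiet = TRUE)))
  expect_equal(viascreen:::trapezoidAuc(roc), ref, tolerance = 1e-10)
})

test_that("cross-validation selects a strong model on separable features", {
  tab <- makeToyTable(n = 80, nPos = 20, delta = 3, seed = 21)
  cv <- crossValidate(tab, folds = 10, seed = 1)
  expect_s4_class(cv, "CvReport")
  expect_equal(cv@folds, 10L)
  expect_length(cvScores(cv), 9)
  expect_gte(cvScores(cv)[1], 0.9)
  # deterministic under the same seed
  cv2 <- crossValidate(tab, folds = 10, seed = 1)
  expect_identical(cvScores(cv), cvScores(cv2))
  expect_identical(cv@perFold, cv2@perFold)
})

test_that("label shuffling collapses the objective towards prevalence", {
  tab <- makeToyTable(n = 80, nPos = 20, delta = 3, seed = 22)
  set.seed(2)
  tab$label <- sample(tab$label)
  cv <- crossValidate(tab, algorithms = c("gradient_boosting",
                                          "logistic_regression",
                                          "naive_bayes"),
                      folds = 10, seed = 2)
  expect_lte(cvScores(cv)[1], 0.25 + 0.25)
})

test_that("folds without positives are rejected with advice", {
  tab <- makeToyTable(n = 30, nPos = 4, seed = 23)
  expect_error(crossValidate(tab, algorithms = "decision_tree",
                             folds = 10, seed = 1), "fewer folds")
  expect_error(crossValidate(tab, algorithms = "not_a_model", folds = 5),
               "valid ids")
})

test_that("final training stores the threshold and replays deterministically", {
  tab <- makeToyTable(n = 60, nPos = 15, delta = 3, seed = 24)
  model <- trainFinal(tab, "gradient_boosting", seed = 7)
  expect_equal(decisionThreshold(model), 0.29)
  expect_error(trainFinal(tab, "gradient_boosting", threshold = 1.5), "threshold")
  expect_error(trainFinal(tab, "quantum_forest"), "valid ids")
  probe <- makeToyTable(n = 20, nPos = 5, delta = 3, seed = 25)
  m2 <- trainFinal(tab, "gradient_boosting", seed = 7)
  expect_identical(scoreTable(model, probe), scoreTable(m2, probe))
  # thresholding convention: score >= t predicts positive
  st <- scoreTable(model, probe)
  expect_identical(st$label, as.integer(st$score >= 0.29))
})

test_that("every algorithm family trains, scores in [0, 1] and is seeded", {
  tab <- makeToyTable(n = 50, nPos = 14, delta = 3, seed = 26)
  probe <- makeToyTable(n = 16, nPos = 5, delta = 3, seed = 27)
  for (alg in listAlgorithms()) {
    m <- trainFinal(tab, alg, seed = 3)
    s1 <- scoreTable(m, probe)$score
    expect_true(all(s1 >= 0 & s1 <= 1), label = alg)
    m2 <- trainFinal(tab, alg, seed = 3)
    expect_identical(s1, scoreTable(m2, probe)$score, label = alg)
    # separable data: positives outscore negatives on average
    expect_gt(mean(s1[probe$label == 1]), mean(s1[probe$label == 0]))
  }
})

test_that("evaluation ties the confusion matrix, ROC and bootstrap together", {
  tab <- makeToyTable(n = 60, nPos = 15, delta = 4, seed = 28)
  test <- makeToyTable(n = 40, nPos = 10, delta = 4, seed = 29)
  model <- trainFinal(tab, "gradient_boosting", seed = 1)
  rep <- evaluateModel(model, test, bootstrap = 200, seed = 5)
  cm <- confusionCounts(rep)
  expect_equal(sum(cm), nrow(test))
  expect_equal(evalMetrics(rep),
               computeMetrics(cm["tp"], cm["fp"], cm["tn"], cm["fn"]))
  expect_true(aucCi(rep)[1] <= auc(rep) && auc(rep) <= aucCi(rep)[2])
  expect_equal(auc(rep), oracleAucU(rep@scores, rep@labels), tolerance = 1e-12)
  expect_error(evaluateModel(model, transform(test, label = 1)), "both classes")
})

test_that("random scores give chance-level AUC", {
  set.seed(30)
  labels <- sample(0:1, 200, replace = TRUE)
  scores <- runif(200)
  a <- viascreen:::trapezoidAuc(viascreen:::rocCurve(scores, labels))
  expect_lt(abs(a - 0.5), 0.12)
})

test_that("a saved model reloads and predicts identically", {
  tab <- makeToyTable(n = 50, nPos = 14, delta = 3, seed = 31)
  probe <- makeToyTable(n = 10, nPos = 3, delta = 3, seed = 32)
  model <- trainFinal(tab, "random_forest", seed = 2)
  dir <- withr::local_tempdir()
  saveModel(model, dir)
  back <- loadModel(dir)
  expect_equal(decisionThreshold(back), decisionThreshold(model))
  expect_identical(scoreTable(back, probe), scoreTable(model, probe))
})
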