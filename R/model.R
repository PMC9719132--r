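#' Best precision at a recall floor
#'
#' Sweeps every candidate decision threshold (the distinct scores plus
#' negative infinity, with "predict positive" meaning score >= threshold) and
#' returns the maximum precision among thresholds whose recall is at least
#' `minRecall`. The all-positive threshold always satisfies the floor, so the
#' result is never below the class prevalence.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels; at least one positive is required.
#' @param minRecall recall floor in (0, 1], default 0.8.
#' @return numeric scalar in \[0, 1\].
#' @examples
#' precisionAtRecall(c(0.9, 0.6, 0.5, 0.4), c(1, 0, 1, 1))   # 0.75
#' @export
precisionAtRecall <- function(scores, labels, minRecall = 0.8) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  P <- sum(labels == 1L)
  if (P == 0L) stop("recall undefined: no positive labels", call. = FALSE)
  if (minRecall <= 0 || minRecall > 1)
    stop("minRecall must lie in (0, 1]", call. = FALSE)
  best <- -Inf
  for (t in c(sort(unique(scores)), -Inf)) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    if (tp / P >= minRecall) {
      prec <- tp / sum(pred)
      if (prec > best) best <- prec
    }
  }
  best
}

stratifiedFolds <- function(labels, folds, seed) {
  set.seed(as.integer(seed))
  assign <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated model selection under precision-at-recall
#'
#' Stratified seeded k-fold cross-validation over the requested algorithm
#' families. Inside every training fold the selection pipeline (zero-variance
#' and collinearity pruning plus z-scoring) is re-fitted from scratch, so no
#' held-out information leaks into the transform. Each algorithm's objective
#' is the mean over folds of PrecisionAtRecall(`minRecall`) computed on the
#' held-out fold's out-of-fold scores.
#'
#' @param train feature data.frame with a `label` column.
#' @param algorithms subset of [listAlgorithms()]; default all nine.
#' @param folds fold count, default 25.
#' @param minRecall recall floor, default 0.8.
#' @param collinearityThreshold pruning threshold, default 0.9.
#' @param seed integer seed for fold assignment and the learners.
#' @return a [CvReport-class].
#' @export
crossValidate <- function(train, algorithms = listAlgorithms(), folds = 25L,
                          minRecall = 0.8, collinearityThreshold = 0.9,
                          seed = 1L) {
  if (!"label" %in% names(train)) stop("train must have a label column", call. = FALSE)
  labels <- as.integer(train$label)
  folds <- as.integer(folds)
  bad <- setdiff(algorithms, listAlgorithms())
  if (length(bad))
    stop("unknown algorithm(s): ", paste(bad, collapse = ", "),
         "; valid ids: ", paste(listAlgorithms(), collapse = ", "), call. = FALSE)
  assign <- stratifiedFolds(labels, folds, seed)
  if (any(tapply(labels, assign, function(l) sum(l == 1L)) == 0L))
    stop("a fold contains no positive sample; use fewer folds", call. = FALSE)
  perFold <- matrix(NA_real_, length(algorithms), folds,
                    dimnames = list(algorithms, NULL))
  for (f in seq_len(folds)) {
    tr <- train[assign != f, , drop = FALSE]
    te <- train[assign == f, , drop = FALSE]
    state <- fitSelection(tr, threshold = collinearityThreshold)
    trN <- applySelection(tr, state)
    teN <- applySelection(te, state)
    Xtr <- as.matrix(trN[, state@keptFeatures, drop = FALSE])
    Xte <- as.matrix(teN[, state@keptFeatures, drop = FALSE])
    ytr <- as.integer(tr$label); yte <- as.integer(te$label)
    for (a in seq_along(algorithms)) {
      algSeed <- as.integer((seed + 131L * f + 17L * a) %% 2147483647L)
      fit <- fitClassifier(algorithms[a], Xtr, ytr, algSeed)
      sc <- scoreClassifier(algorithms[a], fit, Xte)
      perFold[a, f] <- precisionAtRecall(sc, yte, minRecall)
    }
  }
  means <- rowMeans(perFold)
  # ties broken by registry order so the ranking is reproducible
  scores <- means[order(-means, match(names(means), listAlgorithms()))]
  methods::new("CvReport", scores = scores, perFold = perFold,
               folds = folds, minRecall = minRecall, seed = as.integer(seed))
}

#' Train the final model on the full training table
#'
#' Fits the selection state and the chosen classifier on every training row
#' and stores the decision threshold for prediction.
#'
#' @param train feature data.frame with a `label` column.
#' @param algorithmId one of [listAlgorithms()].
#' @param threshold decision threshold in (0, 1), default 0.29.
#' @param config pipeline configuration recorded with the model (and used by
#'   [predictImage()] to replay preprocessing).
#' @param seed integer training seed.
#' @return a [TrainedModel-class].
#' @export
trainFinal <- function(train, algorithmId, threshold = 0.29,
                       config = pipelineConfig(), seed = 1L) {
  if (!algorithmId %in% listAlgorithms())
    stop("unknown algorithm '", algorithmId, "'; valid ids: ",
         paste(listAlgorithms(), collapse = ", "), call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  state <- fitSelection(train, threshold = config$collinearityThreshold)
  trN <- applySelection(train, state)
  X <- as.matrix(trN[, state@keptFeatures, drop = FALSE])
  fit <- fitClassifier(algorithmId, X, as.integer(train$label), as.integer(seed))
  methods::new("TrainedModel", algorithmId = algorithmId, fit = fit,
               selection = state, threshold = threshold,
               config = unclass(config), seed = as.integer(seed))
}

#' Score a feature table with a trained model
#'
#' @param model a [TrainedModel-class].
#' @param table feature data.frame containing the kept features.
#' @return data.frame with `score` and thresholded `label` columns (plus `id`
#'   when present in the input).
#' @export
scoreTable <- function(model, table) {
  norm <- applySelection(table, model@selection)
  X <- as.matrix(norm[, model@selection@keptFeatures, drop = FALSE])
  score <- scoreClassifier(model@algorithmId, model@fit, X)
  out <- data.frame(score = score, label = as.integer(score >= model@threshold))
  if ("id" %in% names(table)) out <- cbind(id = table$id, out)
  out
}

#' Predict the VIA result for a single image
#'
#' Replays the full training pipeline on one image: resize, specular removal,
#' ROI detection, crop/zoom, feature extraction, selection/normalization with
#' the training-time state, then the stored estimator. If ROI detection fails
#' the whole image is used as the ROI with a warning, and a prediction is
#' still returned. A score at or above the stored threshold predicts
#' positive.
#'
#' @param model a [TrainedModel-class].
#' @param img RGB image array (or a PNG path).
#' @return list with `score` and binary `label`.
#' @export
predictImage <- function(model, img) {
  if (is.character(img)) img <- readImageFile(img)
  cfg <- do.call(pipelineConfig, model@config)
  fv <- imageFeatures(img, cfg)
  tab <- as.data.frame(as.list(fv), check.names = FALSE)
  res <- scoreTable(model, tab)
  list(score = res$score[1], label = res$label[1])
}

#' Derived metrics of a confusion matrix
#'
#' sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
#' accuracy = (tp + tn) / total, precision = tp / (tp + fp). A ratio with a
#' zero denominator is reported as NA (not applicable), never as zero.
#'
#' @param tp,fp,tn,fn non-negative integer counts; alternatively pass a named
#'   vector as `tp`.
#' @return named numeric with the four metrics as fractions.
#' @examples
#' computeMetrics(tp = 8, fp = 2, tn = 53, fn = 2)
#' @export
computeMetrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (length(tp) == 4L && !is.null(names(tp))) {
    cm <- tp
    tp <- cm[["tp"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]; fn <- cm[["fn"]]
  }
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = ratio(tp + tn, tp + fp + tn + fn),
    precision = ratio(tp, tp + fp))
}

# Trapezoid-rule AUC over the threshold-swept ROC. Equals the normalized
# Mann-Whitney U statistic (ties counted 1/2).
rocCurve <- function(scores, labels) {
  labels <- as.integer(labels)
  ts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  tpr <- vapply(ts, function(t) sum(scores >= t & labels == 1L) / P, numeric(1))
  fpr <- vapply(ts, function(t) sum(scores >= t & labels == 0L) / N, numeric(1))
  data.frame(fpr = fpr, tpr = tpr, threshold = ts)
}

trapezoidAuc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Evaluate a trained model on a labelled test table
#'
#' Computes the confusion matrix at the stored decision threshold, the four
#' derived metrics, the ROC curve by threshold sweep, the trapezoid-rule AUC,
#' and a 95% confidence interval for the AUC by seeded stratified bootstrap
#' (resampling positives and negatives separately, percentile interval,
#' clipped to \[0, 1\]).
#'
#' @param model a [TrainedModel-class].
#' @param test feature data.frame with a `label` column holding at least one
#'   positive and one negative.
#' @param bootstrap bootstrap resamples for the CI, default 2000.
#' @param seed bootstrap seed.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, test, bootstrap = 2000L, seed = 1L) {
  labels <- as.integer(test$label)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("test set must contain both classes", call. = FALSE)
  scores <- scoreTable(model, test)$score
  pred <- as.integer(scores >= model@threshold)
  confusion <- c(tp = sum(pred == 1L & labels == 1L),
                 fp = sum(pred == 1L & labels == 0L),
                 tn = sum(pred == 0L & labels == 0L),
                 fn = sum(pred == 0L & labels == 1L))
  roc <- rocCurve(scores, labels)
  aucVal <- trapezoidAuc(roc)
  posIdx <- which(labels == 1L); negIdx <- which(labels == 0L)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(bootstrap), function(b) {
    bi <- c(sample(posIdx, length(posIdx), replace = TRUE),
            sample(negIdx, length(negIdx), replace = TRUE))
    trapezoidAuc(rocCurve(scores[bi], labels[bi]))
  }, numeric(1))
  ci <- pmin(pmax(stats::quantile(boot, c(0.025, 0.975), names = FALSE), 0), 1)
  ci <- c(min(ci[1], aucVal), max(ci[2], aucVal))
  methods::new("EvalReport", confusion = as.integer(confusion) |>
                 stats::setNames(names(confusion)),
               metrics = computeMetrics(confusion["tp"], confusion["fp"],
                                        confusion["tn"], confusion["fn"]),
               rocPoints = roc, auc = aucVal, aucCi = ci,
               scores = scores, labels = labels)
}

#' Persist / restore a trained model as a directory
#'
#' Writes the selection state and pipeline configuration as JSON, the
#' threshold and algorithm id as JSON metadata, and the fitted estimator as
#' an RDS blob.
#'
#' @param model a [TrainedModel-class].
#' @param dir output directory.
#' @return `loadModel` returns the restored [TrainedModel-class].
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  selectionToJson(model@selection, file.path(dir, "selection.json"))
  jsonlite::write_json(model@config, file.path(dir, "config.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(algorithmId = model@algorithmId,
                            threshold = model@threshold, seed = model@seed),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model@fit, file.path(dir, "estimator.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  methods::new("TrainedModel", algorithmId = meta$algorithmId,
               fit = readRDS(file.path(dir, "estimator.rds")),
               selection = selectionFromJson(file.path(dir, "selection.json")),
               threshold = meta$threshold, config = as.list(cfg),
               seed = as.integer(meta$seed))
}
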