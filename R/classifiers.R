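# Thin adapters over the nine classifier families. Each adapter exposes
# fit(X, y, seed) -> opaque fit and score(fit, X) -> P(positive) in [0, 1].
# All learners run single-threaded with pinned seeds and library defaults
# (no hyperparameter search). X is a numeric matrix, y an integer 0/1 vector.

xgbFit <- function(X, y, seed, params) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  xgboost::xgb.train(params = c(params, list(objective = "binary:logistic",
                                             nthread = 1L, seed = seed)),
                     data = dtrain, nrounds = 100L, verbose = 0)
}

# AdaBoost.M1 with depth-1 rpart stumps; the score is the alpha-weighted vote
# share for the positive class.
adaboostFit <- function(X, y, seed, rounds = 50L) {
  df <- data.frame(y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1L, minsplit = 2L, cp = -1,
                               xval = 0L, maxcompete = 0L, maxsurrogate = 0L)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != df$y)) / sum(w)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    if (err >= 0.5) break
    agree <- ifelse(pred == df$y, 1, -1)
    w <- w * exp(-alpha * agree)
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  list(stumps = stumps, alphas = alphas)
}

adaboostScore <- function(fit, X) {
  df <- data.frame(X, check.names = FALSE)
  votes <- vapply(seq_along(fit$stumps), function(m) {
    as.numeric(stats::predict(fit$stumps[[m]], df, type = "class") == "1")
  }, numeric(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  as.vector(votes %*% fit$alphas) / sum(fit$alphas)
}

algorithmRegistry <- function() {
  list(
    gradient_boosting = list(
      fit = function(X, y, seed) xgbFit(X, y, seed,
        list(max_depth = 3L, eta = 0.1, tree_method = "exact")),
      score = function(fit, X) stats::predict(fit, X)),
    logistic_regression = list(
      fit = function(X, y, seed) {
        df <- data.frame(y = y, X, check.names = FALSE)
        suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      },
      score = function(fit, X) {
        p <- suppressWarnings(stats::predict(fit, data.frame(X, check.names = FALSE),
                                             type = "response"))
        as.vector(pmin(pmax(p, 0), 1))
      }),
    random_forest = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                   ntree = 300L)
      },
      score = function(fit, X) stats::predict(fit, X, type = "prob")[, "1"]),
    extra_trees = list(
      fit = function(X, y, seed) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
        ranger::ranger(y ~ ., data = df, num.trees = 300L,
                       splitrule = "extratrees", num.random.splits = 1L,
                       replace = FALSE, sample.fraction = 1,
                       probability = TRUE, seed = seed, num.threads = 1L)
      },
      score = function(fit, X)
        stats::predict(fit, data.frame(X, check.names = FALSE),
                       num.threads = 1L)$predictions[, "1"]),
    naive_bayes = list(
      fit = function(X, y, seed)
        e1071::naiveBayes(X, factor(y, levels = c(0, 1))),
      score = function(fit, X)
        stats::predict(fit, X, type = "raw", eps = 1e-9,
                       threshold = 1e-9)[, "1"]),
    adaboost = list(fit = adaboostFit, score = adaboostScore),
    light_gradient_boosting = list(
      fit = function(X, y, seed) xgbFit(X, y, seed,
        list(eta = 0.1, tree_method = "hist", grow_policy = "lossguide",
             max_leaves = 31L, max_depth = 0L)),
      score = function(fit, X) stats::predict(fit, X)),
    knn = list(
      fit = function(X, y, seed) list(X = X, y = factor(y, levels = c(0, 1)),
                                      k = 5L, seed = seed),
      score = function(fit, X) {
        set.seed(fit$seed)
        k <- min(fit$k, nrow(fit$X))
        pred <- class::knn(fit$X, X, fit$y, k = k, prob = TRUE, use.all = TRUE)
        p <- attr(pred, "prob")
        ifelse(pred == "1", p, 1 - p)
      }),
    decision_tree = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        df <- data.frame(y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
        rpart::rpart(y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(xval = 0L))
      },
      score = function(fit, X)
        stats::predict(fit, data.frame(X, check.names = FALSE),
                       type = "prob")[, "1"])
  )
}

#' List the available classifier family ids
#'
#' The nine families of the model-selection stage: gradient boosting,
#' logistic regression, random forest, extra trees, naive Bayes, AdaBoost,
#' light (histogram) gradient boosting, k-nearest neighbours, decision tree.
#'
#' @return character vector of algorithm ids.
#' @export
listAlgorithms <- function() names(algorithmRegistry())

fitClassifier <- function(algorithmId, X, y, seed) {
  reg <- algorithmRegistry()
  if (!algorithmId %in% names(reg))
    stop("unknown algorithm '", algorithmId, "'; valid ids: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[algorithmId]]$fit(X, as.integer(y), as.integer(seed))
}

scoreClassifier <- function(algorithmId, fit, X) {
  as.vector(algorithmRegistry()[[algorithmId]]$score(fit, X))
}
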