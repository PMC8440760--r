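## Classifier backends. Each fit_* takes a numeric matrix `X` (already
## standardised), a two-level factor `y`, and returns a closure mapping
## a matrix of new rows to P(positive class), where the positive class
## is levels(y)[2].

fit_knn9 <- function(X, y) {
  force(X); force(y)
  function(Xn) {
    pred <- class::knn(X, Xn, y, k = min(9L, nrow(X)), prob = TRUE)
    pwin <- attr(pred, "prob")
    ifelse(pred == levels(y)[2], pwin, 1 - pwin)
  }
}

fit_decision_tree <- function(X, y) {
  df <- data.frame(X); df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class")
  function(Xn) predict(fit, data.frame(Xn), type = "prob")[, levels(y)[2]]
}

fit_random_forest <- function(X, y, seed = 1L) {
  fit <- ranger::ranger(x = X, y = y, num.trees = 300, probability = TRUE,
                        seed = seed)
  function(Xn) predict(fit, data.frame(Xn))$predictions[, levels(y)[2]]
}

fit_mlp <- function(X, y, seed = 1L) {
  ybin <- as.numeric(y == levels(y)[2])
  fit <- withr::with_seed(seed,
    nnet::nnet(X, ybin, size = 8, decay = 0.01, maxit = 300,
               trace = FALSE, entropy = TRUE))
  function(Xn) as.vector(predict(fit, Xn))
}

## Discrete AdaBoost (SAMME with two classes) over depth-1 rpart stumps.
## Returns probabilities through the logistic link of the additive
## margin, which preserves score ordering for ROC analysis.
fit_adaboost <- function(X, y, n_rounds = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  ybin <- ifelse(y == levels(y)[2], 1, -1)
  stumps <- list(); alphas <- numeric(0)
  df <- data.frame(X)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(factor(ybin) ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != ybin))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(-alpha * ybin * pred)
    w <- w / sum(w)
    if (err < 1e-8) break
  }
  function(Xn) {
    dfn <- data.frame(Xn)
    margin <- rowSums(vapply(seq_along(stumps), function(m) {
      alphas[m] * ifelse(predict(stumps[[m]], dfn, type = "class") == "1", 1, -1)
    }, numeric(nrow(dfn))))
    1 / (1 + exp(-2 * margin))
  }
}

## Bootstrap-aggregated rpart trees with averaged class probabilities.
fit_bagging <- function(X, y, n_trees = 25, seed = 1L) {
  df <- data.frame(X); df$.y <- y
  trees <- withr::with_seed(seed, purrr::map(seq_len(n_trees), function(b) {
    idx <- sample(nrow(df), replace = TRUE)
    if (length(unique(df$.y[idx])) < 2) idx <- seq_len(nrow(df))
    rpart::rpart(.y ~ ., data = df[idx, ], method = "class")
  }))
  function(Xn) {
    dfn <- data.frame(Xn)
    probs <- vapply(trees, function(tr) {
      predict(tr, dfn, type = "prob")[, levels(y)[2]]
    }, numeric(nrow(dfn)))
    rowMeans(matrix(probs, nrow = nrow(dfn)))
  }
}

fit_gradient_boosting <- function(X, y, seed = 1L) {
  ybin <- as.numeric(y == levels(y)[2])
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = ybin)
  fit <- withr::with_seed(seed,
    xgboost::xgb.train(params = list(objective = "binary:logistic",
                                     max_depth = 3, eta = 0.3, nthread = 1),
                       data = dtrain, nrounds = 50, verbose = 0))
  function(Xn) predict(fit, xgboost::xgb.DMatrix(as.matrix(Xn)))
}

BASE_CLASSIFIERS <- c("knn9", "decision_tree", "random_forest", "mlp",
                      "adaboost", "bagging", "gradient_boosting")

#' Names of the available classifiers
#'
#' The eight mandatory classifier designs: 9-nearest neighbours,
#' decision tree, random forest, multi-layer perceptron, adaptive
#' boosting, bagging, gradient boosting, and soft ensemble voting over
#' the other seven.
#'
#' @return Character vector of classifier names.
#' @export
classifier_names <- function() c(BASE_CLASSIFIERS, "ensemble_voting")

fit_one_classifier <- function(name, X, y, seed = 1L) {
  switch(name,
         knn9 = fit_knn9(X, y),
         decision_tree = fit_decision_tree(X, y),
         random_forest = fit_random_forest(X, y, seed = seed),
         mlp = fit_mlp(X, y, seed = seed),
         adaboost = fit_adaboost(X, y),
         bagging = fit_bagging(X, y, seed = seed),
         gradient_boosting = fit_gradient_boosting(X, y, seed = seed),
         abort(sprintf("Unknown classifier '%s'.", name)))
}
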