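# The nine base learners of the stacking ensemble. Each spec exposes
# fit(X, y) and predict(fit, X) returning the positive-class (Lingerer)
# probability. Library learners are used where the environment provides
# them; AdaBoost (SAMME with decision stumps) and bootstrap bagging of trees
# are implemented here.

POSITIVE_CLASS <- "Lingerer"

as_learner_df <- function(X) {
  df <- as.data.frame(X)
  names(df) <- colnames(X)
  df
}

fit_adaboost_stumps <- function(X, y, n_rounds = 50L) {
  df <- as_learner_df(X)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  dat <- cbind(df, .y = y)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    if (err <= 1e-9 || err >= 0.5) break
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost_stumps <- function(fit, X) {
  df <- as_learner_df(X)
  votes <- numeric(nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], df, type = "class")
    votes <- votes + fit$alphas[m] * (pred == POSITIVE_CLASS)
  }
  votes / sum(fit$alphas)
}

fit_bagged_trees <- function(X, y, n_trees = 10L) {
  df <- as_learner_df(X)
  dat <- cbind(df, .y = y)
  n <- nrow(df)
  lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.y ~ ., data = dat[idx, , drop = FALSE], method = "class",
                 control = rpart::rpart.control(xval = 0))
  })
}

predict_bagged_trees <- function(fit, X) {
  df <- as_learner_df(X)
  probs <- vapply(fit, function(tree) {
    p <- predict(tree, df, type = "prob")
    if (POSITIVE_CLASS %in% colnames(p)) p[, POSITIVE_CLASS] else numeric(nrow(df))
  }, numeric(nrow(df)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

# drop near-constant columns (Gaussian NB cannot use them)
nb_usable_cols <- function(X) {
  which(apply(X, 2, function(v) length(unique(v)) > 1L))
}

#' Base-learner registry
#'
#' The ordered list of the nine base classifiers of the stacking ensemble:
#' logistic regression, decision tree, SVM (RBF, probability outputs),
#' Gaussian naive Bayes, k-nearest neighbours (k = 5), AdaBoost (decision
#' stumps), bagged trees, random forest, and extremely randomized trees.
#'
#' @return named list of specs, each with elements `fit(X, y)` and
#'   `predict(fit, X)` (positive-class probability).
#' @export
base_learner_specs <- function() {
  list(
    logistic = list(
      fit = function(X, y) {
        dat <- cbind(as_learner_df(X), .y = y)
        suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
      },
      predict = function(fit, X) {
        suppressWarnings(unname(
          stats::predict(fit, as_learner_df(X), type = "response")))
      }),
    tree = list(
      fit = function(X, y) {
        dat <- cbind(as_learner_df(X), .y = y)
        rpart::rpart(.y ~ ., data = dat, method = "class",
                     control = rpart::rpart.control(xval = 0))
      },
      predict = function(fit, X) {
        p <- predict(fit, as_learner_df(X), type = "prob")
        if (POSITIVE_CLASS %in% colnames(p)) unname(p[, POSITIVE_CLASS]) else numeric(nrow(X))
      }),
    svm = list(
      # features arrive standardized; scale = FALSE avoids degenerate
      # rescaling of dummy columns absent from a fold
      fit = function(X, y) e1071::svm(X, y, probability = TRUE,
                                      kernel = "radial", scale = FALSE),
      predict = function(fit, X) {
        pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
        unname(pr[, POSITIVE_CLASS])
      }),
    naive_bayes = list(
      fit = function(X, y) {
        keep <- nb_usable_cols(X)
        list(model = e1071::naiveBayes(as_learner_df(X[, keep, drop = FALSE]), y),
             keep = keep)
      },
      predict = function(fit, X) {
        p <- predict(fit$model, as_learner_df(X[, fit$keep, drop = FALSE]),
                     type = "raw")
        unname(p[, POSITIVE_CLASS])
      }),
    knn = list(
      fit = function(X, y) list(X = X, y = y, k = 5L),
      predict = function(fit, X) {
        pred <- class::knn(fit$X, X, fit$y, k = min(fit$k, nrow(fit$X)),
                           prob = TRUE)
        pw <- attr(pred, "prob")
        ifelse(pred == POSITIVE_CLASS, pw, 1 - pw)
      }),
    adaboost = list(
      fit = function(X, y) fit_adaboost_stumps(X, y),
      predict = predict_adaboost_stumps),
    bagging = list(
      fit = function(X, y) fit_bagged_trees(X, y),
      predict = predict_bagged_trees),
    random_forest = list(
      fit = function(X, y) randomForest::randomForest(X, y, ntree = 300L),
      predict = function(fit, X) {
        unname(predict(fit, X, type = "prob")[, POSITIVE_CLASS])
      }),
    extra_trees = list(
      fit = function(X, y) {
        ranger::ranger(x = X, y = y, probability = TRUE, num.trees = 300L,
                       splitrule = "extratrees", num.random.splits = 1L,
                       seed = sample.int(.Machine$integer.max, 1L))
      },
      predict = function(fit, X) {
        unname(stats::predict(fit, data = X)$predictions[, POSITIVE_CLASS])
      })
  )
}
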