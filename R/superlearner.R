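# Super Learner stacking classifier for gut permanence. The base learners
# are run in k-fold cross-validation on the training data to produce an
# n x m matrix of out-of-fold positive-class probabilities (the
# meta-features); a logistic meta-model is fitted on that matrix; the base
# learners are then refit on the complete training data for deployment.

#' Fit a Super Learner stacking classifier
#'
#' @param X standardized feature matrix from [build_feature_matrix()]
#'   (training rows only).
#' @param y binary labels: factor or character with values `Traverser` /
#'   `Lingerer` (`Lingerer` is the positive class).
#' @param cv_folds number of cross-validation folds for the out-of-fold
#'   meta-features (default 7).
#' @param seed integer seed controlling fold assignment and the stochastic
#'   base learners.
#' @param strata optional stratification labels for the internal CV folds
#'   (e.g. chemical class); defaults to stratification on `y`.
#' @param folds optional precomputed fold vector in 1..cv_folds, overriding
#'   the internal assignment (used when the outer protocol already defines
#'   the folds).
#' @return object of class `gutperm_superlearner`: fitted base learners
#'   (refit on all training rows), the `n x 9` meta-feature matrix, the
#'   logistic meta-model, fold assignment, seed and feature names.
#' @export
fit_superlearner <- function(X, y, cv_folds = 7L, seed = 1L, strata = NULL,
                             folds = NULL) {
  y <- factor(as.character(y), levels = PERMANENCE_LABELS)
  if (anyNA(y)) stop("labels must be Traverser/Lingerer")
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  n <- nrow(X)
  if (n < cv_folds) stop("fewer rows than cv folds")
  specs <- base_learner_specs()
  m <- length(specs)
  if (is.null(folds)) {
    folds <- stratified_folds(if (is.null(strata)) y else strata,
                              k = cv_folds, seed = seed)
  }
  stopifnot(length(folds) == n)
  meta <- matrix(NA_real_, n, m, dimnames = list(NULL, names(specs)))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (!any(tr) || nlevels(droplevels(y[tr])) < 2L) {
      stop("fold ", f, " leaves a single-class training set")
    }
    for (j in seq_len(m)) {
      set.seed((seed + 7919L * f + 104729L * j) %% .Machine$integer.max)
      fit <- tryCatch(specs[[j]]$fit(X[tr, , drop = FALSE], y[tr]),
                      error = function(e) {
        stop("base learner '", names(specs)[j], "' failed on fold ", f, ": ",
             conditionMessage(e))
      })
      meta[!tr, j] <- specs[[j]]$predict(fit, X[!tr, , drop = FALSE])
    }
  }
  meta_df <- as.data.frame(meta)
  meta_df$.y <- y
  meta_model <- suppressWarnings(
    stats::glm(.y ~ ., data = meta_df, family = stats::binomial()))
  fitted_base <- vector("list", m)
  names(fitted_base) <- names(specs)
  for (j in seq_len(m)) {
    set.seed((seed + 104729L * j) %% .Machine$integer.max)
    fitted_base[[j]] <- specs[[j]]$fit(X, y)
  }
  structure(list(base_specs = names(specs), fitted_base = fitted_base,
                 meta_features = meta, meta_model = meta_model,
                 cv_folds = cv_folds, seed = seed, folds = folds,
                 feature_names = colnames(X),
                 feature_stats = attr(X, "feature_stats")),
            class = "gutperm_superlearner")
}

#' Predict gut-permanence probabilities from a fitted Super Learner
#'
#' The fitted base learners generate the meta-features for the new data,
#' which the logistic meta-model converts to a positive-class (Lingerer)
#' probability. A probability of exactly 0.5 classifies as the positive
#' class.
#'
#' @param object fitted `gutperm_superlearner`.
#' @param newdata standardized feature matrix with the training columns
#'   (standardized with the training parameters).
#' @param type `"prob"` for probabilities, `"class"` for hard labels.
#' @param ... unused.
#' @return numeric vector of probabilities, or a factor of labels.
#' @export
predict.gutperm_superlearner <- function(object, newdata,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (ncol(newdata) != length(object$feature_names) ||
      !all(colnames(newdata) == object$feature_names)) {
    stop("newdata columns do not match the training feature matrix")
  }
  specs <- base_learner_specs()
  meta <- matrix(NA_real_, nrow(newdata), length(specs),
                 dimnames = list(NULL, object$base_specs))
  for (j in seq_along(specs)) {
    set.seed((object$seed + 104729L * j + 1L) %% .Machine$integer.max)
    meta[, j] <- specs[[j]]$predict(object$fitted_base[[j]], newdata)
  }
  p <- suppressWarnings(unname(
    stats::predict(object$meta_model, as.data.frame(meta), type = "response")))
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, "Lingerer", "Traverser"), levels = PERMANENCE_LABELS)
}

#' @export
print.gutperm_superlearner <- function(x, ...) {
  cat("Super Learner gut-permanence classifier\n")
  cat("  base learners:", paste(x$base_specs, collapse = ", "), "\n")
  cat("  meta-features:", nrow(x$meta_features), "x", ncol(x$meta_features), "\n")
  cat("  cv folds:", x$cv_folds, " seed:", x$seed, "\n")
  invisible(x)
}
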