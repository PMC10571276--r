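# Evaluation of permanence predictions: overall, FL-subset, noFL-subset and
# standardized (subset-averaged) accuracy/precision/recall/F1/AUROC/AUPRC.

EVAL_METRICS <- c("accuracy", "precision", "recall", "f1", "auroc", "auprc")

# Mann-Whitney / rank formulation of the ROC area; NA when one class absent.
auroc_score <- function(y_pos, scores) {
  np <- sum(y_pos); nn <- sum(!y_pos)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_pos]) - np * (np + 1) / 2) / (np * nn)
}

# Average precision (step-wise integral of the precision-recall curve),
# grouping tied scores at a common threshold.
auprc_score <- function(y_pos, scores) {
  np <- sum(y_pos)
  if (np == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y_pos[ord]; s <- scores[ord]
  grp_last <- which(diff(s) != 0)
  cuts <- c(grp_last, length(s))
  tp <- cumsum(y)[cuts]
  fp <- cumsum(!y)[cuts]
  prec <- tp / (tp + fp)
  rec <- tp / np
  ap <- 0
  prev_rec <- 0
  for (i in seq_along(cuts)) {
    ap <- ap + (rec[i] - prev_rec) * prec[i]
    prev_rec <- rec[i]
  }
  ap
}

scope_metrics <- function(y_pos, scores, threshold, with_curves) {
  n <- length(y_pos)
  if (n == 0L) return(stats::setNames(rep(NA_real_, length(EVAL_METRICS)), EVAL_METRICS))
  pred <- scores >= threshold
  tp <- sum(pred & y_pos); fp <- sum(pred & !y_pos)
  fn <- sum(!pred & y_pos)
  acc <- mean(pred == y_pos)
  # zero-denominator convention: 0, as in the common ML library reports
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auroc <- if (with_curves) auroc_score(y_pos, scores) else NA_real_
  auprc <- if (with_curves) auprc_score(y_pos, scores) else NA_real_
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
    auroc = auroc, auprc = auprc)
}

#' Standardized (subset-averaged) metrics
#'
#' The arithmetic mean, metric by metric, of the FL-subset and noFL-subset
#' values; used to adjust for the large size imbalance between the
#' structurally homogeneous FL stratum and the rest of the external test
#' fold. A metric undefined in either subset (e.g. AUROC on a one-class
#' subset) is undefined in the standardized row.
#'
#' @param fl,nofl named numeric vectors of subset metrics (names as in the
#'   rows of [evaluate_predictions()]).
#' @return named numeric vector of the averaged metrics.
#' @export
standardize_report <- function(fl, nofl) {
  metrics <- intersect(names(fl), names(nofl))
  out <- (fl[metrics] + nofl[metrics]) / 2
  out
}

#' Evaluate permanence predictions
#'
#' Accuracy, precision, recall and F1 at the 0.5 threshold plus AUROC and
#' AUPRC (average precision) from the probabilities, computed for the whole
#' sample and, when an FL mask is supplied, for the FL and noFL subsets and
#' their standardized average. `Lingerer` is the positive class. AUROC is
#' reported as `NA` for a scope containing a single class; for hard
#' (rule-based) label predictions set `scores_are_probabilities = FALSE` and
#' the curve metrics are reported `NA` throughout.
#'
#' @param y_true true labels (factor/character Traverser/Lingerer, or
#'   logical with `TRUE` = Lingerer).
#' @param scores positive-class probabilities in [0,1] (or 0/1 hard labels).
#' @param fl_mask optional logical vector marking the FL molecules.
#' @param threshold classification threshold (default 0.5; a probability of
#'   exactly 0.5 is classified positive).
#' @param scores_are_probabilities set `FALSE` for hard-label predictors.
#' @return data.frame of class `gutperm_eval`, one row per scope (`all`,
#'   and with a mask `fl`, `nofl`, `standardized`), columns
#'   accuracy/precision/recall/f1/auroc/auprc.
#' @export
evaluate_predictions <- function(y_true, scores, fl_mask = NULL,
                                 threshold = 0.5,
                                 scores_are_probabilities = TRUE) {
  y_pos <- if (is.logical(y_true)) y_true else as.character(y_true) == POSITIVE_CLASS
  if (is.factor(scores) || is.character(scores)) {
    scores <- as.numeric(as.character(scores) == POSITIVE_CLASS)
    scores_are_probabilities <- FALSE
  }
  stopifnot(length(y_pos) == length(scores))
  rows <- list(all = scope_metrics(y_pos, scores, threshold,
                                   scores_are_probabilities))
  if (!is.null(fl_mask)) {
    stopifnot(length(fl_mask) == length(scores))
    fl <- scope_metrics(y_pos[fl_mask], scores[fl_mask], threshold,
                        scores_are_probabilities)
    nofl <- scope_metrics(y_pos[!fl_mask], scores[!fl_mask], threshold,
                          scores_are_probabilities)
    rows$fl <- fl
    rows$nofl <- nofl
    rows$standardized <- standardize_report(fl, nofl)
  }
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("gutperm_eval", class(out))
  out
}
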