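# Evaluation metrics, implemented library-free (rank-based AUC with tie
# correction, step-interpolated average precision for AUPR, Cohen's kappa,
# accuracy, macro-precision); cross-checked against independent references in
# the test suite.

#' Area under the ROC curve of binary scores
#'
#' Rank-based (Mann-Whitney) with midrank tie handling.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in 0..1.
#' @export
binary_auc <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over increasing-recall steps of
#' precision at each positive, ties in score handled by grouping.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUPR in 0..1.
#' @export
binary_aupr <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPR needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  # evaluate at the last index of each tied score group
  last <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Cohen's kappa of a hard classification
#'
#' @param y_true,y_pred integer class vectors.
#' @return `(p_o - p_e) / (1 - p_e)`.
#' @export
cohen_kappa <- function(y_true, y_pred) {
  lev <- sort(unique(c(y_true, y_pred)))
  t1 <- factor(y_true, levels = lev); t2 <- factor(y_pred, levels = lev)
  cm <- table(t1, t2)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

#' Macro-averaged precision
#'
#' Unweighted mean of per-class precision over the classes present in
#' `y_true`; a class never predicted contributes 0.
#'
#' @param y_true,y_pred integer class vectors.
#' @return Macro-precision in 0..1.
#' @export
macro_precision <- function(y_true, y_pred) {
  classes <- sort(unique(y_true))
  prec <- vapply(classes, function(cl) {
    pred_cl <- y_pred == cl
    if (!any(pred_cl)) return(0)
    mean(y_true[pred_cl] == cl)
  }, 0)
  mean(prec)
}

#' Evaluate DDI-type predictions
#'
#' Multiclass: micro-averaged AUPR and AUC over the one-vs-rest binarized
#' (pair, type) scores, plus Cohen's kappa, accuracy and macro-precision on
#' the argmax prediction. Multilabel: micro AUPR/AUC over all (pair, type)
#' scores.
#'
#' @param y_true integer class vector (multiclass) or binary matrix
#'   (pairs x types, multilabel).
#' @param scores probability matrix (pairs x types).
#' @param task `"multiclass"` or `"multilabel"`.
#' @param average `"micro"` (default: all one-vs-rest cells pooled) or
#'   `"macro"` (unweighted mean of per-type AUPR/AUC over types with both
#'   outcomes present) for the curve metrics.
#' @return Named list of metric values.
#' @export
evaluate_predictions <- function(y_true, scores,
                                 task = c("multiclass", "multilabel"),
                                 average = c("micro", "macro")) {
  task <- match.arg(task)
  average <- match.arg(average)
  curve_metrics <- function(z, s) {
    if (average == "micro") {
      list(aupr = binary_aupr(as.numeric(z), as.numeric(s)),
           auc = binary_auc(as.numeric(z), as.numeric(s)))
    } else {
      ok <- which(colSums(z) > 0 & colSums(z) < nrow(z))
      list(aupr = mean(vapply(ok, function(k) binary_aupr(z[, k], s[, k]), 0)),
           auc = mean(vapply(ok, function(k) binary_auc(z[, k], s[, k]), 0)))
    }
  }
  if (task == "multiclass") {
    if (length(unique(y_true)) < 2) stop("y_true contains a single class")
    K <- ncol(scores)
    z <- matrix(0, length(y_true), K)
    z[cbind(seq_along(y_true), y_true)] <- 1
    y_pred <- max.col(scores, ties.method = "first")
    cm <- curve_metrics(z, scores)
    list(aupr = cm$aupr,
         auc = cm$auc,
         kappa = cohen_kappa(y_true, y_pred),
         accuracy = mean(y_true == y_pred),
         macro_precision = macro_precision(y_true, y_pred))
  } else {
    if (!is.matrix(y_true) || !all(y_true %in% c(0, 1))) {
      stop("multilabel y_true must be a binary matrix")
    }
    if (length(unique(as.numeric(y_true))) < 2) {
      stop("y_true contains a single class")
    }
    curve_metrics(y_true, scores)
  }
}
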