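# DDI-type prediction head and task losses: a three-layer fully connected
# network (2048 and 4096 hidden units at full scale) with softmax output for
# multiclass prediction or elementwise sigmoid for multilabel prediction;
# cross-entropy / positively-reweighted binary cross-entropy losses.

.LOG_CLAMP <- 1e-12

#' Initialize predictor parameters
#'
#' @param in_dim input width (1024 for the default fused representation).
#' @param hidden1,hidden2 widths of the two hidden layers (2048 / 4096).
#' @param n_classes number of DDI types.
#' @param task `"multiclass"` or `"multilabel"`.
#' @param seed integer seed.
#' @return list of class `predictor_params` with `W1..W3`, `b1..b3`, `task`.
#' @export
predictor_init <- function(in_dim = 1024L, hidden1 = 2048L, hidden2 = 4096L,
                           n_classes, task = c("multiclass", "multilabel"),
                           seed = 0L) {
  task <- match.arg(task)
  stopifnot_count(n_classes, "n_classes", min = 2L)
  with_seed(seed, {
    structure(list(W1 = glorot(hidden1, in_dim), b1 = numeric(hidden1),
                   W2 = glorot(hidden2, hidden1), b2 = numeric(hidden2),
                   W3 = glorot(n_classes, hidden2), b3 = numeric(n_classes),
                   task = task, n_classes = as.integer(n_classes)),
              class = "predictor_params")
  })
}

#' Predict DDI-type probabilities from a fused pair representation
#'
#' Three affine layers with ReLU between; the output nonlinearity is softmax
#' (multiclass, entries sum to 1) or elementwise sigmoid (multilabel).
#'
#' @param S fused representation: a vector, or a matrix with one pair per row.
#' @param params a `predictor_params`.
#' @return Probability vector (or matrix, one row per pair) of width
#'   `n_classes`.
#' @export
predict_ddi <- function(S, params) {
  single <- is.null(dim(S))
  X <- if (single) matrix(S, nrow = 1) else S
  if (ncol(X) != ncol(params$W1)) {
    stop("input width ", ncol(X), " does not match W1 (", ncol(params$W1), ")")
  }
  H1 <- relu(X %*% t(params$W1) + rep(params$b1, each = nrow(X)))
  H2 <- relu(H1 %*% t(params$W2) + rep(params$b2, each = nrow(X)))
  Z <- H2 %*% t(params$W3) + rep(params$b3, each = nrow(X))
  Q <- if (params$task == "multiclass") softmax_rows(Z) else 1 / (1 + exp(-Z))
  if (single) drop(Q) else Q
}

#' Multiclass cross-entropy loss of one prediction
#'
#' `-log q_c*` for the true class, with the predicted probability clamped
#' away from zero.
#'
#' @param z one-hot indicator vector of the true class.
#' @param q predicted probability vector.
#' @return Nonnegative scalar.
#' @export
multiclass_loss <- function(z, q) {
  if (sum(z == 1) != 1 || !all(z %in% c(0, 1))) {
    stop("z must be a one-hot indicator vector")
  }
  -log(max(q[which(z == 1)], .LOG_CLAMP))
}

#' Weighted binary cross-entropy loss of one multilabel prediction
#'
#' Mean over types of `p_c z_c log q_c + (1 - z_c) log(1 - q_c)`, negated,
#' where `p_c` reweights positive examples of type c.
#'
#' @param z 0/1 indicator vector over types.
#' @param q predicted per-type probabilities.
#' @param pos_weights per-type positive weights `p_c` (default 1).
#' @return Nonnegative scalar.
#' @export
multilabel_loss <- function(z, q, pos_weights = 1) {
  if (!all(z %in% c(0, 1))) stop("z must be binary")
  q <- pmin(pmax(q, .LOG_CLAMP), 1 - .LOG_CLAMP)
  p <- rep_len(pos_weights, length(z))
  -mean(p * z * log(q) + (1 - z) * log(1 - q))
}

#' Per-type positive weights from training labels
#'
#' `p_c` equals the proportion of negative to positive samples of type c in
#' the training fold.
#'
#' @param train_labels binary matrix (pairs x types).
#' @return Numeric vector of per-type weights.
#' @export
positive_weights <- function(train_labels) {
  pos <- colSums(train_labels)
  if (any(pos == 0)) {
    bad <- which(pos == 0)
    nm <- colnames(train_labels)[bad] %||% as.character(bad)
    stop("type(s) with zero positives in training: ", paste(nm, collapse = ", "))
  }
  (nrow(train_labels) - pos) / pos
}

#' Mean per-pair loss of a batch
#'
#' @param z binary label matrix (pairs x types; one-hot rows for multiclass).
#' @param q predicted probability matrix of the same shape.
#' @param task `"multiclass"` or `"multilabel"`.
#' @param pos_weights per-type positive weights (multilabel).
#' @return Scalar mean loss.
#' @export
total_loss <- function(z, q, task = c("multiclass", "multilabel"),
                       pos_weights = 1) {
  task <- match.arg(task)
  if (nrow(z) == 0) stop("empty batch")
  per <- vapply(seq_len(nrow(z)), function(i) {
    if (task == "multiclass") multiclass_loss(z[i, ], q[i, ])
    else multilabel_loss(z[i, ], q[i, ], pos_weights)
  }, 0)
  mean(per)
}
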