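# Capsule-network fusion of the four pair-level modality vectors. Each
# modality is projected to a common capsule dimension, squashed into an
# initial capsule, and passed through two capsule layers (4 -> 4 -> 2 by
# default) coupled by dynamic routing; the two final capsules flatten to the
# 1024-d comprehensive pair representation.

#' Squashing nonlinearity
#'
#' Rescales a vector to norm `||s||^2 / (1 + ||s||^2)` (always < 1),
#' preserving direction; the zero vector maps to zero.
#'
#' @param s numeric vector.
#' @return Squashed vector of the same length.
#' @export
squash <- function(s) {
  r2 <- sum(s * s)
  if (r2 == 0) return(s)
  s * sqrt(r2) / (1 + r2)
}

# Row-wise squash for a batch matrix.
squash_rows <- function(m) {
  r2 <- rowSums(m * m)
  f <- ifelse(r2 == 0, 0, sqrt(r2) / (1 + r2))
  m * f
}

# Row-wise squash backward: given s, grad wrt squash(s) -> grad wrt s.
# squash(s) = phi(r) s with phi(r) = r/(1+r^2); Jacobian = phi I +
# (phi'(r)/r) s s^T.
squash_rows_backward <- function(s, dout) {
  r2 <- rowSums(s * s)
  r <- sqrt(r2)
  phi <- ifelse(r == 0, 0, r / (1 + r2))
  dphi <- (1 - r2) / (1 + r2)^2
  dot <- rowSums(s * dout)
  scale2 <- ifelse(r == 0, 0, dphi / r * dot)
  dout * phi + s * scale2
}

#' Initialize capsule-fusion parameters
#'
#' @param widths integer vector of the four pair-level modality widths
#'   (KG, fingerprint, molecular-graph, pharmacology order).
#' @param dim capsule dimension (512).
#' @param n_mid capsules in the first capsule layer (4).
#' @param n_out capsules in the second capsule layer (2).
#' @param routing_iters dynamic-routing iterations (3).
#' @param bias include a projection bias (initialized to zero).
#' @param seed integer seed.
#' @return list of class `caps_params`.
#' @export
caps_init <- function(widths, dim = 512L, n_mid = 4L, n_out = 2L,
                      routing_iters = 3L, bias = TRUE, seed = 0L) {
  stopifnot_count(routing_iters, "routing_iters")
  stopifnot_count(n_out, "n_out")
  n_in <- length(widths)
  with_seed(seed, {
    W_proj <- lapply(widths, function(w) glorot(dim, w))
    b_proj <- if (bias) lapply(widths, function(w) numeric(dim)) else NULL
    W1 <- lapply(seq_len(n_in), function(i)
      lapply(seq_len(n_mid), function(j) glorot(dim, dim)))
    W2 <- lapply(seq_len(n_mid), function(i)
      lapply(seq_len(n_out), function(j) glorot(dim, dim)))
    structure(list(W_proj = W_proj, b_proj = b_proj, W1 = W1, W2 = W2,
                   widths = as.integer(widths), dim = as.integer(dim),
                   n_mid = as.integer(n_mid), n_out = as.integer(n_out),
                   routing_iters = as.integer(routing_iters)),
              class = "caps_params")
  })
}

#' Project modality vectors into the capsule space
#'
#' One linear map per modality brings the four pair-level feature vectors to
#' the common capsule dimension.
#'
#' @param bundle list of the four modality vectors (order must match the
#'   widths used in [caps_init()]).
#' @param params a `caps_params`.
#' @return Matrix (n_modalities x dim); one row per projected modality.
#' @export
project_modalities <- function(bundle, params) {
  if (length(bundle) != length(params$W_proj)) {
    stop("bundle has ", length(bundle), " modalities but params expect ",
         length(params$W_proj))
  }
  out <- matrix(0, length(bundle), params$dim)
  for (k in seq_along(bundle)) {
    if (length(bundle[[k]]) != params$widths[k]) {
      stop("modality ", k, " has width ", length(bundle[[k]]),
           ", expected ", params$widths[k])
    }
    out[k, ] <- drop(params$W_proj[[k]] %*% bundle[[k]])
    if (!is.null(params$b_proj)) out[k, ] <- out[k, ] + params$b_proj[[k]]
  }
  out
}

#' Dynamic routing between two capsule layers
#'
#' Each input capsule i proposes a predictive representation
#' `a_ij = W_ij c_i` for every output capsule j. Coupling coefficients
#' `beta_ij = softmax_j(m_ij)` start from zero logits, outputs are
#' `c_j = squash(sum_i beta_ij a_ij)`, and logits are updated by the scalar
#' agreement `m_ij += a_ij . c_j`, for a fixed number of iterations. Logits
#' reset to zero on every call (routing is not persistent state).
#'
#' @param inputs matrix (n_in x dim) of squashed input capsules.
#' @param W list of lists: `W[[i]][[j]]` is the (dim x dim) transform.
#' @param iters routing iterations (>= 1).
#' @param trace if `TRUE`, attach per-iteration couplings as attribute
#'   `"trace"`.
#' @return Matrix (n_out x dim) of output capsules; attribute `"beta"` holds
#'   the final coupling matrix (rows sum to 1).
#' @export
dynamic_routing <- function(inputs, W, iters = 3L, trace = FALSE) {
  n_in <- nrow(inputs)
  n_out <- length(W[[1]])
  dim_out <- nrow(W[[1]][[1]])
  a <- array(0, c(n_in, n_out, dim_out))
  for (i in seq_len(n_in)) for (j in seq_len(n_out)) {
    a[i, j, ] <- drop(W[[i]][[j]] %*% inputs[i, ])
  }
  m <- matrix(0, n_in, n_out)
  tr <- list()
  out <- matrix(0, n_out, dim_out)
  beta <- softmax_rows(m)
  for (it in seq_len(iters)) {
    beta <- softmax_rows(m)
    for (j in seq_len(n_out)) {
      aj <- matrix(a[, j, ], nrow = n_in)
      out[j, ] <- squash(colSums(aj * beta[, j]))
    }
    for (i in seq_len(n_in)) for (j in seq_len(n_out)) {
      m[i, j] <- m[i, j] + sum(a[i, j, ] * out[j, ])
    }
    if (trace) tr[[it]] <- beta
  }
  attr(out, "beta") <- beta
  if (trace) attr(out, "trace") <- tr
  out
}

#' Fuse a modality bundle into the comprehensive pair representation
#'
#' Projection (one linear map per modality), squashing into initial
#' capsules, two capsule layers with dynamic routing, then flattening of the
#' final output capsules. With the default configuration (capsule dim 512,
#' 2 output capsules) the result has length 1024.
#'
#' @param bundle list of the four pair-level modality vectors.
#' @param params a `caps_params`.
#' @param fusion `"capsule"` for the full module or `"concat"` for the
#'   ablation that splices the projected modality vectors directly.
#' @return Numeric vector: `n_out * dim` (capsule) or
#'   `n_modalities * dim` (concat).
#' @export
fuse <- function(bundle, params, fusion = c("capsule", "concat")) {
  fusion <- match.arg(fusion)
  proj <- project_modalities(bundle, params)
  if (fusion == "concat") return(as.numeric(t(proj)))
  c0 <- squash_rows(proj)
  c1 <- dynamic_routing(c0, params$W1, params$routing_iters)
  c2 <- dynamic_routing(c1, params$W2, params$routing_iters)
  as.numeric(t(c2))
}
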