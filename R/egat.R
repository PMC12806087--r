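# Edge-featured graph attention encoder for molecular graphs. Four layers
# are applied but only two parameter objects exist: layer 1 (consuming the
# 69-d atom / 6-d bond features) and one shared object reused by layers 2-4.
# Each layer jointly updates edge features (from [n_i || e_ij || n_j]),
# projects node features, computes per-head attention scores from the
# updated edge features, softmax-normalizes them over each destination
# node's incoming edges, and aggregates neighbour features per 128-d head
# slice. A final global average pool yields a 512-d per-drug vector.

egat_layer_params <- function(node_in, edge_in, dim, heads, seed_offset = 0L) {
  head_dim <- dim %/% heads
  edge_cat <- 2L * node_in + edge_in
  list(W_e = glorot(dim, edge_cat), b_e = numeric(dim),
       W_n = glorot(dim, node_in), b_n = numeric(dim),
       W_att = glorot(heads, head_dim),
       W_att_gat = glorot(heads, 2L * head_dim),
       node_in = node_in, edge_in = edge_in, dim = dim, heads = heads)
}

#' Initialize edge-featured graph attention parameters
#'
#' Creates the two parameter objects of the four-layer encoder: a first
#' layer sized for raw atom/bond features and a single shared object applied
#' as layers 2-4 (weight sharing is structural: they are one object).
#'
#' @param node_in raw atom feature width (69).
#' @param edge_in raw bond feature width (6).
#' @param dim hidden width (512).
#' @param heads number of attention heads (4; `dim` must be divisible).
#' @param leaky_slope LeakyReLU negative slope used in attention.
#' @param seed integer seed for Glorot initialization.
#' @return list of class `egat_params` with elements `layer1`, `shared`,
#'   `leaky_slope`, `n_layers`.
#' @export
egat_init <- function(node_in = 69L, edge_in = 6L, dim = 512L, heads = 4L,
                      leaky_slope = 0.2, seed = 0L) {
  if (dim %% heads != 0) stop("dim must be divisible by heads")
  with_seed(seed, {
    layer1 <- egat_layer_params(node_in, edge_in, dim, heads)
    shared <- egat_layer_params(dim, dim, dim, heads)
    structure(list(layer1 = layer1, shared = shared,
                   leaky_slope = leaky_slope, n_layers = 4L),
              class = "egat_params")
  })
}

#' Total trainable parameter count of the encoder
#'
#' Counts entries of the two parameter objects only; the three shared
#' applications of layers 2-4 add none.
#'
#' @param params an `egat_params` from [egat_init()].
#' @param mode `"egat"` (edge-feature attention) or `"gat"` (node-pair
#'   attention ablation), which decides which attention vectors count.
#' @return Integer number of trainable scalars.
#' @export
egat_param_count <- function(params, mode = c("egat", "gat")) {
  mode <- match.arg(mode)
  att <- if (mode == "egat") "W_att" else "W_att_gat"
  count_one <- function(p) {
    length(p$W_e) + length(p$b_e) + length(p$W_n) + length(p$b_n) +
      length(p[[att]])
  }
  count_one(params$layer1) + count_one(params$shared)
}

#' Update one edge feature from its endpoints
#'
#' `W_e [n_i || e_ij || n_j] + b_e`; direction-sensitive through the
#' concatenation order.
#'
#' @param n_i,n_j node feature vectors of source and destination.
#' @param e_ij current edge feature vector.
#' @param p one layer parameter object (`layer1` or `shared`).
#' @return Updated edge feature of length `p$dim`.
#' @export
update_edge <- function(n_i, e_ij, n_j, p) {
  if (length(n_i) != p$node_in || length(n_j) != p$node_in ||
      length(e_ij) != p$edge_in) {
    stop("feature widths do not match the layer specification")
  }
  drop(p$W_e %*% c(n_i, e_ij, n_j)) + p$b_e
}

#' Linearly project one node feature
#'
#' `W_n n_i + b_n`.
#'
#' @param n_i node feature vector.
#' @param p one layer parameter object.
#' @return Projected feature of length `p$dim`.
#' @export
project_node <- function(n_i, p) {
  if (length(n_i) != p$node_in) {
    stop("feature width does not match the layer specification")
  }
  drop(p$W_n %*% n_i) + p$b_n
}

#' Per-head attention logits of one updated edge feature
#'
#' The edge feature is reshaped into `heads` contiguous slices; each head's
#' logit is its attention vector dotted with the LeakyReLU of its slice.
#'
#' @param e_prime updated edge feature (length `p$dim`).
#' @param p one layer parameter object.
#' @param leaky_slope LeakyReLU negative slope.
#' @return Numeric vector of `p$heads` logits.
#' @export
edge_attention <- function(e_prime, p, leaky_slope = 0.2) {
  head_dim <- p$dim %/% p$heads
  sl <- matrix(leaky_relu(e_prime, leaky_slope), head_dim, p$heads)
  vapply(seq_len(p$heads), function(h) sum(p$W_att[h, ] * sl[, h]), 0)
}

#' Softmax-normalize attention logits over destination nodes
#'
#' For every destination node and head, logits of its incoming edges are
#' softmax-normalized so they sum to one.
#'
#' @param eps matrix of logits (n_edges x heads).
#' @param dst integer destination node per edge.
#' @return Matrix of attention scores, same shape as `eps`.
#' @export
normalize_attention <- function(eps, dst) {
  alpha <- eps
  for (grp in split(seq_along(dst), dst)) {
    alpha[grp, ] <- apply(eps[grp, , drop = FALSE], 2, function(col) {
      e <- exp(col - max(col)); e / sum(e)
    })
  }
  alpha
}

#' Aggregate projected neighbour features with attention weights
#'
#' Per head, every node's new feature slice is the attention-weighted sum of
#' its in-neighbours' projected slices; head slices are re-concatenated.
#' Nodes without incoming edges keep their projected feature.
#'
#' @param nprime projected node features (n_nodes x dim).
#' @param alpha attention scores (n_edges x heads).
#' @param edges integer matrix (n_edges x 2) of src/dst.
#' @param heads number of heads.
#' @return Aggregated node features (n_nodes x dim).
#' @export
aggregate_nodes <- function(nprime, alpha, edges, heads) {
  n <- nrow(nprime); dim <- ncol(nprime)
  head_dim <- dim %/% heads
  out <- nprime                     # fallback for in-degree-0 nodes
  if (nrow(edges) == 0) return(out)
  has_in <- unique(edges[, 2])
  out[has_in, ] <- 0
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * head_dim + seq_len(head_dim)
    contrib <- nprime[edges[, 1], cols, drop = FALSE] * alpha[, h]
    agg <- rowsum(contrib, group = edges[, 2])
    out[as.integer(rownames(agg)), cols] <- agg
  }
  out
}

# One full layer over a graph state; returns updated node and edge features.
egat_layer_forward <- function(node_feats, edge_feats, edges, p, leaky_slope,
                               mode = "egat") {
  nproj <- node_feats %*% t(p$W_n) + rep(p$b_n, each = nrow(node_feats))
  if (nrow(edges) == 0) {
    return(list(node_feats = nproj,
                edge_feats = matrix(numeric(0), 0, p$dim),
                attention = matrix(numeric(0), 0, p$heads)))
  }
  eprime <- cbind(node_feats[edges[, 1], , drop = FALSE], edge_feats,
                  node_feats[edges[, 2], , drop = FALSE]) %*% t(p$W_e) +
    rep(p$b_e, each = nrow(edges))
  head_dim <- p$dim %/% p$heads
  eps <- matrix(0, nrow(edges), p$heads)
  if (mode == "egat") {
    act <- leaky_relu(eprime, leaky_slope)
    for (h in seq_len(p$heads)) {
      cols <- (h - 1L) * head_dim + seq_len(head_dim)
      eps[, h] <- act[, cols, drop = FALSE] %*% p$W_att[h, ]
    }
  } else {
    # standard GAT ablation: attention from the projected node pair
    for (h in seq_len(p$heads)) {
      cols <- (h - 1L) * head_dim + seq_len(head_dim)
      pair <- cbind(nproj[edges[, 1], cols, drop = FALSE],
                    nproj[edges[, 2], cols, drop = FALSE])
      eps[, h] <- leaky_relu(pair %*% p$W_att_gat[h, ], leaky_slope)
    }
  }
  alpha <- normalize_attention(eps, edges[, 2])
  list(node_feats = aggregate_nodes(nproj, alpha, edges, p$heads),
       edge_feats = eprime, attention = alpha)
}

#' Encode a molecular graph into a 512-d drug vector
#'
#' Applies layer 1 followed by three applications of the shared layer object
#' (each layer's updated node and edge features feed the next), then global
#' average pooling over atoms.
#'
#' @param g a [build_molecular_graph()] result.
#' @param params an `egat_params` from [egat_init()].
#' @param mode `"egat"` or `"gat"` (node-pair attention, ignoring edge
#'   features — the encoder ablation).
#' @param keep_states return per-layer states as an attribute (for tests).
#' @return Numeric vector of length `params$layer1$dim`.
#' @export
egat_encode <- function(g, params, mode = c("egat", "gat"),
                        keep_states = FALSE) {
  mode <- match.arg(mode)
  state <- list(node_feats = g$atom_features, edge_feats = g$edge_features,
                edges = g$edges)
  layers <- c(list(params$layer1),
              rep(list(params$shared), params$n_layers - 1L))
  states <- list()
  for (p in layers) {
    res <- egat_layer_forward(state$node_feats, state$edge_feats,
                              state$edges, p, params$leaky_slope, mode)
    state <- list(node_feats = res$node_feats, edge_feats = res$edge_feats,
                  edges = state$edges)
    if (keep_states) states[[length(states) + 1L]] <- res
  }
  out <- colMeans(state$node_feats)
  if (keep_states) attr(out, "states") <- states
  out
}
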