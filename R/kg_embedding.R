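# Knowledge-graph drug features: TransE pretraining of entity/relation
# embeddings (translation principle v_h + v_r ~ v_t under a margin ranking
# loss with corrupted triples), followed by a degree-reweighted graph
# convolution over the undirected entity neighbourhood and per-node L2
# normalization. Per-pair features concatenate the two drugs' 400-d vectors.

#' Undirected neighbourhood index of a knowledge graph
#'
#' Neighbourhoods ignore relation type and direction and contain no self
#' entries.
#'
#' @param kg a [triple_store()].
#' @return list of class `neighbor_index` with `neighbors` (list of integer
#'   vectors per entity) and `degree` (integer vector).
#' @export
neighbor_index <- function(kg) {
  n <- length(kg$entity_vocab)
  t <- kg$triples
  nb <- vector("list", n)
  if (nrow(t)) {
    ends <- rbind(cbind(t$head, t$tail), cbind(t$tail, t$head))
    ends <- ends[ends[, 1] != ends[, 2], , drop = FALSE]
    sp <- split(ends[, 2], factor(ends[, 1], levels = seq_len(n)))
    nb <- lapply(sp, function(x) sort(unique(x)))
  } else {
    nb <- replicate(n, integer(0), simplify = FALSE)
  }
  structure(list(neighbors = nb, degree = vapply(nb, length, 1L)),
            class = "neighbor_index")
}

#' TransE plausibility score of a triple
#'
#' The L2 norm of `vh + vr - vt`; small scores mean plausible triples.
#'
#' @param vh,vr,vt embedding vectors of head, relation and tail.
#' @return Nonnegative scalar.
#' @export
transe_score <- function(vh, vr, vt) {
  if (length(vh) != length(vr) || length(vr) != length(vt)) {
    stop("embedding dimensions differ")
  }
  sqrt(sum((vh + vr - vt)^2))
}

# Vectorized scores for a batch of triples (rows of ids).
transe_scores_batch <- function(triples, params) {
  e <- params$entity_embeddings; r <- params$relation_embeddings
  diff <- e[triples$head, , drop = FALSE] + r[triples$relation, , drop = FALSE] -
    e[triples$tail, , drop = FALSE]
  sqrt(rowSums(diff * diff))
}

#' Margin ranking loss over paired positive/negative triples
#'
#' `sum over pairs of max(0, score(pos) + margin - score(neg))`.
#'
#' @param pos,neg data.frames of triples (`head`, `relation`, `tail` ids),
#'   row-paired.
#' @param params a `kg_embed_params` object (see [train_transe()]).
#' @param margin margin hyperparameter; defaults to the one in `params`.
#' @return Nonnegative scalar loss.
#' @export
transe_margin_loss <- function(pos, neg, params, margin = params$margin) {
  if (nrow(pos) != nrow(neg)) stop("positive and negative batches must pair up")
  if (nrow(pos) == 0) {
    warning("empty batch: loss is 0")
    return(0)
  }
  sum(pmax(0, transe_scores_batch(pos, params) + margin -
             transe_scores_batch(neg, params)))
}

#' Sample corrupted (negative) triples
#'
#' For each positive triple exactly one of head/tail is replaced by a
#' uniformly drawn entity; candidates already present in the store are
#' rejected and resampled (filtered sampling).
#'
#' @param pos data.frame of positive triples.
#' @param store a [triple_store()].
#' @param seed integer seed.
#' @param max_retries resampling bound before giving up.
#' @return data.frame of corrupted triples, row-paired with `pos`.
#' @export
sample_negatives <- function(pos, store, seed, max_retries = 100L) {
  key <- function(h, r, t) paste(h, r, t)
  seen <- key(store$triples$head, store$triples$relation, store$triples$tail)
  ne <- length(store$entity_vocab)
  with_seed(seed, {
    n <- nrow(pos)
    out <- pos
    corrupt_head <- stats::runif(n) < 0.5
    pending <- seq_len(n)
    for (it in seq_len(max_retries)) {
      if (!length(pending)) break
      repl <- sample(ne, length(pending), replace = TRUE)
      h <- ifelse(corrupt_head[pending], repl, pos$head[pending])
      t <- ifelse(corrupt_head[pending], pos$tail[pending], repl)
      ok <- !(key(h, pos$relation[pending], t) %in% seen) &
        h != t &
        repl != ifelse(corrupt_head[pending], pos$head[pending],
                       pos$tail[pending])
      out$head[pending[ok]] <- h[ok]
      out$tail[pending[ok]] <- t[ok]
      pending <- pending[!ok]
    }
    if (length(pending)) {
      stop("could not sample negatives after ", max_retries,
           " retries; the store is too dense")
    }
    out
  })
}

#' Pretrain TransE embeddings on a knowledge graph
#'
#' Full-batch Adam on the margin ranking loss with one fresh corrupted triple
#' per positive per epoch; entity embeddings are re-normalized to unit L2
#' norm after every step. A fixed monitoring subset of the triples (with
#' fixed corrupted counterparts) tracks the hinge loss; training exits early
#' when it stops improving and the best-monitored embeddings are returned.
#' Graph-convolution weights for the refinement stage are initialized
#' (Glorot, seeded) alongside.
#'
#' @param store a [triple_store()].
#' @param d embedding dimension (400 by default).
#' @param margin margin hyperparameter lambda.
#' @param lr Adam learning rate.
#' @param epochs maximum epochs.
#' @param patience early-exit patience in monitoring checks.
#' @param monitor_fraction fraction of triples in the monitoring subset.
#' @param gcn_layers number of graph-convolution layers to initialize.
#' @param gcn_norm neighbour weighting: `"sqrt"` for symmetric
#'   `1/sqrt(|Ni||Nj|)` or `"product"` for `1/(|Ni||Nj|)`.
#' @param seed integer seed controlling initialization and sampling.
#' @return list of class `kg_embed_params`: `entity_embeddings` (rownames =
#'   entity names), `relation_embeddings`, `margin`, `gcn_weights`,
#'   `gcn_norm`, and the training `history` of monitored losses.
#' @export
train_transe <- function(store, d = 400L, margin = 1, lr = 0.05,
                         epochs = 200L, patience = 50L,
                         monitor_fraction = 0.1,
                         gcn_layers = 2L, gcn_norm = c("sqrt", "product"),
                         seed = 0L) {
  gcn_norm <- match.arg(gcn_norm)
  nt <- nrow(store$triples)
  if (nt == 0) stop("empty triple store")
  ne <- length(store$entity_vocab); nr <- length(store$relation_vocab)
  with_seed(seed, {
    a <- 6 / sqrt(d)
    E <- matrix(stats::runif(ne * d, -a, a), ne,
                dimnames = list(store$entity_vocab, NULL))
    R <- matrix(stats::runif(nr * d, -a, a), nr,
                dimnames = list(store$relation_vocab, NULL))
    E <- l2_normalize_rows(E)
    n_val <- max(1L, floor(nt * monitor_fraction))
    val_idx <- sample(nt, n_val)
    val_pos <- store$triples[val_idx, , drop = FALSE]
    train_pos <- store$triples
    val_neg <- sample_negatives(val_pos, store,
                                seed = sample.int(2^31 - 1, 1))
    params <- list(E = E, R = R)
    state <- adam_init(params)
    history <- numeric(0)
    best <- Inf; best_params <- params; bad <- 0L
    for (epoch in seq_len(epochs)) {
      neg <- sample_negatives(train_pos, store,
                              seed = sample.int(2^31 - 1, 1))
      Ec <- params$E; Rc <- params$R
      dp <- Ec[train_pos$head, , drop = FALSE] +
        Rc[train_pos$relation, , drop = FALSE] -
        Ec[train_pos$tail, , drop = FALSE]
      dn <- Ec[neg$head, , drop = FALSE] + Rc[neg$relation, , drop = FALSE] -
        Ec[neg$tail, , drop = FALSE]
      sp <- sqrt(rowSums(dp * dp)); sn <- sqrt(rowSums(dn * dn))
      active <- sp + margin - sn > 0
      if (any(is.na(c(sp, sn)))) stop("TransE diverged (NaN) at epoch ", epoch)
      gE <- matrix(0, ne, d); gR <- matrix(0, nr, d)
      if (any(active)) {
        up <- dp[active, , drop = FALSE] / pmax(sp[active], 1e-12)
        un <- dn[active, , drop = FALSE] / pmax(sn[active], 1e-12)
        add <- function(G, idx, val) {
          agg <- rowsum(val, group = idx)
          ids <- as.integer(rownames(agg))
          G[ids, ] <- G[ids, , drop = FALSE] + agg
          G
        }
        pa <- train_pos[active, , drop = FALSE]
        na_ <- neg[active, , drop = FALSE]
        gE <- add(gE, pa$head, up)
        gE <- add(gE, pa$tail, -up)
        gR <- add(gR, pa$relation, up)
        gE <- add(gE, na_$head, -un)
        gE <- add(gE, na_$tail, un)
        gR <- add(gR, na_$relation, -un)
      }
      st <- adam_step(params, list(E = gE, R = gR), state, lr = lr)
      params <- st$params; state <- st$state
      params$E <- l2_normalize_rows(params$E)
      val_loss <- mean(pmax(0, transe_scores_batch(val_pos, list(
        entity_embeddings = params$E, relation_embeddings = params$R)) +
          margin -
          transe_scores_batch(val_neg, list(
            entity_embeddings = params$E, relation_embeddings = params$R))))
      history <- c(history, val_loss)
      if (val_loss < best - 1e-6) {
        best <- val_loss; best_params <- params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    gcn_w <- lapply(seq_len(gcn_layers), function(l) glorot(d, d))
    structure(list(entity_embeddings = best_params$E,
                   relation_embeddings = best_params$R,
                   margin = margin, gcn_weights = gcn_w,
                   gcn_norm = gcn_norm, history = history,
                   drug_entity_ids = store$drug_entity_ids),
              class = "kg_embed_params")
  })
}

#' One reweighted graph-convolution layer
#'
#' Updates every node as
#' `h_i' = ReLU(sum_j w_ij W h_j + w_i h_i)` over the undirected
#' neighbourhood, with `w_ij = 1/sqrt(|Ni||Nj|)` (symmetric normalization,
#' the default) or `w_ij = 1/(|Ni||Nj|)`, and self weight `w_i = 1/|Ni|`
#' (defined as 1 for isolated nodes).
#'
#' @param h node feature matrix (n x d).
#' @param idx a [neighbor_index()].
#' @param W layer weight matrix (d_out x d).
#' @param norm `"sqrt"` or `"product"` neighbour weighting.
#' @return Updated node feature matrix.
#' @export
gcn_layer <- function(h, idx, W, norm = c("sqrt", "product")) {
  norm <- match.arg(norm)
  n <- nrow(h)
  deg <- pmax(idx$degree, 0L)
  hw <- h %*% t(W)
  agg <- matrix(0, n, ncol(hw))
  for (i in seq_len(n)) {
    nb <- idx$neighbors[[i]]
    if (!length(nb)) next
    w <- if (norm == "sqrt") 1 / sqrt(deg[i] * deg[nb]) else 1 / (deg[i] * deg[nb])
    agg[i, ] <- colSums(hw[nb, , drop = FALSE] * w)
  }
  wi <- ifelse(deg > 0, 1 / deg, 1)
  relu(agg + h * wi)
}

#' Graph-convolution-refined, normalized KG features for all entities
#'
#' Runs the configured graph-convolution stack on the TransE entity
#' embeddings and L2-normalizes every node's final feature.
#'
#' @param params a `kg_embed_params` from [train_transe()].
#' @param idx a [neighbor_index()] over the same entity vocabulary.
#' @return Matrix (n_entities x d) with unit-norm rows, rownames = entities.
#' @export
kg_entity_features <- function(params, idx) {
  h <- params$entity_embeddings
  for (W in params$gcn_weights) {
    h <- gcn_layer(h, idx, W, norm = params$gcn_norm)
  }
  out <- l2_normalize_rows(h)
  rownames(out) <- rownames(params$entity_embeddings)
  out
}

#' Pair-level knowledge-graph feature
#'
#' Concatenates the two drugs' refined, unit-normalized KG features
#' (drug_i first), giving an 800-d vector at the default dimension.
#'
#' @param drug_i,drug_j entity names of the two drugs.
#' @param params a `kg_embed_params` from [train_transe()].
#' @param idx a [neighbor_index()].
#' @param features optional precomputed [kg_entity_features()] matrix.
#' @return Numeric vector of length `2 * d`.
#' @export
kg_feature <- function(drug_i, drug_j, params, idx, features = NULL) {
  if (is.null(features)) features <- kg_entity_features(params, idx)
  for (d in c(drug_i, drug_j)) {
    if (!d %in% rownames(features)) stop("unknown drug entity: ", d)
  }
  pair_concat(features[drug_i, ], features[drug_j, ])
}
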