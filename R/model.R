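# Batched forward/backward pass of the trainable trunk: per-modality
# projections, two capsule layers with dynamic routing, and the predictor
# head. Gradients are hand-derived; the converged routing couplings are
# treated as constants of the backward pass (gradients flow through the
# predictive representations, the weighted sums and the squashing).

# Flat parameter list for the trunk. Modalities are named; widths are the
# pair-level widths.
trunk_init <- function(widths, n_classes, caps_dim = 512L, n_mid = 4L,
                       n_out = 2L, routing_iters = 3L, hidden1 = 2048L,
                       hidden2 = 4096L, task = "multiclass",
                       fusion = "capsule", seed = 0L) {
  n_in <- length(widths)
  with_seed(seed, {
    params <- list()
    for (k in seq_len(n_in)) {
      params[[paste0("proj_W", k)]] <- glorot(caps_dim, widths[k])
      params[[paste0("proj_b", k)]] <- numeric(caps_dim)
    }
    if (fusion == "capsule") {
      for (i in seq_len(n_in)) for (j in seq_len(n_mid)) {
        params[[paste0("W1_", i, "_", j)]] <- glorot(caps_dim, caps_dim)
      }
      for (i in seq_len(n_mid)) for (j in seq_len(n_out)) {
        params[[paste0("W2_", i, "_", j)]] <- glorot(caps_dim, caps_dim)
      }
      fused_dim <- n_out * caps_dim
    } else {
      fused_dim <- n_in * caps_dim
    }
    params$P_W1 <- glorot(hidden1, fused_dim); params$P_b1 <- numeric(hidden1)
    params$P_W2 <- glorot(hidden2, hidden1);  params$P_b2 <- numeric(hidden2)
    params$P_W3 <- glorot(n_classes, hidden2); params$P_b3 <- numeric(n_classes)
    attr(params, "shape") <- list(n_in = n_in, n_mid = n_mid, n_out = n_out,
                                  caps_dim = caps_dim, iters = routing_iters,
                                  task = task, fusion = fusion,
                                  n_classes = n_classes)
    params
  })
}

# Batched dynamic routing. A: list of lists of (B x D) predictive
# representations. Returns output capsules C (list of B x D), final beta
# (B x n_in x n_out array) and pre-squash sums F.
routing_forward_batch <- function(A, n_in, n_out, iters) {
  B <- nrow(A[[1]][[1]])
  m <- array(0, c(B, n_in, n_out))
  C <- vector("list", n_out)
  F_ <- vector("list", n_out)
  beta <- NULL
  for (it in seq_len(iters)) {
    em <- exp(m - as.vector(apply(m, c(1, 2), max)))
    beta <- em / as.vector(apply(em, c(1, 2), sum))
    for (j in seq_len(n_out)) {
      Fj <- 0
      for (i in seq_len(n_in)) Fj <- Fj + A[[i]][[j]] * beta[, i, j]
      F_[[j]] <- Fj
      C[[j]] <- squash_rows(Fj)
    }
    for (i in seq_len(n_in)) for (j in seq_len(n_out)) {
      m[, i, j] <- m[, i, j] + rowSums(A[[i]][[j]] * C[[j]])
    }
  }
  list(C = C, F = F_, beta = beta)
}

# Forward pass over a batch. X: named list of (B x width) modality matrices
# in the trunk's modality order. Returns probabilities plus intermediates.
trunk_forward <- function(X, params) {
  sh <- attr(params, "shape")
  B <- nrow(X[[1]])
  P <- vector("list", sh$n_in); C0 <- vector("list", sh$n_in)
  for (k in seq_len(sh$n_in)) {
    P[[k]] <- X[[k]] %*% t(params[[paste0("proj_W", k)]]) +
      rep(params[[paste0("proj_b", k)]], each = B)
    C0[[k]] <- squash_rows(P[[k]])
  }
  if (sh$fusion == "capsule") {
    A1 <- lapply(seq_len(sh$n_in), function(i)
      lapply(seq_len(sh$n_mid), function(j)
        C0[[i]] %*% t(params[[paste0("W1_", i, "_", j)]])))
    r1 <- routing_forward_batch(A1, sh$n_in, sh$n_mid, sh$iters)
    A2 <- lapply(seq_len(sh$n_mid), function(i)
      lapply(seq_len(sh$n_out), function(j)
        r1$C[[i]] %*% t(params[[paste0("W2_", i, "_", j)]])))
    r2 <- routing_forward_batch(A2, sh$n_mid, sh$n_out, sh$iters)
    S <- do.call(cbind, r2$C)
  } else {
    A1 <- r1 <- A2 <- r2 <- NULL
    S <- do.call(cbind, P)
  }
  H1 <- relu(S %*% t(params$P_W1) + rep(params$P_b1, each = B))
  H2 <- relu(H1 %*% t(params$P_W2) + rep(params$P_b2, each = B))
  Z <- H2 %*% t(params$P_W3) + rep(params$P_b3, each = B)
  Q <- if (sh$task == "multiclass") softmax_rows(Z) else 1 / (1 + exp(-Z))
  list(Q = Q, Z = Z, H1 = H1, H2 = H2, S = S, P = P, C0 = C0,
       A1 = A1, r1 = r1, A2 = A2, r2 = r2, X = X)
}

# Loss and gradient wrt logits for a batch. z: binary label matrix.
trunk_loss_grad <- function(fw, z, task, pos_weights = 1) {
  B <- nrow(z); K <- ncol(z)
  Q <- pmin(pmax(fw$Q, 1e-12), 1 - 1e-12)
  if (task == "multiclass") {
    loss <- -mean(log(Q[z == 1]))
    dZ <- (fw$Q - z) / B
  } else {
    p <- matrix(rep_len(pos_weights, K), B, K, byrow = TRUE)
    loss <- -mean(rowMeans(p * z * log(Q) + (1 - z) * log(1 - Q)))
    dZ <- (-p * z * (1 - fw$Q) + (1 - z) * fw$Q) / (B * K)
  }
  list(loss = loss, dZ = dZ)
}

# Backward pass: returns gradient list matching params' names.
trunk_backward <- function(fw, dZ, params) {
  sh <- attr(params, "shape")
  g <- list()
  g$P_W3 <- t(dZ) %*% fw$H2; g$P_b3 <- colSums(dZ)
  dH2 <- (dZ %*% params$P_W3) * (fw$H2 > 0)
  g$P_W2 <- t(dH2) %*% fw$H1; g$P_b2 <- colSums(dH2)
  dH1 <- (dH2 %*% params$P_W2) * (fw$H1 > 0)
  g$P_W1 <- t(dH1) %*% fw$S; g$P_b1 <- colSums(dH1)
  dS <- dH1 %*% params$P_W1
  D <- sh$caps_dim
  if (sh$fusion == "capsule") {
    dC1 <- vector("list", sh$n_mid)
    for (i in seq_len(sh$n_mid)) dC1[[i]] <- 0
    for (j in seq_len(sh$n_out)) {
      dC2j <- dS[, (j - 1L) * D + seq_len(D), drop = FALSE]
      dF2j <- squash_rows_backward(fw$r2$F[[j]], dC2j)
      for (i in seq_len(sh$n_mid)) {
        dA <- dF2j * fw$r2$beta[, i, j]
        g[[paste0("W2_", i, "_", j)]] <- t(dA) %*% fw$r1$C[[i]]
        dC1[[i]] <- dC1[[i]] + dA %*% params[[paste0("W2_", i, "_", j)]]
      }
    }
    dC0 <- vector("list", sh$n_in)
    for (k in seq_len(sh$n_in)) dC0[[k]] <- 0
    for (j in seq_len(sh$n_mid)) {
      dF1j <- squash_rows_backward(fw$r1$F[[j]], dC1[[j]])
      for (i in seq_len(sh$n_in)) {
        dA <- dF1j * fw$r1$beta[, i, j]
        g[[paste0("W1_", i, "_", j)]] <- t(dA) %*% fw$C0[[i]]
        dC0[[i]] <- dC0[[i]] + dA %*% params[[paste0("W1_", i, "_", j)]]
      }
    }
    dP <- lapply(seq_len(sh$n_in), function(k)
      squash_rows_backward(fw$P[[k]], dC0[[k]]))
  } else {
    dP <- lapply(seq_len(sh$n_in), function(k)
      dS[, (k - 1L) * D + seq_len(D), drop = FALSE])
  }
  for (k in seq_len(sh$n_in)) {
    g[[paste0("proj_W", k)]] <- t(dP[[k]]) %*% fw$X[[k]]
    g[[paste0("proj_b", k)]] <- colSums(dP[[k]])
  }
  g
}
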