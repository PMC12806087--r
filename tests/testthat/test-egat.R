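# Edge-featured graph attention encoder.

small_egat <- function(dim = 8L, heads = 2L, seed = 3) {
  egat_init(node_in = 5L, edge_in = 3L, dim = dim, heads = heads, seed = seed)
}

test_that("update_edge and project_node match explicit products", {
  p <- small_egat()$layer1
  expect_equal(update_edge(numeric(5), numeric(3), numeric(5),
                           within(p, b_e <- numeric(8))),
               numeric(8))
  for (seed in 1:10) {
    set.seed(seed)
    ni <- rnorm(5); e <- rnorm(3); nj <- rnorm(5)
    expect_equal(update_edge(ni, e, nj, p),
                 as.numeric(p$W_e %*% c(ni, e, nj)) + p$b_e,
                 tolerance = 1e-12)
    expect_equal(project_node(ni, p),
                 as.numeric(p$W_n %*% ni) + p$b_n, tolerance = 1e-12)
  }
  expect_length(update_edge(rnorm(5), rnorm(3), rnorm(5), p), 8)
  expect_error(update_edge(rnorm(4), rnorm(3), rnorm(5), p), "widths")
  expect_error(project_node(rnorm(4), p), "width")
})

test_that("project_node with identity weights is the identity", {
  p <- small_egat()$shared
  p$W_n <- diag(8); p$b_n <- numeric(8)
  x <- rnorm(8)
  expect_equal(project_node(x, p), x)
  expect_equal(project_node(numeric(8), small_egat()$shared),
               small_egat()$shared$b_n)
})

test_that("edge_attention applies LeakyReLU slices per head", {
  p <- small_egat()$layer1
  expect_equal(edge_attention(numeric(8), p), c(0, 0))
  for (seed in 1:10) {
    set.seed(seed)
    e <- rnorm(8)
    oracle <- vapply(1:2, function(h) {
      slice <- e[(h - 1) * 4 + 1:4]
      act <- ifelse(slice >= 0, slice, 0.2 * slice)
      sum(p$W_att[h, ] * act)
    }, 0)
    expect_equal(edge_attention(e, p, 0.2), oracle, tolerance = 1e-12)
  }
  # negative entries are scaled by the slope before the dot product
  expect_equal(edge_attention(rep(-1, 8), p, 0.2),
               as.numeric(-0.2 * rowSums(p$W_att)))
})

test_that("attention normalizes to the softmax over incoming edges", {
  # single neighbor -> 1; equal logits -> 0.5/0.5; worked softmax of (1,2,3)
  a1 <- normalize_attention(matrix(c(5, 5), 1, 2), dst = 1L)
  expect_equal(as.numeric(a1), c(1, 1))
  a2 <- normalize_attention(matrix(c(0.7, 0.7), 2, 1), dst = c(1L, 1L))
  expect_equal(as.numeric(a2), c(0.5, 0.5))
  a3 <- normalize_attention(matrix(c(1, 2, 3), 3, 1), dst = c(1L, 1L, 1L))
  expect_equal(as.numeric(a3), c(0.0900, 0.2447, 0.6652), tolerance = 1e-3)
  # per-destination grouping: two nodes normalized independently
  a4 <- normalize_attention(matrix(1:4, 4, 1), dst = c(1L, 1L, 2L, 2L))
  expect_equal(sum(a4[1:2, 1]), 1)
  expect_equal(sum(a4[3:4, 1]), 1)
})

test_that("aggregate_nodes matches a brute-force double loop", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 5; heads <- 2; dim <- 8
    und <- t(combn(n, 2))
    und <- und[sample(nrow(und), 6), ]
    edges <- cbind(c(und[, 1], und[, 2]), c(und[, 2], und[, 1]))
    np <- matrix(rnorm(n * dim), n)
    eps <- matrix(rnorm(nrow(edges) * heads), nrow(edges))
    alpha <- normalize_attention(eps, edges[, 2])
    out <- aggregate_nodes(np, alpha, edges, heads)
    oracle <- matrix(0, n, dim)
    for (i in seq_len(n)) {
      inc <- which(edges[, 2] == i)
      if (!length(inc)) { oracle[i, ] <- np[i, ]; next }
      for (h in seq_len(heads)) {
        cols <- (h - 1) * 4 + 1:4
        oracle[i, cols] <- colSums(np[edges[inc, 1], cols, drop = FALSE] *
                                     alpha[inc, h])
      }
    }
    expect_equal(out, oracle, tolerance = 1e-12)
  }
  # one neighbor -> copies it; two identical neighbors -> equals either
  np <- matrix(rnorm(2 * 8), 2)
  out1 <- aggregate_nodes(np, matrix(1, 1, 2), cbind(2L, 1L), 2)
  expect_equal(out1[1, ], np[2, ])
})

test_that("per-node per-head attention sums to one on every layer of pool molecules", {
  params <- egat_init(dim = 32, seed = 1)
  for (s in smiles_pool()[c(1, 9, 17, 25)]) {
    g <- build_molecular_graph(s)
    out <- egat_encode(g, params, keep_states = TRUE)
    for (st in attr(out, "states")) {
      if (!nrow(st$attention)) next
      sums <- rowsum(st$attention, group = g$edges[, 2])
      expect_true(all(abs(sums - 1) < 1e-5))
    }
  }
})

test_that("the encoder emits a fixed-width vector and handles single atoms", {
  params <- egat_init(dim = 64, seed = 2)
  g <- build_molecular_graph("CCO")
  expect_length(egat_encode(g, params), 64)
  g1 <- build_molecular_graph("C")
  out <- egat_encode(g1, params, keep_states = TRUE)
  expect_length(out, 64)
  st <- attr(out, "states")
  # single atom: pooled vector equals that atom's final projected feature
  expect_equal(as.numeric(out), as.numeric(st[[4]]$node_feats))
})

test_that("the encoder is permutation-invariant and deterministic", {
  params <- egat_init(dim = 32, seed = 4)
  g <- random_molgraph(7, seed = 9)
  out <- egat_encode(g, params)
  expect_identical(egat_encode(g, params), out)
  set.seed(1); perm <- sample(7)
  inv <- order(perm)
  g2 <- g
  g2$atom_features <- g$atom_features[perm, ]
  g2$edges <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  expect_equal(egat_encode(g2, params), out, tolerance = 1e-10)
})

test_that("layers 2-4 are one shared parameter object", {
  params <- egat_init(dim = 32, seed = 5)
  n_one <- function(p) length(p$W_e) + length(p$b_e) + length(p$W_n) +
    length(p$b_n) + length(p$W_att)
  expect_equal(egat_param_count(params),
               n_one(params$layer1) + n_one(params$shared))
  # mutating the shared object changes the output (all deep layers see it)
  g <- random_molgraph(5, seed = 2)
  base <- egat_encode(g, params)
  params2 <- params
  params2$shared$W_n <- params2$shared$W_n * 1.01
  expect_false(isTRUE(all.equal(egat_encode(g, params2), base)))
})

test_that("the node-pair attention ablation runs with unchanged output shape", {
  params <- egat_init(dim = 32, seed = 6)
  g <- build_molecular_graph("CC(=O)OC1=CC=CC=C1C(=O)O")
  out_egat <- egat_encode(g, params, mode = "egat")
  out_gat <- egat_encode(g, params, mode = "gat")
  expect_length(out_gat, 32)
  expect_false(isTRUE(all.equal(out_egat, out_gat)))
  # gat attention ignores edge features entirely
  g2 <- g; g2$edge_features <- g$edge_features * 0
  expect_equal(egat_encode(g2, params, mode = "gat"), out_gat)
})
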