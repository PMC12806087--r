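# TransE + graph-convolution knowledge-graph features.

test_that("transe_score is the L2 norm of vh + vr - vt", {
  expect_equal(transe_score(c(0, 0), c(0, 0), c(0, 0)), 0)
  expect_equal(transe_score(c(1, 0), c(0, 1), c(1, 1)), 0)
  expect_equal(transe_score(c(3, 0), c(0, 4), c(0, 0)), 5)
  expect_error(transe_score(1:3, 1:3, 1:2), "dimensions")
})

test_that("the margin ranking loss matches its hand evaluation", {
  ev <- rbind(a = c(1, 0), b = c(0, 0), c = c(0.2, 0))
  rv <- rbind(r = c(0.5, 0))
  params <- list(entity_embeddings = ev, relation_embeddings = rv, margin = 1)
  # score(pos)=0.5 with (a,r,b): ||1+0.5-0||... construct directly instead:
  pos <- data.frame(head = 2, relation = 1, tail = 1)   # ||0+0.5-1|| = 0.5
  neg <- data.frame(head = 2, relation = 1, tail = 3)   # ||0+0.5-0.2|| = 0.3
  # hinge: max(0, 0.5 + 1 - 0.3)... use margin to match the worked value
  expect_equal(transe_margin_loss(pos, neg, params,
                                  margin = 1 - 0.1), 1.1)
  # spec worked example: pos 0.5, neg 0.2, margin 1 -> 1.3
  neg2 <- data.frame(head = 2, relation = 1, tail = 4)
  params2 <- list(entity_embeddings = rbind(ev, d = c(0.3, 0)),
                  relation_embeddings = rv, margin = 1)
  expect_equal(transe_margin_loss(pos, neg2, params2), 1.3)
  # hinge inactive when negatives are far worse than margin
  far <- data.frame(head = 2, relation = 1, tail = 5)
  params3 <- list(entity_embeddings = rbind(ev, d = c(0.3, 0), e = c(9, 0)),
                  relation_embeddings = rv, margin = 1)
  expect_equal(transe_margin_loss(pos, far, params3), 0)
  # order invariance within the batch
  pos2 <- rbind(pos, pos); neg3 <- rbind(neg2, far)
  expect_equal(transe_margin_loss(pos2, neg3, params3),
               transe_margin_loss(pos2, neg3[2:1, ], params3))
  expect_warning(l0 <- transe_margin_loss(pos[0, ], neg[0, ], params), "empty")
  expect_equal(l0, 0)
})

test_that("negative sampling corrupts exactly one side, filtered and balanced", {
  kg <- generate_kg(synth_config(n_drugs = 10, n_other_entities = 10,
                                 n_triples = 60, n_pairs = 10, seed = 5))
  key <- paste(kg$triples$head, kg$triples$relation, kg$triples$tail)
  pos <- kg$triples[rep(seq_len(nrow(kg$triples)), length.out = 10000), ]
  neg <- sample_negatives(pos, kg, seed = 0)
  head_changed <- neg$head != pos$head
  tail_changed <- neg$tail != pos$tail
  expect_true(all(xor(head_changed, tail_changed)))
  expect_identical(neg$relation, pos$relation)
  expect_false(any(paste(neg$head, neg$relation, neg$tail) %in% key))
  expect_lt(abs(mean(head_changed) - 0.5), 0.02)
  expect_identical(sample_negatives(pos, kg, seed = 0), neg)
})

test_that("TransE training reduces the monitored hinge loss deterministically", {
  kg <- fixture_dataset()$kg
  p1 <- train_transe(kg, d = 64, epochs = 60, seed = 0)
  expect_lt(tail(p1$history, 1), p1$history[1])
  expect_lt(min(p1$history), p1$history[1])
  p2 <- train_transe(kg, d = 64, epochs = 60, seed = 0)
  expect_identical(p1$entity_embeddings, p2$entity_embeddings)
  expect_true(all(abs(row_norms(p1$entity_embeddings) - 1) < 1e-8))
})

test_that("trained TransE ranks true tails above corrupted tails", {
  kg <- fixture_dataset()$kg
  params <- train_transe(kg, d = 64, epochs = 120, seed = 0)
  E <- params$entity_embeddings; R <- params$relation_embeddings
  set.seed(0)
  ranks <- vapply(sample(nrow(kg$triples), 80), function(i) {
    tr <- kg$triples[i, ]
    cand <- c(tr$tail, sample(setdiff(seq_len(nrow(E)), tr$tail), 50))
    diff <- matrix(E[tr$head, ] + R[tr$relation, ], length(cand), ncol(E),
                   byrow = TRUE) - E[cand, ]
    rank(sqrt(rowSums(diff^2)))[1]
  }, 0)
  expect_lt(mean(ranks), 26)   # random baseline: (51 + 1) / 2
})

test_that("gcn_layer matches a brute-force double loop on random graphs", {
  gcn_oracle <- function(h, idx, W, norm) {
    n <- nrow(h); out <- matrix(0, n, nrow(W))
    deg <- idx$degree
    for (i in seq_len(n)) {
      acc <- numeric(nrow(W))
      for (j in idx$neighbors[[i]]) {
        w <- if (norm == "sqrt") 1 / sqrt(deg[i] * deg[j])
             else 1 / (deg[i] * deg[j])
        acc <- acc + w * as.numeric(W %*% h[j, ])
      }
      wi <- if (deg[i] > 0) 1 / deg[i] else 1
      out[i, ] <- pmax(0, acc + wi * h[i, ])
    }
    out
  }
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:20, 1)
    tr <- data.frame(head = sample(n, 3 * n, TRUE),
                     relation = 1, tail = sample(n, 3 * n, TRUE))
    tr <- tr[tr$head != tr$tail, ]
    kg <- triple_store(tr, sprintf("e%02d", 1:n), "r", integer(0))
    idx <- neighbor_index(kg)
    h <- matrix(rnorm(n * 5), n)
    W <- matrix(rnorm(25), 5)
    for (norm in c("sqrt", "product")) {
      expect_equal(gcn_layer(h, idx, W, norm), gcn_oracle(h, idx, W, norm),
                   tolerance = 1e-10)
    }
  }
})

test_that("gcn_layer handles the two-node worked example and zero input", {
  kg <- triple_store(data.frame(head = 1, relation = 1, tail = 2),
                     c("a", "b"), "r", integer(0))
  idx <- neighbor_index(kg)
  h <- rbind(c(1, 0), c(0, 1))
  out <- gcn_layer(h, idx, diag(2))
  expect_equal(out, rbind(c(1, 1), c(1, 1)))
  expect_equal(gcn_layer(h * 0, idx, diag(2)), matrix(0, 2, 2))
})

test_that("kg_feature concatenates two unit-norm halves and swaps with order", {
  kg <- fixture_dataset()$kg
  params <- train_transe(kg, d = 32, epochs = 20, seed = 1)
  idx <- neighbor_index(kg)
  feats <- kg_entity_features(params, idx)
  f <- kg_feature("D001", "D002", params, idx, feats)
  expect_length(f, 64)
  expect_equal(sqrt(sum(f[1:32]^2)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(f[33:64]^2)), 1, tolerance = 1e-8)
  g <- kg_feature("D002", "D001", params, idx, feats)
  expect_equal(f, c(g[33:64], g[1:32]))
  expect_identical(kg_feature("D001", "D002", params, idx, feats), f)
  expect_error(kg_feature("NOPE", "D002", params, idx, feats), "unknown drug")
})
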