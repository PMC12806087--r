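# Prediction head, losses and evaluation metrics.

test_that("multiclass predictions are probability vectors and match a layer oracle", {
  p <- predictor_init(in_dim = 10, hidden1 = 7, hidden2 = 9, n_classes = 5,
                      task = "multiclass", seed = 1)
  set.seed(1)
  S <- rnorm(10)
  q <- predict_ddi(S, p)
  expect_length(q, 5)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_true(all(q >= 0))
  for (seed in 1:10) {
    set.seed(seed)
    s <- rnorm(10)
    h1 <- pmax(0, as.numeric(p$W1 %*% s) + p$b1)
    h2 <- pmax(0, as.numeric(p$W2 %*% h1) + p$b2)
    z <- as.numeric(p$W3 %*% h2) + p$b3
    expect_equal(predict_ddi(s, p), exp(z) / sum(exp(z)), tolerance = 1e-10)
  }
  expect_error(predict_ddi(rnorm(9), p), "width")
})

test_that("all-zero parameters give the uniform multiclass prediction", {
  p <- predictor_init(in_dim = 4, hidden1 = 3, hidden2 = 3, n_classes = 8,
                      task = "multiclass", seed = 2)
  for (nm in c("W1", "W2", "W3")) p[[nm]] <- p[[nm]] * 0
  expect_equal(predict_ddi(rnorm(4), p), rep(1 / 8, 8))
})

test_that("multilabel predictions are elementwise sigmoid", {
  p <- predictor_init(in_dim = 6, hidden1 = 4, hidden2 = 4, n_classes = 3,
                      task = "multilabel", seed = 3)
  q <- predict_ddi(rnorm(6), p)
  expect_true(all(q > 0 & q < 1))
  expect_false(isTRUE(all.equal(sum(q), 1)))
})

test_that("multiclass loss is -log of the true-class probability", {
  z <- c(0, 1, 0)
  expect_equal(multiclass_loss(z, c(0, 1, 0)), 0)
  K <- 85
  expect_equal(multiclass_loss(c(1, rep(0, K - 1)), rep(1 / K, K)), log(85))
  expect_equal(log(85), 4.4427, tolerance = 1e-4)
  # strictly decreasing in the true-class probability
  ls <- vapply(seq(0.1, 0.9, by = 0.1), function(q)
    multiclass_loss(z, c((1 - q) / 2, q, (1 - q) / 2)), 0)
  expect_true(all(diff(ls) < 0))
  expect_equal(multiclass_loss(z, c(0.5, 0, 0.5)), -log(1e-12))
  expect_error(multiclass_loss(c(1, 1, 0), c(0.5, 0.5, 0)), "one-hot")
})

test_that("multilabel loss matches closed forms and weighting behaviour", {
  expect_lt(multilabel_loss(c(1, 0, 1), c(1, 0, 1)), 1e-10)
  expect_equal(multilabel_loss(c(1, 0, 1, 0), rep(0.5, 4)), log(2))
  expect_equal(log(2), 0.6931, tolerance = 1e-4)
  z <- c(1, 0); q <- c(0.7, 0.2)
  base <- multilabel_loss(z, q, c(1, 1))
  up_pos <- multilabel_loss(z, q, c(2, 1))
  up_neg <- multilabel_loss(z, q, c(1, 2))
  expect_gt(up_pos, base)          # doubling p_c on an imperfect positive
  expect_equal(up_neg, base)       # p_c on a negative type has no effect
})

test_that("positive weights equal the negative-to-positive ratio per type", {
  zm <- matrix(0, 10, 2); zm[1:2, 1] <- 1; zm[1:5, 2] <- 1
  expect_equal(positive_weights(zm), c(4, 1))
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rbinom(60, 1, 0.5), 20)
    if (any(colSums(m) == 0)) next
    expect_equal(positive_weights(m), (20 - colSums(m)) / colSums(m))
  }
  zm[, 1] <- 0
  expect_error(positive_weights(zm), "zero positives")
})

test_that("total_loss is the permutation-invariant batch mean", {
  set.seed(4)
  z <- diag(3)[sample(3, 6, TRUE), ]
  q <- softmax_rows(matrix(rnorm(18), 6))
  per <- vapply(1:6, function(i) multiclass_loss(z[i, ], q[i, ]), 0)
  expect_equal(total_loss(z, q, "multiclass"), mean(per))
  perm <- sample(6)
  expect_equal(total_loss(z[perm, ], q[perm, ], "multiclass"),
               total_loss(z, q, "multiclass"))
  expect_equal(total_loss(z[c(1, 1), ], q[c(1, 1), ], "multiclass"), per[1])
  expect_error(total_loss(z[0, ], q[0, ], "multiclass"), "empty")
})

test_that("multiclass loss is the one-hot multilabel loss up to the 1/Nc factor", {
  for (seed in 1:10) {
    set.seed(seed)
    K <- 6
    z <- diag(K)[sample(K, 1), ]
    q <- exp(rnorm(K)); q <- q / sum(q)
    ml_pos_term <- -sum(z * log(q)) / K
    full_ml <- multilabel_loss(z, q, pos_weights = 1)
    neg_term <- -sum((1 - z) * log(1 - q)) / K
    expect_equal(full_ml, ml_pos_term + neg_term, tolerance = 1e-10)
    expect_equal(multiclass_loss(z, q), ml_pos_term * K, tolerance = 1e-10)
  }
})

test_that("a few optimization steps strictly decrease the batch loss", {
  set.seed(5)
  p <- predictor_init(in_dim = 8, hidden1 = 6, hidden2 = 6, n_classes = 3,
                      task = "multiclass", seed = 5)
  S <- matrix(rnorm(20 * 8), 20)
  y <- sample(3, 20, TRUE)
  z <- diag(3)[y, ]
  params <- p[c("W1", "b1", "W2", "b2", "W3", "b3")]
  state <- adam_init(params)
  losses <- numeric(6)
  for (step in 1:6) {
    H1 <- relu(S %*% t(params$W1) + rep(params$b1, each = 20))
    H2 <- relu(H1 %*% t(params$W2) + rep(params$b2, each = 20))
    Z <- H2 %*% t(params$W3) + rep(params$b3, each = 20)
    Q <- softmax_rows(Z)
    losses[step] <- -mean(log(Q[z == 1]))
    dZ <- (Q - z) / 20
    g <- list(W3 = t(dZ) %*% H2, b3 = colSums(dZ))
    dH2 <- (dZ %*% params$W3) * (H2 > 0)
    g$W2 <- t(dH2) %*% H1; g$b2 <- colSums(dH2)
    dH1 <- (dH2 %*% params$W2) * (H1 > 0)
    g$W1 <- t(dH1) %*% S; g$b1 <- colSums(dH1)
    st <- adam_step(params, g, state, lr = 0.05)
    params <- st$params; state <- st$state
  }
  expect_true(all(diff(losses) < 0))
})

test_that("metrics match hand arithmetic on the worked confusion matrix", {
  # confusion [[40,10],[20,30]]: accuracy 0.70, kappa 0.40
  y_true <- c(rep(1, 50), rep(2, 50))
  y_pred <- c(rep(1, 40), rep(2, 10), rep(1, 20), rep(2, 30))
  expect_equal(mean(y_true == y_pred), 0.70)
  expect_equal(cohen_kappa(y_true, y_pred), 0.40)
  expect_equal(macro_precision(1:4, 1:4), 1)
  expect_equal(cohen_kappa(1:4, 1:4), 1)
  # a class never predicted contributes zero precision
  expect_equal(macro_precision(c(1, 1, 2, 2), c(1, 1, 1, 1)),
               mean(c(0.5, 0)))
})

test_that("evaluate matches frozen independent reference values", {
  y <- c(1, 1, 2, 2, 3, 3, 3, 2, 1, 3)
  s <- rbind(c(0.7, 0.2, 0.1), c(0.4, 0.5, 0.1), c(0.3, 0.6, 0.1),
             c(0.2, 0.3, 0.5), c(0.1, 0.2, 0.7), c(0.3, 0.3, 0.4),
             c(0.25, 0.25, 0.5), c(0.6, 0.3, 0.1), c(0.5, 0.3, 0.2),
             c(0.2, 0.5, 0.3))
  m <- evaluate_predictions(y, s, "multiclass")
  expect_equal(m$aupr, 0.680050505050505, tolerance = 1e-9)
  expect_equal(m$auc, 0.8425, tolerance = 1e-9)
  expect_equal(m$kappa, 0.3939393939393939, tolerance = 1e-9)
  expect_equal(m$macro_precision, 0.5833333333333334, tolerance = 1e-9)
})

test_that("rank-based AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  for (seed in 1:10) {
    set.seed(seed)
    lab <- rbinom(50, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- rnorm(50) + lab
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(binary_auc(lab, sc), ref, tolerance = 1e-9)
  }
})

test_that("random scores give chance-level AUC and single-class input errors", {
  set.seed(0)
  y <- sample(2, 2000, TRUE)
  s <- matrix(runif(4000), 2000)
  m <- evaluate_predictions(y, s, "multiclass")
  expect_lt(abs(m$auc - 0.5), 0.05)
  expect_error(evaluate_predictions(rep(1, 10), s[1:10, ], "multiclass"),
               "single class")
  expect_error(evaluate_predictions(matrix(1, 5, 3), matrix(runif(15), 5),
                                    "multilabel"), "single class")
})

test_that("multilabel evaluation scores all pair-type cells micro-averaged", {
  set.seed(6)
  z <- matrix(rbinom(60, 1, 0.3), 20)
  z[1, ] <- c(1, 0, 0)
  s <- matrix(runif(60), 20) + z
  m <- evaluate_predictions(z, s, "multilabel")
  expect_equal(m$aupr, binary_aupr(as.numeric(z), as.numeric(s)))
  expect_equal(m$auc, binary_auc(as.numeric(z), as.numeric(s)))
  expect_gt(m$auc, 0.8)
})
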