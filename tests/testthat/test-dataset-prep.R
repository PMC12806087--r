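# Dataset-construction filters: counts, idempotence, brute-force oracles.

make_kg <- function(triples, n_drugs, n_other, n_rel = 2) {
  ev <- c(sprintf("D%02d", seq_len(n_drugs)), sprintf("E%02d", seq_len(n_other)))
  triple_store(triples, ev, sprintf("r%d", seq_len(n_rel)), seq_len(n_drugs))
}

test_that("remove_ddi_edges drops exactly the flagged relations", {
  tr <- data.frame(head = c(1, 2, 3, 4, 1, 2, 3, 1, 2, 4),
                   relation = c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2),
                   tail = c(5, 6, 7, 5, 6, 7, 5, 6, 7, 6))
  kg <- make_kg(tr, 4, 3)
  out <- remove_ddi_edges(kg, "r1")
  expect_equal(nrow(out$triples), 7)
  expect_identical(out$entity_vocab, kg$entity_vocab)
  expect_identical(remove_ddi_edges(kg, character(0))$triples, kg$triples)
  expect_error(remove_ddi_edges(kg, "nope"), "unknown relation")
})

test_that("a drug whose only edges carried DDI information becomes isolated", {
  tr <- data.frame(head = c(1, 2, 2), relation = c(1, 2, 2), tail = c(4, 4, 3))
  kg <- make_kg(tr, 3, 1)
  before <- entity_degrees(kg)
  out <- remove_ddi_edges(kg, "r1")
  after <- entity_degrees(out)
  expect_gte(before["D01"], 1)
  expect_equal(unname(after["D01"]), 0)
})

test_that("remove_isolated_entities reports and drops only zero-degree scoped entities", {
  tr <- data.frame(head = c(1, 2), relation = c(1, 1), tail = c(4, 5))
  kg <- make_kg(tr, 3, 3)                    # D03 and E03 are isolated
  res <- remove_isolated_entities(kg)
  expect_setequal(res$removed, c("D03", "E03"))
  expect_equal(nrow(res$store$triples), 2)
  # triples still name the same entities
  expect_identical(res$store$entity_vocab[res$store$triples$head],
                   kg$entity_vocab[kg$triples$head])
  # idempotence: second application is the identity with empty removal
  res2 <- remove_isolated_entities(res$store)
  expect_length(res2$removed, 0)
  expect_identical(res2$store$triples, res$store$triples)
})

test_that("enforce_single_type keeps exactly the uniquely labelled pairs", {
  ddi <- ddi_table(c("a", "b", "c"), c("b", "c", "d"),
                   list("A", c("A", "B"), "B"))
  out <- enforce_single_type(ddi)
  expect_equal(n_pairs(out), 2)
  expect_true(all(vapply(out$labels, length, 1L) == 1L))
  expect_identical(enforce_single_type(out)$pairs, out$pairs)
})

test_that("enforce_single_type removes the planted multi-label fraction", {
  set.seed(1)
  n <- 2000
  ids <- sprintf("x%04d", 1:4000)
  multi <- runif(n) < 0.05
  labels <- lapply(multi, function(m) if (m) c("A", "B") else "A")
  ddi <- ddi_table(ids[seq_len(n) * 2 - 1], ids[seq_len(n) * 2], labels)
  frac <- 1 - n_pairs(enforce_single_type(ddi)) / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("dedupe halves a fully mirrored table and matches a set oracle", {
  ids_a <- sprintf("a%02d", 1:30); ids_b <- sprintf("b%02d", 1:30)
  lab <- sample(LETTERS[1:4], 30, replace = TRUE)
  ddi <- ddi_table(c(ids_a, ids_b), c(ids_b, ids_a), c(lab, lab))
  out <- dedupe_unordered_pairs(ddi)
  expect_equal(n_pairs(out), 30)
  # mixed case: oracle by frozen-pair set
  small <- fixture_small_ddi()
  mixed <- ddi_table(c(small$pairs$drug_i, small$pairs$drug_j[1:10]),
                     c(small$pairs$drug_j, small$pairs$drug_i[1:10]),
                     c(small$labels, small$labels[1:10]))
  ded <- dedupe_unordered_pairs(mixed)
  oracle <- unique(paste(pmin(mixed$pairs$drug_i, mixed$pairs$drug_j),
                         pmax(mixed$pairs$drug_i, mixed$pairs$drug_j)))
  expect_equal(n_pairs(ded), length(oracle))
  expect_identical(dedupe_unordered_pairs(ded)$pairs, ded$pairs)
  # conflicting single labels on mirrored rows are an error
  bad <- ddi_table(c("u", "v"), c("v", "u"), list("A", "B"))
  expect_error(dedupe_unordered_pairs(bad), "conflicting")
})

test_that("intersect_with_drugs equals the brute-force filter", {
  ddi <- fixture_small_ddi()
  expect_identical(intersect_with_drugs(ddi, unique(c(ddi$pairs$drug_i,
                                                      ddi$pairs$drug_j)))$pairs,
                   ddi$pairs)
  expect_equal(n_pairs(intersect_with_drugs(ddi, character(0))), 0)
  set.seed(3)
  keep <- sample(unique(c(ddi$pairs$drug_i, ddi$pairs$drug_j)), 6)
  out <- intersect_with_drugs(ddi, keep)
  sel <- ddi$pairs$drug_i %in% keep & ddi$pairs$drug_j %in% keep
  expect_identical(out$pairs$drug_i, ddi$pairs$drug_i[sel])
})

test_that("select_label_types keeps the smallest-count survivors", {
  counts <- c(A = 5, B = 12, C = 20, D = 30)
  rows <- rep(names(counts), counts)
  n <- length(rows)
  ddi <- ddi_table(sprintf("p%03d", 1:n), sprintf("q%03d", 1:n), rows)
  out <- select_label_types(ddi, min_count = 10, top_n = 2)
  expect_setequal(out$type_vocab, c("B", "C"))
  expect_equal(n_pairs(out), 32)
  # identity up to vocab reindex
  all_kept <- select_label_types(ddi, min_count = 0, top_n = 4)
  expect_equal(n_pairs(all_kept), n)
  expect_error(select_label_types(ddi, min_count = 10, top_n = 5), "survive")
})

test_that("select_label_types matches a brute-force oracle on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    labs <- sample(LETTERS[1:8], n, replace = TRUE)
    ddi <- ddi_table(sprintf("p%03d", 1:n), sprintf("q%03d", 1:n), labs)
    out <- select_label_types(ddi, min_count = 5, top_n = 3)
    tab <- table(labs)
    surv <- tab[tab >= 5]
    oracle <- names(surv)[order(as.integer(surv), names(surv))][1:3]
    expect_setequal(out$type_vocab, oracle)
    expect_equal(n_pairs(out), sum(labs %in% oracle))
    # idempotence at neutral settings
    again <- select_label_types(out, min_count = 0, top_n = 3)
    expect_equal(n_pairs(again), n_pairs(out))
  }
})

test_that("the multiclass prep recipe composes cleanly on synthetic data", {
  ds <- fixture_dataset()
  ddi <- dedupe_unordered_pairs(enforce_single_type(ds$ddi))
  keep <- ds$drugs$id[vapply(ds$drugs$smiles, function(s)
    !inherits(try(parse_molecule(s), silent = TRUE), "try-error"), TRUE)]
  keep <- intersect(keep, ds$kg$entity_vocab)
  ddi <- intersect_with_drugs(ddi, keep)
  expect_gt(n_pairs(ddi), 0)
  expect_true(all(vapply(ddi$labels, length, 1L) == 1L))
  drugs_used <- unique(c(ddi$pairs$drug_i, ddi$pairs$drug_j))
  expect_true(all(drugs_used %in% ds$kg$entity_vocab))
})
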