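#' Triple store for a biomedical knowledge graph
#'
#' A knowledge graph is held as integer-coded (head, relation, tail) triples
#' together with the entity and relation vocabularies and the subset of
#' entities that are drugs. Ids are 1-based indices into the vocabularies.
#'
#' @param triples data.frame with integer columns `head`, `relation`, `tail`.
#' @param entity_vocab character vector of unique entity names; position is id.
#' @param relation_vocab character vector of unique relation names.
#' @param drug_entity_ids integer vector of entity ids that are drugs.
#' @return An object of class `triple_store`.
#' @export
triple_store <- function(triples, entity_vocab, relation_vocab, drug_entity_ids) {
  if (anyDuplicated(entity_vocab)) stop("duplicate entity names in vocab")
  if (anyDuplicated(relation_vocab)) stop("duplicate relation names in vocab")
  triples <- as.data.frame(triples)[, c("head", "relation", "tail")]
  ne <- length(entity_vocab)
  if (nrow(triples) > 0) {
    if (any(triples$head < 1 | triples$head > ne) ||
        any(triples$tail < 1 | triples$tail > ne)) {
      stop("triple entity id outside vocabulary range")
    }
    if (any(triples$relation < 1 | triples$relation > length(relation_vocab))) {
      stop("triple relation id outside vocabulary range")
    }
  }
  if (any(drug_entity_ids < 1 | drug_entity_ids > ne)) {
    stop("drug entity id outside vocabulary range")
  }
  structure(
    list(triples = triples, entity_vocab = entity_vocab,
         relation_vocab = relation_vocab,
         drug_entity_ids = as.integer(drug_entity_ids)),
    class = "triple_store")
}

#' @export
print.triple_store <- function(x, ...) {
  cat("<triple_store> ", nrow(x$triples), " triples, ",
      length(x$entity_vocab), " entities (", length(x$drug_entity_ids),
      " drugs), ", length(x$relation_vocab), " relations\n", sep = "")
  invisible(x)
}

#' Number of triple incidences per entity (degree census)
#'
#' Counts, for every entity in the vocabulary, how many triples it appears in
#' as head or tail.
#'
#' @param kg a [triple_store()].
#' @return Named integer vector over the entity vocabulary.
#' @export
entity_degrees <- function(kg) {
  d <- integer(length(kg$entity_vocab))
  t <- kg$triples
  if (nrow(t) > 0) {
    tab <- table(factor(c(t$head, t$tail), levels = seq_along(kg$entity_vocab)))
    d <- as.integer(tab)
  }
  names(d) <- kg$entity_vocab
  d
}

#' Table of drug-drug interactions with type labels
#'
#' Rows are unordered drug pairs; each row carries a non-empty set of type
#' labels (a single label in the multiclass setting). Pair keys need not be
#' unique on construction: [dedupe_unordered_pairs()] establishes uniqueness.
#'
#' @param drug_i,drug_j character vectors of drug identifiers.
#' @param labels list of character vectors (or a character vector for
#'   single-label tables), one element per pair.
#' @param type_vocab character vector of all admissible labels; defaults to
#'   the sorted set of labels present.
#' @return An object of class `ddi_table`.
#' @export
ddi_table <- function(drug_i, drug_j, labels, type_vocab = NULL) {
  drug_i <- as.character(drug_i); drug_j <- as.character(drug_j)
  if (length(drug_i) != length(drug_j)) stop("drug_i and drug_j lengths differ")
  if (any(drug_i == drug_j)) stop("self-pairs (drug_i == drug_j) are not allowed")
  if (!is.list(labels)) labels <- as.list(as.character(labels))
  if (length(labels) != length(drug_i)) stop("labels length mismatch")
  labels <- lapply(labels, function(l) unique(as.character(l)))
  if (any(vapply(labels, length, 1L) == 0)) stop("every pair needs >= 1 label")
  if (is.null(type_vocab)) type_vocab <- sort(unique(unlist(labels)))
  missing <- setdiff(unlist(labels), type_vocab)
  if (length(missing)) stop("labels outside type vocab: ", paste(missing, collapse = ", "))
  structure(list(pairs = data.frame(drug_i = drug_i, drug_j = drug_j,
                                    stringsAsFactors = FALSE),
                 labels = labels, type_vocab = type_vocab),
            class = "ddi_table")
}

#' @export
print.ddi_table <- function(x, ...) {
  cat("<ddi_table> ", nrow(x$pairs), " pairs, ", length(x$type_vocab),
      " types\n", sep = "")
  invisible(x)
}

#' Number of pairs in a DDI table
#' @param ddi a [ddi_table()].
#' @return Integer count of rows.
#' @export
n_pairs <- function(ddi) nrow(ddi$pairs)

# Canonical unordered pair key.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Remove knowledge-graph edges that carry DDI information
#'
#' Drops every triple whose relation is in `ddi_relations`, so that no
#' interaction prior leaks into the prediction model. Vocabularies are
#' preserved unchanged.
#'
#' @param kg a [triple_store()].
#' @param ddi_relations character vector of relation names to remove.
#' @return A filtered [triple_store()].
#' @export
remove_ddi_edges <- function(kg, ddi_relations) {
  unknown <- setdiff(ddi_relations, kg$relation_vocab)
  if (length(unknown)) stop("unknown relation(s): ", paste(unknown, collapse = ", "))
  drop_ids <- match(ddi_relations, kg$relation_vocab)
  keep <- !(kg$triples$relation %in% drop_ids)
  triple_store(kg$triples[keep, , drop = FALSE], kg$entity_vocab,
               kg$relation_vocab, kg$drug_entity_ids)
}

#' Drop entities that no triple touches
#'
#' Entities in `scope` with zero triple incidence are removed from the
#' vocabulary (ids are re-indexed; triples are unchanged as name-level facts)
#' and reported back.
#'
#' @param kg a [triple_store()].
#' @param scope character vector of entity names eligible for removal;
#'   defaults to the whole vocabulary.
#' @return list with elements `store` (filtered [triple_store()]) and
#'   `removed` (character vector of dropped entity names).
#' @export
remove_isolated_entities <- function(kg, scope = kg$entity_vocab) {
  unknown <- setdiff(scope, kg$entity_vocab)
  if (length(unknown)) stop("unknown entity(ies): ", paste(unknown, collapse = ", "))
  deg <- entity_degrees(kg)
  removed <- intersect(scope, names(deg)[deg == 0])
  if (!length(removed)) {
    return(list(store = kg, removed = character(0)))
  }
  keep_names <- setdiff(kg$entity_vocab, removed)
  remap <- match(kg$entity_vocab, keep_names)          # old id -> new id
  triples <- kg$triples
  triples$head <- remap[triples$head]
  triples$tail <- remap[triples$tail]
  drug_names <- kg$entity_vocab[kg$drug_entity_ids]
  new_drugs <- match(intersect(drug_names, keep_names), keep_names)
  list(store = triple_store(triples, keep_names, kg$relation_vocab, new_drugs),
       removed = removed)
}

#' Keep only uniquely typed drug pairs
#'
#' Pairs annotated with two or more distinct labels are removed so that every
#' remaining pair is categorized by exactly one interaction type.
#'
#' @param ddi a [ddi_table()].
#' @return A filtered [ddi_table()].
#' @export
enforce_single_type <- function(ddi) {
  keep <- vapply(ddi$labels, length, 1L) == 1L
  ddi_table(ddi$pairs$drug_i[keep], ddi$pairs$drug_j[keep],
            ddi$labels[keep], ddi$type_vocab)
}

#' Collapse mirrored duplicate pairs
#'
#' `(a, b)` and `(b, a)` rows describing the same unordered pair collapse to
#' one row. Mirrored single-label rows with different labels are a data error.
#' Mirrored multilabel rows merge by label-set union.
#'
#' @param ddi a [ddi_table()].
#' @return A [ddi_table()] with one row per unordered pair.
#' @export
dedupe_unordered_pairs <- function(ddi) {
  key <- pair_key(ddi$pairs$drug_i, ddi$pairs$drug_j)
  first <- !duplicated(key)
  groups <- split(seq_along(key), key)
  labels <- ddi$labels
  merged <- lapply(groups, function(idx) {
    sets <- labels[idx]
    u <- sort(unique(unlist(sets)))
    single <- all(vapply(sets, length, 1L) == 1L)
    if (single && length(u) > 1L) {
      stop("conflicting labels for mirrored pair ",
           ddi$pairs$drug_i[idx[1]], " / ", ddi$pairs$drug_j[idx[1]],
           ": ", paste(u, collapse = ", "))
    }
    u
  })
  ord <- which(first)
  keys_first <- key[ord]
  ddi_table(ddi$pairs$drug_i[ord], ddi$pairs$drug_j[ord],
            merged[keys_first], ddi$type_vocab)
}

#' Restrict a DDI table to a drug set
#'
#' Keeps a row only when both of its drugs are in `keep` (e.g. the drugs that
#' are knowledge-graph entities and have a parseable SMILES).
#'
#' @param ddi a [ddi_table()].
#' @param keep character vector of drug ids to retain.
#' @return A filtered [ddi_table()].
#' @export
intersect_with_drugs <- function(ddi, keep) {
  sel <- ddi$pairs$drug_i %in% keep & ddi$pairs$drug_j %in% keep
  ddi_table(ddi$pairs$drug_i[sel], ddi$pairs$drug_j[sel],
            ddi$labels[sel], ddi$type_vocab)
}

#' Select interaction types by frequency
#'
#' Types occurring fewer than `min_count` times are dropped; among the
#' survivors the `top_n` types with the smallest pair counts are selected
#' (ascending count, ties broken by label order). Rows are relabelled against
#' the reduced vocabulary; multilabel rows keep only surviving labels and are
#' dropped when none survive.
#'
#' @param ddi a [ddi_table()].
#' @param min_count minimum number of pairs a type needs to survive.
#' @param top_n number of surviving types to keep.
#' @return A filtered, re-vocabularied [ddi_table()].
#' @export
select_label_types <- function(ddi, min_count, top_n) {
  stopifnot_count(min_count, "min_count", min = 0L)
  stopifnot_count(top_n, "top_n", min = 1L)
  counts <- table(factor(unlist(ddi$labels), levels = ddi$type_vocab))
  counts <- counts[counts > 0]
  survivors <- counts[counts >= min_count]
  if (length(survivors) < top_n) {
    stop("only ", length(survivors), " type(s) survive min_count=", min_count,
         " but top_n=", top_n, "; counts: ",
         paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  }
  ord <- order(as.integer(survivors), names(survivors))
  selected <- names(survivors)[ord][seq_len(top_n)]
  new_labels <- lapply(ddi$labels, function(l) intersect(l, selected))
  keep <- vapply(new_labels, length, 1L) > 0L
  ddi_table(ddi$pairs$drug_i[keep], ddi$pairs$drug_j[keep],
            new_labels[keep], selected)
}
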