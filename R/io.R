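# Plain-text file formats shared by the synthetic generator and the real
# pipeline: drugs as 2-column CSV (id,smiles); KG as 3-column TSV
# (head,relation,tail); DDI table as CSV (drug_i,drug_j,labels with multiple
# labels pipe-joined); pharmacology as CSV of id + bit-string.

#' Write a drug table
#' @param drugs data.frame with columns `id`, `smiles`.
#' @param path output CSV path.
#' @export
write_drug_table <- function(drugs, path) {
  utils::write.csv(drugs[, c("id", "smiles")], path, row.names = FALSE,
                   quote = FALSE)
}

#' Read a drug table
#' @param path CSV path with columns `id`, `smiles`.
#' @return data.frame with character columns `id`, `smiles`.
#' @export
read_drug_table <- function(path) {
  utils::read.csv(path, colClasses = "character")
}

#' Write knowledge-graph triples as TSV
#' @param kg a [triple_store()].
#' @param path output TSV path (`head`, `relation`, `tail` entity/relation names).
#' @export
write_triples <- function(kg, path) {
  df <- data.frame(head = kg$entity_vocab[kg$triples$head],
                   relation = kg$relation_vocab[kg$triples$relation],
                   tail = kg$entity_vocab[kg$triples$tail])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read knowledge-graph triples from TSV
#'
#' @param path TSV path with columns `head`, `relation`, `tail`.
#' @param drug_ids character vector naming which entities are drugs; entities
#'   matching are flagged in the returned store.
#' @return A [triple_store()].
#' @export
read_triples <- function(path, drug_ids = character(0)) {
  df <- utils::read.delim(path, colClasses = "character")
  entity_vocab <- sort(unique(c(df$head, df$tail, drug_ids)))
  relation_vocab <- sort(unique(df$relation))
  triples <- data.frame(head = match(df$head, entity_vocab),
                        relation = match(df$relation, relation_vocab),
                        tail = match(df$tail, entity_vocab))
  triple_store(triples, entity_vocab, relation_vocab,
               which(entity_vocab %in% drug_ids))
}

#' Write a DDI table as CSV
#' @param ddi a [ddi_table()]; multiple labels are pipe-joined.
#' @param path output CSV path.
#' @export
write_ddi_table <- function(ddi, path) {
  df <- data.frame(drug_i = ddi$pairs$drug_i, drug_j = ddi$pairs$drug_j,
                   labels = vapply(ddi$labels, paste, "", collapse = "|"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a DDI table from CSV
#' @param path CSV with columns `drug_i`, `drug_j`, `labels` (pipe-joined).
#' @return A [ddi_table()].
#' @export
read_ddi_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  ddi_table(df$drug_i, df$drug_j, strsplit(df$labels, "|", fixed = TRUE))
}

#' Write pharmacology bit vectors as CSV
#' @param pharm list with binary matrices `enzyme`, `target` (rownames = ids).
#' @param path output CSV path (columns id, enzyme, target as 0/1 strings).
#' @export
write_pharm_table <- function(pharm, path) {
  df <- data.frame(id = rownames(pharm$enzyme),
                   enzyme = apply(pharm$enzyme, 1, paste, collapse = ""),
                   target = apply(pharm$target, 1, paste, collapse = ""))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read pharmacology bit vectors from CSV
#' @param path CSV written by [write_pharm_table()].
#' @return list with binary matrices `enzyme` and `target`.
#' @export
read_pharm_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  unpack <- function(col) {
    m <- t(vapply(strsplit(col, ""), function(x) as.integer(x),
                  integer(nchar(col[1]))))
    rownames(m) <- df$id
    m
  }
  list(enzyme = unpack(df$enzyme), target = unpack(df$target))
}

#' Write a synthetic dataset to a directory
#' @param ds result of [generate_synthetic_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_drug_table(ds$drugs, file.path(dir, "drugs.csv"))
  write_triples(ds$kg, file.path(dir, "kg.tsv"))
  write_ddi_table(ds$ddi, file.path(dir, "ddi.csv"))
  write_pharm_table(ds$pharm, file.path(dir, "pharm.csv"))
  invisible(dir)
}
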