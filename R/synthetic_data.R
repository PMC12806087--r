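# Seeded toy-data generators. They emulate the statistical shape of the real
# inputs (multi-relation biomedical KG with drug entities, valid SMILES,
# sparse binary pharmacology vectors, planted pair labels) so every stage of
# the pipeline is testable with no download.

# Curated drug-like molecules; every entry is verified parseable in the test
# suite. First entry is aspirin.
.smiles_pool <- c(
  "CC(=O)OC1=CC=CC=C1C(=O)O",                      # aspirin
  "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",                  # caffeine
  "CC(=O)NC1=CC=C(O)C=C1",                         # paracetamol
  "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",                 # ibuprofen
  "CN1CCCC1C2=CN=CC=C2",                           # nicotine
  "CCOC(=O)C1=CC=C(N)C=C1",                        # benzocaine
  "CCN(CC)CCOC(=O)C1=CC=C(N)C=C1",                 # procaine
  "CCN(CC)CC(=O)NC1=C(C)C=CC=C1C",                 # lidocaine
  "CCC1(C2=CC=CC=C2)C(=O)NC(=O)NC1=O",             # phenobarbital
  "CC(=O)CC(C1=CC=CC=C1)C2=C(O)C3=CC=CC=C3OC2=O",  # warfarin
  "CN1C(=O)CN=C(C2=CC=CC=C2)C3=CC(Cl)=CC=C13",     # diazepam
  "CN(C)C(=N)NC(=N)N",                             # metformin
  "CC(C)(C)NCC(O)C1=CC(CO)=C(O)C=C1",              # salbutamol
  "CC(C)NCC(O)COC1=CC=CC2=CC=CC=C12",              # propranolol
  "CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1",             # atenolol
  "CN(C)CCCN1C2=CC=CC=C2SC3=CC=C(Cl)C=C13",        # chlorpromazine
  "CN(C)CCCN1C2=CC=CC=C2CCC3=CC=CC=C13",           # imipramine
  "CNCCC(OC1=CC=C(C=C1)C(F)(F)F)C2=CC=CC=C2",      # fluoxetine
  "CC1=CC(=NO1)NS(=O)(=O)C2=CC=C(N)C=C2",          # sulfamethoxazole
  "COC1=CC(=CC(OC)=C1OC)CC2=CN=C(N)N=C2N",         # trimethoprim
  "NNC(=O)C1=CC=NC=C1",                            # isoniazid
  "NC(=O)C1=CN=CC=N1",                             # pyrazinamide
  "CN1C(=O)N(C)C2=C(NC=N2)C1=O",                   # theophylline
  "OC(=O)C1=CN(C2CC2)C3=CC(N4CCNCC4)=C(F)C=C3C1=O",# ciprofloxacin
  "NCCC1=CC=C(O)C(O)=C1",                          # dopamine
  "NCCC1=CNC2=CC=C(O)C=C12",                       # serotonin
  "NCCC1=CNC=N1",                                  # histamine
  "CNCC(O)C1=CC=C(O)C(O)=C1",                      # adrenaline
  "COC1=CC2=C(NC=C2CCNC(C)=O)C=C1",                # melatonin
  "O=C1NC(=O)C(C2=CC=CC=C2)(C3=CC=CC=C3)N1",       # phenytoin
  "NC(=O)N1C2=CC=CC=C2C=CC3=CC=CC=C13",            # carbamazepine
  "NS(=O)(=O)C1=CC2=C(C=C1Cl)NCNS2(=O)=O",         # hydrochlorothiazide
  "CCOC1=CC=C(NC(C)=O)C=C1",                       # phenacetin
  "CC(N)CC1=CC=CC=C1",                             # amphetamine
  "CNC(C)C(O)C1=CC=CC=C1",                         # ephedrine (no stereo)
  "CC(C(=O)O)C1=CC=CC(=C1)C(=O)C2=CC=CC=C2",       # ketoprofen
  "OC(=O)CC1=CC=CC=C1NC2=C(Cl)C=CC=C2Cl",          # diclofenac
  "CC1=CC=CC(NC2=CC=CC=C2C(=O)O)=C1C",             # mefenamic acid
  "CC1=CC=C(C=C1)C2=CC(=NN2C3=CC=C(C=C3)S(N)(=O)=O)C(F)(F)F", # celecoxib
  "COC1=CC2=C(C=C1)N(C(=O)C3=CC=C(Cl)C=C3)C(C)=C2CC(=O)O"     # indomethacin
)

#' Built-in pool of drug-like SMILES
#'
#' @return Character vector of curated, parseable SMILES strings.
#' @export
smiles_pool <- function() .smiles_pool

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the package's standard desk-scale study conditions:
#' 60 drugs, 40 other entities, 6 relations, 400 triples, 8 interaction
#' types, 600 pairs.
#'
#' @param n_drugs,n_other_entities,n_relations,n_triples number of drug
#'   entities, non-drug entities, relation types and KG triples.
#' @param n_types number of DDI types K.
#' @param n_pairs number of labelled drug pairs.
#' @param task `"multiclass"` (one label per pair) or `"multilabel"`.
#' @param labels_per_pair label-set size per pair (multilabel only).
#' @param n_enzymes,n_targets widths of the binary pharmacology blocks.
#' @param seed integer seed that fully determines every generated object.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 60, n_other_entities = 40, n_relations = 6,
                         n_triples = 400, n_types = 8, n_pairs = 600,
                         task = c("multiclass", "multilabel"),
                         labels_per_pair = 2, n_enzymes = 64, n_targets = 128,
                         seed = 0) {
  task <- match.arg(task)
  for (nm in c("n_drugs", "n_other_entities", "n_relations", "n_triples",
               "n_pairs", "labels_per_pair", "n_enzymes", "n_targets")) {
    stopifnot_count(get(nm), nm)
  }
  stopifnot_count(n_types, "n_types", min = 2L)
  stopifnot_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(n_drugs = n_drugs, n_other_entities = n_other_entities,
                 n_relations = n_relations, n_triples = n_triples,
                 n_types = n_types, n_pairs = n_pairs, task = task,
                 labels_per_pair = labels_per_pair, n_enzymes = n_enzymes,
                 n_targets = n_targets, seed = seed),
            class = "synth_config")
}

#' Draw SMILES for n synthetic drugs
#'
#' Cycles replacement-free through a seeded shuffle of the built-in pool, so
#' no molecule repeats until the pool is exhausted.
#'
#' @param n number of drugs.
#' @param seed integer seed.
#' @return Character vector of n valid SMILES.
#' @export
generate_smiles_pool <- function(n, seed) {
  stopifnot_count(n, "n")
  pool <- smiles_pool()
  with_seed(seed, {
    perm <- sample(pool)
    rep(perm, length.out = n)
  })
}

# Drug / other-entity / relation naming shared by generators and IO.
synth_drug_ids <- function(n) sprintf("D%03d", seq_len(n))

#' Generate a synthetic multi-relation knowledge graph
#'
#' Entities are `n_drugs` drugs plus `n_other_entities` non-drug entities;
#' triples connect them over `n_relations` relations. Every drug is
#' guaranteed at least one triple (no isolated drugs).
#'
#' @param cfg a [synth_config()].
#' @return A [triple_store()].
#' @export
generate_kg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_triples < cfg$n_drugs) {
    stop("n_triples must be >= n_drugs so that no drug is isolated")
  }
  ne <- cfg$n_drugs + cfg$n_other_entities
  entity_vocab <- c(synth_drug_ids(cfg$n_drugs),
                    sprintf("E%03d", seq_len(cfg$n_other_entities)))
  relation_vocab <- sprintf("r%d", seq_len(cfg$n_relations))
  with_seed(cfg$seed + 101L, {
    others <- cfg$n_drugs + seq_len(cfg$n_other_entities)
    # one anchoring triple per drug, random direction
    anchor_other <- sample(others, cfg$n_drugs, replace = TRUE)
    anchor_rel <- sample(cfg$n_relations, cfg$n_drugs, replace = TRUE)
    flip <- stats::runif(cfg$n_drugs) < 0.5
    triples <- data.frame(
      head = ifelse(flip, anchor_other, seq_len(cfg$n_drugs)),
      relation = anchor_rel,
      tail = ifelse(flip, seq_len(cfg$n_drugs), anchor_other))
    key <- function(t) paste(t$head, t$relation, t$tail)
    seen <- key(triples)
    while (nrow(triples) < cfg$n_triples) {
      m <- cfg$n_triples - nrow(triples)
      h <- sample(ne, m, replace = TRUE)
      t <- sample(ne, m, replace = TRUE)
      r <- sample(cfg$n_relations, m, replace = TRUE)
      cand <- data.frame(head = h, relation = r, tail = t)
      cand <- cand[cand$head != cand$tail, , drop = FALSE]
      k <- key(cand)
      ok <- !(k %in% seen) & !duplicated(k)
      cand <- cand[ok, , drop = FALSE]
      seen <- c(seen, k[ok])
      triples <- rbind(triples, cand)
    }
    triple_store(triples, entity_vocab, relation_vocab, seq_len(cfg$n_drugs))
  })
}

#' Planted label rule
#'
#' The synthetic label of a pair is a deterministic function of the two
#' drugs' molecular fingerprints alone: the number of shared on-bits is
#' binned into K classes using fixed breaks derived from the built-in SMILES
#' pool, so a correctly wired model can learn the task above chance through
#' the fingerprint channel while other modalities act as distractors.
#'
#' @param fp_i,fp_j fingerprint vectors (see [compute_fingerprints()]).
#' @param n_types number of classes K.
#' @return Integer class in 1..K.
#' @export
planted_label <- function(fp_i, fp_j, n_types) {
  s <- sum(fp_i > 0 & fp_j > 0)
  br <- planted_breaks(n_types)
  as.integer(findInterval(s, br) + 1L)
}

.planted_cache <- new.env(parent = emptyenv())

#' Fixed class breaks for the planted label rule
#'
#' Quantile breaks of the shared-on-bit count over all unordered pairs of the
#' built-in SMILES pool; a pure function of the package's own constants.
#'
#' @param n_types number of classes K.
#' @return Numeric vector of K-1 strictly increasing interval breaks.
#' @export
planted_breaks <- function(n_types) {
  key <- as.character(n_types)
  if (!is.null(.planted_cache[[key]])) return(.planted_cache[[key]])
  fps <- pool_fingerprints()
  on <- fps > 0
  np <- nrow(on)
  counts <- c()
  ov <- on %*% t(on)
  counts <- ov[upper.tri(ov)]
  br <- unique(stats::quantile(counts, probs = seq_len(n_types - 1) / n_types,
                               type = 1))
  .planted_cache[[key]] <- as.numeric(br) + 0.5
  .planted_cache[[key]]
}

# Fingerprints of the full built-in pool, cached.
pool_fingerprints <- function() {
  if (!is.null(.planted_cache$fps)) return(.planted_cache$fps)
  fps <- t(vapply(smiles_pool(), function(s) compute_fingerprints(s)$values,
                  numeric(2656)))
  .planted_cache$fps <- fps
  fps
}

#' Generate a synthetic DDI table with planted labels
#'
#' Draws `n_pairs` distinct unordered drug pairs and labels each with the
#' deterministic fingerprint rule of [planted_label()]. Multilabel tables get
#' `labels_per_pair` evenly spaced classes starting at the planted class.
#'
#' @param cfg a [synth_config()].
#' @param smiles optional character vector of the drugs' SMILES; defaults to
#'   [generate_smiles_pool()] under the config seed.
#' @return A [ddi_table()] whose drug ids match [generate_kg()].
#' @export
generate_ddi_table <- function(cfg, smiles = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_drugs
  max_pairs <- n * (n - 1) / 2
  if (cfg$n_pairs > max_pairs) {
    stop("n_pairs (", cfg$n_pairs, ") exceeds the ", max_pairs,
         " distinct pairs of ", n, " drugs")
  }
  if (is.null(smiles)) smiles <- generate_smiles_pool(n, cfg$seed)
  ids <- synth_drug_ids(n)
  pool <- smiles_pool()
  pool_fp <- pool_fingerprints()
  fp <- pool_fp[match(smiles, pool), , drop = FALSE]
  sel <- with_seed(cfg$seed + 202L, sample(max_pairs, cfg$n_pairs))
  # enumerate unordered pairs (i < j) in a fixed column-major order
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[sel, 1]; j <- idx[sel, 2]
  K <- cfg$n_types
  base <- vapply(seq_along(i), function(k) {
    planted_label(fp[i[k], ], fp[j[k], ], K)
  }, integer(1))
  type_vocab <- sprintf("T%d", seq_len(K))
  if (cfg$task == "multiclass") {
    labels <- as.list(type_vocab[base])
  } else {
    L <- min(cfg$labels_per_pair, K)
    step <- max(1L, K %/% L)
    labels <- lapply(base, function(b) {
      type_vocab[((b - 1L + (seq_len(L) - 1L) * step) %% K) + 1L]
    })
  }
  ddi_table(ids[i], ids[j], labels, type_vocab)
}

#' Generate sparse binary pharmacology vectors
#'
#' Each drug receives an enzyme and a target annotation vector with
#' approximately 10% bit density.
#'
#' @param cfg a [synth_config()].
#' @return list with binary matrices `enzyme` (n_drugs x n_enzymes) and
#'   `target` (n_drugs x n_targets), rownames = drug ids.
#' @export
generate_pharm_bits <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  ids <- synth_drug_ids(cfg$n_drugs)
  with_seed(cfg$seed + 303L, {
    enz <- matrix(as.integer(stats::runif(cfg$n_drugs * cfg$n_enzymes) < 0.10),
                  nrow = cfg$n_drugs, dimnames = list(ids, NULL))
    tar <- matrix(as.integer(stats::runif(cfg$n_drugs * cfg$n_targets) < 0.10),
                  nrow = cfg$n_drugs, dimnames = list(ids, NULL))
    list(enzyme = enz, target = tar)
  })
}

#' Generate a complete synthetic dataset
#'
#' @param cfg a [synth_config()].
#' @return list with `drugs` (data.frame id, smiles), `kg` ([triple_store()]),
#'   `ddi` ([ddi_table()]), `pharm` (see [generate_pharm_bits()]) and `config`.
#' @export
generate_synthetic_dataset <- function(cfg = synth_config()) {
  smiles <- generate_smiles_pool(cfg$n_drugs, cfg$seed)
  list(drugs = data.frame(id = synth_drug_ids(cfg$n_drugs), smiles = smiles,
                          stringsAsFactors = FALSE),
       kg = generate_kg(cfg),
       ddi = generate_ddi_table(cfg, smiles),
       pharm = generate_pharm_bits(cfg),
       config = cfg)
}
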