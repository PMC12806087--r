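# Shared fixtures, memoized so expensive objects build once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# The package's standard synthetic study conditions.
fixture_config <- function() memo("cfg", synth_config(seed = 0))

fixture_dataset <- function() memo("ds", generate_synthetic_dataset(fixture_config()))

fixture_train_config <- function() memo("tcfg", toy_train_config(seed = 0))

fixture_features <- function() {
  memo("feats", featurize_dataset(fixture_dataset(), fixture_train_config()))
}

# A small deterministic multiclass DDI table for filter tests.
fixture_small_ddi <- function() {
  memo("small_ddi", {
    set.seed(42)
    n <- 12
    ids <- sprintf("D%02d", 1:n)
    pairs <- t(combn(n, 2))
    sel <- sample(nrow(pairs), 40)
    ddi_table(ids[pairs[sel, 1]], ids[pairs[sel, 2]],
              sample(LETTERS[1:5], 40, replace = TRUE))
  })
}

# Random molecular graph stand-in: a connected graph with feature widths
# matching the raw atom/bond layout, for encoder tests that do not need
# chemistry.
random_molgraph <- function(n_atoms, seed = 1) {
  set.seed(seed)
  af <- matrix(runif(n_atoms * 69), n_atoms)
  if (n_atoms == 1) {
    edges <- matrix(integer(0), ncol = 2)
    ef <- matrix(numeric(0), ncol = 6)
  } else {
    spine <- cbind(1:(n_atoms - 1), 2:n_atoms)
    extra <- if (n_atoms > 3) cbind(sample(n_atoms, 2), sample(n_atoms, 2))
             else NULL
    und <- rbind(spine, extra)
    und <- und[und[, 1] != und[, 2], , drop = FALSE]
    und <- unique(t(apply(und, 1, sort)))
    ef1 <- matrix(runif(nrow(und) * 6), nrow(und))
    edges <- cbind(src = c(und[, 1], und[, 2]), dst = c(und[, 2], und[, 1]))
    ef <- rbind(ef1, ef1)
  }
  structure(list(atom_features = af, edges = edges, edge_features = ef,
                 smiles = NA_character_),
            class = "molecular_graph")
}
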