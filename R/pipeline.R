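# End-to-end orchestration: featurize drugs, assemble pair-level modality
# bundles, train under stratified k-fold cross-validation with Adam, the
# step learning-rate schedule and early stopping, and report per-fold and
# aggregate metrics. Ablation switches drop a modality, swap the molecular
# encoder to plain node-pair attention, or replace capsule fusion by
# concatenation.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 1024, Adam with
#' learning rate 0.001 and weight decay 0.0001, rate reduced to 10% every 50
#' epochs, early stopping after 20 stagnant epochs, 5 folds. Architecture
#' widths default to full scale (capsule dim 512, hidden 2048/4096, KG
#' dim 400, molecular-graph dim 512).
#'
#' @param batch_size minibatch size.
#' @param lr initial Adam learning rate.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param lr_step,lr_factor step schedule: multiply by `lr_factor` every
#'   `lr_step` epochs.
#' @param patience early-stopping patience (epochs without improvement of
#'   the monitored validation metric: accuracy for multiclass, AUPR for
#'   multilabel).
#' @param epochs maximum epochs.
#' @param folds number of cross-validation folds.
#' @param val_fraction fraction of each training fold held out for early
#'   stopping.
#' @param seed master seed for folds, initialization and batch order.
#' @param ablation character vector among `"wkg"`, `"wfp"`, `"wmg"`,
#'   `"wph"` (drop a modality), `"wegat"` (node-pair attention encoder),
#'   `"wcapsule"` (concatenation fusion).
#' @param caps_dim,n_mid,n_out,routing_iters capsule-fusion architecture.
#' @param hidden1,hidden2 predictor hidden widths.
#' @param kg_dim TransE/GCN embedding dimension.
#' @param kg_epochs TransE pretraining epochs.
#' @param egat_dim molecular-graph encoder width.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 1024L, lr = 1e-3, weight_decay = 1e-4,
                         lr_step = 50L, lr_factor = 0.1, patience = 20L,
                         epochs = 200L, folds = 5L, val_fraction = 0.1,
                         seed = 0L, ablation = character(0),
                         caps_dim = 512L, n_mid = 4L, n_out = 2L,
                         routing_iters = 3L, hidden1 = 2048L,
                         hidden2 = 4096L, kg_dim = 400L, kg_epochs = 200L,
                         egat_dim = 512L) {
  bad <- setdiff(ablation, c("wkg", "wfp", "wmg", "wph", "wegat", "wcapsule"))
  if (length(bad)) stop("unknown ablation flag(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "train_config")
}

#' Desk-scale training profile
#'
#' The configuration used for the synthetic study conditions: smaller
#' capsule and predictor widths and a shorter epoch budget, so the full
#' cross-validated run converges in minutes on one CPU. All other defaults
#' (optimizer, schedule, folds) are inherited from [train_config()].
#'
#' @param seed master seed.
#' @param ... overrides passed on to [train_config()].
#' @return A `train_config`.
#' @export
toy_train_config <- function(seed = 0L, ...) {
  defaults <- list(caps_dim = 64L, hidden1 = 256L, hidden2 = 256L,
                   epochs = 120L, kg_epochs = 80L, lr = 2e-3, seed = seed)
  override <- list(...)
  do.call(train_config, utils::modifyList(defaults, override))
}

#' Compute all per-drug features of a dataset
#'
#' Fingerprints and molecular graphs from SMILES, the frozen seeded
#' edge-featured attention encoding, pharmacology vectors, and the
#' TransE-pretrained, graph-convolution-refined KG features.
#'
#' @param ds dataset list as from [generate_synthetic_dataset()] (`drugs`,
#'   `kg`, `ddi`, `pharm`).
#' @param cfg a [train_config()].
#' @return list of per-drug feature matrices `fp`, `mg`, `ph`, `kg`
#'   (rownames = drug ids) plus the `egat_params` and `kg_params` used.
#' @export
featurize_dataset <- function(ds, cfg = train_config()) {
  ids <- ds$drugs$id
  smiles <- ds$drugs$smiles
  uniq <- !duplicated(smiles)
  fp_u <- vapply(smiles[uniq], function(s) compute_fingerprints(s)$values,
                 numeric(2656))
  fp <- t(fp_u)[match(smiles, smiles[uniq]), , drop = FALSE]
  rownames(fp) <- ids
  encoder_mode <- if ("wegat" %in% cfg$ablation) "gat" else "egat"
  egat_params <- egat_init(dim = cfg$egat_dim, seed = cfg$seed + 11L)
  mg_u <- vapply(smiles[uniq], function(s) {
    egat_encode(build_molecular_graph(s), egat_params, mode = encoder_mode)
  }, numeric(cfg$egat_dim))
  mg <- t(mg_u)[match(smiles, smiles[uniq]), , drop = FALSE]
  rownames(mg) <- ids
  ph <- cbind(ds$pharm$enzyme, ds$pharm$target)[ids, , drop = FALSE]
  kg_params <- train_transe(ds$kg, d = cfg$kg_dim, epochs = cfg$kg_epochs,
                            seed = cfg$seed + 13L)
  kgf <- kg_entity_features(kg_params, neighbor_index(ds$kg))
  kg <- kgf[ids, , drop = FALSE]
  list(fp = fp, mg = mg, ph = ph, kg = kg,
       egat_params = egat_params, kg_params = kg_params)
}

# Active modalities under the ablation flags, in canonical order.
active_modalities <- function(ablation) {
  mods <- c("kg", "fp", "mg", "ph")
  drop <- c(kg = "wkg", fp = "wfp", mg = "wmg", ph = "wph")
  mods[!(drop[mods] %in% ablation)]
}

# Pair-level modality matrices for the rows of a ddi table.
pair_modality_matrices <- function(features, ddi, modalities) {
  i <- ddi$pairs$drug_i; j <- ddi$pairs$drug_j
  out <- lapply(modalities, function(mod) {
    f <- features[[mod]]
    unname(cbind(f[i, , drop = FALSE], f[j, , drop = FALSE]))
  })
  names(out) <- modalities
  out
}

# Binary label matrix (pairs x types) of a ddi table.
label_matrix <- function(ddi) {
  z <- matrix(0, n_pairs(ddi), length(ddi$type_vocab),
              dimnames = list(NULL, ddi$type_vocab))
  for (r in seq_len(n_pairs(ddi))) {
    z[r, match(ddi$labels[[r]], ddi$type_vocab)] <- 1
  }
  z
}

#' Stratified cross-validation folds over drug pairs
#'
#' Partitions pair indices into k folds, stratified by interaction type
#' (first label for multilabel rows) so per-type proportions match the
#' global ones up to one sample. Types with fewer than k pairs trigger a
#' warning and are spread without stratification guarantees.
#'
#' @param ddi a [ddi_table()].
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of class `fold_split`: integer fold id per pair plus
#'   per-fold index lists.
#' @export
make_folds <- function(ddi, k = 5L, seed = 0L) {
  stopifnot_count(k, "k", min = 2L)
  n <- n_pairs(ddi)
  first_label <- vapply(ddi$labels, `[`, "", 1)
  small <- names(which(table(first_label) < k))
  if (length(small)) {
    warning("type(s) with fewer than ", k, " pairs: ",
            paste(small, collapse = ", "), "; stratification is best-effort")
  }
  assignment <- integer(n)
  with_seed(seed, {
    cursor <- sample.int(k, 1) - 1L
    for (grp in split(seq_len(n), first_label)) {
      grp <- sample(grp)
      assignment[grp] <- ((cursor + seq_along(grp) - 1L) %% k) + 1L
      cursor <- (cursor + length(grp)) %% k
    }
  })
  structure(list(assignment = assignment,
                 folds = split(seq_len(n), assignment), k = k),
            class = "fold_split")
}

# Train the trunk on fixed design matrices. Returns best params and history.
fit_trunk <- function(X_train, z_train, X_val, z_val, cfg, task, n_classes,
                      widths, pos_w = 1) {
  params <- trunk_init(widths, n_classes, caps_dim = cfg$caps_dim,
                       n_mid = cfg$n_mid, n_out = cfg$n_out,
                       routing_iters = cfg$routing_iters,
                       hidden1 = cfg$hidden1, hidden2 = cfg$hidden2,
                       task = task,
                       fusion = if ("wcapsule" %in% cfg$ablation) "concat"
                                else "capsule",
                       seed = cfg$seed + 17L)
  shape <- attr(params, "shape")
  state <- adam_init(params)
  decay_on <- grep("_W|W1_|W2_", names(params), value = TRUE)
  n <- nrow(z_train)
  best_metric <- -Inf; best_params <- params; bad <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_metric = numeric(0))
  monitor <- if (task == "multiclass") "accuracy" else "aupr"
  with_seed(cfg$seed + 19L, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_schedule(epoch, cfg$lr, cfg$lr_step, cfg$lr_factor)
      ord <- sample(n)
      starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- lapply(X_train, function(m) m[rows, , drop = FALSE])
        fw <- trunk_forward(Xb, params)
        lg <- trunk_loss_grad(fw, z_train[rows, , drop = FALSE], task, pos_w)
        if (!is.finite(lg$loss)) stop("training loss is not finite (epoch ",
                                      epoch, ")")
        grads <- trunk_backward(fw, lg$dZ, params)
        shp <- attr(params, "shape")
        st <- adam_step(params, grads, state, lr = lr,
                        weight_decay = cfg$weight_decay, decay_on = decay_on)
        params <- st$params; state <- st$state
        attr(params, "shape") <- shp
        ep_loss <- ep_loss + lg$loss * length(rows)
      }
      fwv <- trunk_forward(X_val, params)
      vm <- if (task == "multiclass") {
        mean(max.col(fwv$Q, ties.method = "first") == max.col(z_val))
      } else {
        binary_aupr(as.numeric(z_val), as.numeric(fwv$Q))
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / n,
                                           val_metric = vm))
      if (vm > best_metric + 1e-9) {
        best_metric <- vm; best_params <- params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
  })
  list(params = best_params, history = history, monitor = monitor,
       best_metric = best_metric)
}

#' Train and evaluate the full model under cross-validation
#'
#' Featurizes the dataset (unless precomputed features are supplied), builds
#' stratified folds, and per fold: holds out a validation slice of the
#' training pairs for early stopping, trains the projection + capsule +
#' predictor trunk with Adam and the step learning-rate schedule, restores
#' the best-validation parameters and evaluates on the test fold.
#'
#' @param ds dataset list (`drugs`, `kg`, `ddi`, `pharm`).
#' @param cfg a [train_config()].
#' @param features optional precomputed [featurize_dataset()] result.
#' @param fold_subset optional integer vector restricting which folds run.
#' @return list of class `ddi_fit`: `per_fold` (list of metric lists),
#'   `summary` (see [report()]), `folds`, `histories`, and the last fold's
#'   trained `params`.
#' @export
train_model <- function(ds, cfg = train_config(), features = NULL,
                        fold_subset = NULL) {
  ddi <- ds$ddi
  task <- if (all(vapply(ddi$labels, length, 1L) == 1L)) "multiclass"
          else "multilabel"
  if (is.null(features)) features <- featurize_dataset(ds, cfg)
  mods <- active_modalities(cfg$ablation)
  X_all <- pair_modality_matrices(features, ddi, mods)
  z_all <- label_matrix(ddi)
  widths <- vapply(X_all, ncol, 0L)
  split_ <- make_folds(ddi, cfg$folds, cfg$seed)
  run_folds <- fold_subset %||% seq_len(cfg$folds)
  per_fold <- list(); histories <- list(); fit <- NULL
  for (f in run_folds) {
    test_idx <- split_$folds[[f]]
    train_idx <- setdiff(seq_len(n_pairs(ddi)), test_idx)
    n_val <- max(1L, floor(length(train_idx) * cfg$val_fraction))
    val_idx <- with_seed(cfg$seed + 23L + f,
                         sample(train_idx, n_val))
    tr_idx <- setdiff(train_idx, val_idx)
    take <- function(idx) lapply(X_all, function(m) m[idx, , drop = FALSE])
    pos_w <- if (task == "multilabel") {
      positive_weights(z_all[tr_idx, , drop = FALSE])
    } else 1
    fit <- fit_trunk(take(tr_idx), z_all[tr_idx, , drop = FALSE],
                     take(val_idx), z_all[val_idx, , drop = FALSE],
                     cfg, task, ncol(z_all), widths, pos_w)
    fw <- trunk_forward(take(test_idx), fit$params)
    m <- if (task == "multiclass") {
      evaluate_predictions(max.col(z_all[test_idx, , drop = FALSE]), fw$Q,
                           task)
    } else {
      evaluate_predictions(z_all[test_idx, , drop = FALSE], fw$Q, task)
    }
    per_fold[[as.character(f)]] <- m
    histories[[as.character(f)]] <- fit$history
  }
  structure(list(per_fold = per_fold, summary = report(per_fold),
                 folds = split_, histories = histories,
                 params = fit$params, task = task, config = cfg,
                 modalities = mods),
            class = "ddi_fit")
}

#' Aggregate per-fold metrics into a summary table
#'
#' @param per_fold list of named metric lists, one per fold.
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
report <- function(per_fold) {
  if (!length(per_fold)) stop("no fold metrics to aggregate")
  metrics <- names(per_fold[[1]])
  vals <- vapply(metrics, function(m)
    vapply(per_fold, function(f) f[[m]], 0), numeric(length(per_fold)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  data.frame(metric = metrics,
             mean = apply(vals, 2, mean),
             sd = apply(vals, 2, stats::sd),
             row.names = NULL)
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat("<ddi_fit> ", x$task, " task, ", length(x$per_fold), " fold(s), ",
      "modalities: ", paste(x$modalities, collapse = "+"), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Save a trained model checkpoint
#'
#' @param fit a `ddi_fit` (or any parameter list).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return The saved object.
#' @export
load_checkpoint <- function(path) readRDS(path)
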