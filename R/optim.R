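# Minimal Adam optimizer over a named list of numeric arrays. Used by the
# TransE pretraining stage and the main training loop.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam update. `grads` must be a named list matching `params` (entries
# may be NULL to skip). Decoupled weight decay is applied to matched entries
# listed in `decay_on`.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0,
                      decay_on = names(params)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && nm %in% decay_on) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Learning rate at a given epoch under the step schedule
#'
#' The rate starts at `lr0` and is reduced to `factor` times its previous
#' value every `step` epochs.
#'
#' @param epoch 1-based epoch number.
#' @param lr0 initial learning rate.
#' @param step epochs between reductions.
#' @param factor multiplicative reduction.
#' @return The learning rate in effect at `epoch`.
#' @export
lr_schedule <- function(epoch, lr0 = 1e-3, step = 50L, factor = 0.1) {
  lr0 * factor^((epoch - 1L) %/% step)
}
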