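# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

leaky_relu <- function(x, slope = 0.2) {
  ifelse(x >= 0, x, slope * x)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

row_norms <- function(m) sqrt(rowSums(m * m))

# L2-normalize rows; zero rows stay zero.
l2_normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

# Glorot/Xavier uniform initialization for a fan_out x fan_in matrix.
glorot <- function(fan_out, fan_in) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_out * fan_in, -a, a), nrow = fan_out)
}

one_hot <- function(value, levels_vec, clamp = FALSE, other = FALSE) {
  v <- numeric(length(levels_vec) + as.integer(other))
  i <- match(value, levels_vec)
  if (is.na(i)) {
    if (other) {
      i <- length(v)
    } else if (clamp) {
      i <- length(levels_vec)
    } else {
      stop("value '", value, "' not in one-hot vocabulary", call. = FALSE)
    }
  }
  v[i] <- 1
  v
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop("'", name, "' must be an integer >= ", min, call. = FALSE)
  }
}
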