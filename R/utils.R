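# small shared numerics

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# softmax backward for a single vector: given y = softmax(x) and dL/dy,
# returns dL/dx = y * (dy - sum(dy * y))
softmax_vec_backward <- function(y, dy) {
  y * (dy - sum(dy * y))
}

leaky_relu <- function(x, slope = 0.01) {
  pos <- x > 0
  x * pos + slope * x * !pos
}

leaky_relu_grad <- function(x, slope = 0.01) {
  pos <- x > 0
  pos + slope * !pos
}

onehot <- function(idx, z) {
  v <- numeric(z)
  v[idx] <- 1
  v
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
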