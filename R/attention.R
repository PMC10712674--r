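#' Initialize per-channel multi-head self-attention parameters
#'
#' Every EEG channel's length-`n` feature vector is split into `h` equal
#' parts; each head applies scaled dot-product attention to its part with its
#' own query/key/value matrices (all `n/h x n/h`), and the concatenated head
#' outputs are mixed by an `n x n` output transform. There are no bias terms.
#' Value and output matrices start near the identity (small Gaussian
#' perturbation), query/key matrices start small, so the module begins close
#' to a mean-pooling map and training is stable from the first epoch.
#'
#' @param n features per channel; must be divisible by `h`.
#' @param h head count.
#' @param sd standard deviation of the initialization noise.
#' @return list of class `"attention_params"` with per-head lists `Wq`, `Wk`,
#'   `Wv` and the output matrix `Wio`.
#' @export
init_attention <- function(n, h = 1, sd = 0.01) {
  if (n %% h != 0) stopf("head count h = %d must divide n = %d", h, n)
  d <- n %/% h
  mk <- function(near_identity) {
    base <- if (near_identity) diag(d) else matrix(0, d, d)
    base + matrix(rnorm(d * d, 0, sd), d, d)
  }
  structure(list(
    h = h, n = n,
    Wq = lapply(seq_len(h), function(i) matrix(rnorm(d * d, 0, sd), d, d)),
    Wk = lapply(seq_len(h), function(i) matrix(rnorm(d * d, 0, sd), d, d)),
    Wv = lapply(seq_len(h), function(i) mk(TRUE)),
    Wio = diag(n) + matrix(rnorm(n * n, 0, sd), n, n)),
    class = "attention_params")
}

#' Single attention head on one channel part
#'
#' Scaled dot-product attention on a length-`d` part `x` of a channel's
#' feature vector: `q = Wq x`, `k = Wk x`, `v = Wv x`,
#' `A = rowwise_softmax(q k' / sqrt(d))`, output `A v`.
#'
#' @param x numeric vector of length `d`.
#' @param wq,wk,wv `d x d` weight matrices.
#' @return list with `out` (length-`d` vector) and the attention matrix `A`
#'   (rows sum to 1).
#' @export
attention_head <- function(x, wq, wk, wv) {
  d <- length(x)
  q <- drop(wq %*% x)
  k <- drop(wk %*% x)
  v <- drop(wv %*% x)
  s <- outer(q, k) / sqrt(d)
  a <- if (d == 1) matrix(1, 1, 1) else softmax_rows(s)
  list(out = drop(a %*% v), A = a)
}

# row-wise softmax of a matrix, vectorized
softmax_rows <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

# forward over a full feature matrix with cache for backprop
attention_forward <- function(x, params, keep_cache = FALSE) {
  n <- nrow(x); m <- ncol(x); h <- params$h
  if (n != params$n) stopf("attention built for n = %d, input has %d rows", params$n, n)
  d <- n %/% h
  u <- matrix(0, n, m)
  cache <- if (keep_cache) vector("list", m)
  for (i in seq_len(m)) {
    xi <- x[, i]
    ui <- numeric(n)
    ch_cache <- if (keep_cache) vector("list", h)
    for (a in seq_len(h)) {
      idx <- ((a - 1) * d + 1):(a * d)
      xp <- xi[idx]
      q <- drop(params$Wq[[a]] %*% xp)
      k <- drop(params$Wk[[a]] %*% xp)
      v <- drop(params$Wv[[a]] %*% xp)
      s <- outer(q, k) / sqrt(d)
      A <- if (d == 1) matrix(1, 1, 1) else softmax_rows(s)
      ui[idx] <- drop(A %*% v)
      if (keep_cache) ch_cache[[a]] <- list(xp = xp, q = q, k = k, v = v, A = A)
    }
    u[, i] <- ui
    if (keep_cache) cache[[i]] <- ch_cache
  }
  out <- params$Wio %*% u
  list(out = out, cache = if (keep_cache) list(u = u, per_channel = cache))
}

# backward through attention_forward; returns grads for all matrices and dX
attention_backward <- function(dout, x, params, cache) {
  n <- nrow(x); m <- ncol(x); h <- params$h
  d <- n %/% h
  dWio <- dout %*% t(cache$u)
  du <- crossprod(params$Wio, dout)
  dx <- matrix(0, n, m)
  dWq <- lapply(seq_len(h), function(a) matrix(0, d, d))
  dWk <- lapply(seq_len(h), function(a) matrix(0, d, d))
  dWv <- lapply(seq_len(h), function(a) matrix(0, d, d))
  for (i in seq_len(m)) {
    for (a in seq_len(h)) {
      idx <- ((a - 1) * d + 1):(a * d)
      cc <- cache$per_channel[[i]][[a]]
      dui <- du[idx, i]
      # out_p = A v
      dA <- outer(dui, cc$v)
      dv <- drop(crossprod(cc$A, dui))
      if (d == 1) {
        dS <- matrix(0, 1, 1)
      } else {
        # row-wise softmax backward: dS_r = A_r * (dA_r - <dA_r, A_r>)
        dS <- cc$A * (dA - rowSums(dA * cc$A))
      }
      dq <- drop(dS %*% cc$k) / sqrt(d)
      dk <- drop(crossprod(dS, cc$q)) / sqrt(d)
      dWq[[a]] <- dWq[[a]] + outer(dq, cc$xp)
      dWk[[a]] <- dWk[[a]] + outer(dk, cc$xp)
      dWv[[a]] <- dWv[[a]] + outer(dv, cc$xp)
      dx[idx, i] <- drop(crossprod(params$Wq[[a]], dq)) +
        drop(crossprod(params$Wk[[a]], dk)) +
        drop(crossprod(params$Wv[[a]], dv))
    }
  }
  list(dWq = dWq, dWk = dWk, dWv = dWv, dWio = dWio, dx = dx)
}

#' Apply per-channel multi-head self-attention to a feature matrix
#'
#' Channels are processed independently (column `i` of the output depends only
#' on column `i` of the input), so a channel permutation of the input permutes
#' the output identically.
#'
#' @param x numeric `n x m` feature matrix.
#' @param params an [init_attention()] parameter set.
#' @return re-weighted `n x m` matrix.
#' @export
apply_attention <- function(x, params) {
  attention_forward(x, params)$out
}
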