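#' Initialize the classification head
#'
#' The head takes the fractal representation (`n x m`), pushes it through a
#' readout soma (`n1` spiking neurons), raises the dimension with a linear
#' layer (`2*n1`), applies a leaky ReLU, projects to `z` class logits per
#' channel, pools the per-channel logits with learnable channel weights, and
#' applies softmax.
#'
#' @param n fractal output rows per channel.
#' @param m channel count.
#' @param z class count (>= 2).
#' @param n1 readout soma size; defaults to `n`.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @return list of class `"head_params"` with `W_readout` (`n1 x n`), `L1`
#'   (`2*n1 x n1`), `b1`, `L2` (`z x 2*n1`), `b2`, `w_pool` (length `m`) and
#'   the scalar `leaky_slope`.
#' @export
init_head <- function(n, m, z, n1 = n, leaky_slope = 0.01) {
  if (z < 2) stopf("need at least 2 classes")
  list(
    n1 = n1, z = z, leaky_slope = leaky_slope,
    W_readout = matrix(rnorm(n1 * n, 0, 1 / sqrt(n)), n1, n),
    L1 = matrix(rnorm(2 * n1 * n1, 0, sqrt(2 / n1)), 2 * n1, n1),
    b1 = numeric(2 * n1),
    L2 = matrix(rnorm(z * 2 * n1, 0, sqrt(1 / n1)), z, 2 * n1),
    b2 = numeric(z),
    w_pool = rep(1 / m, m))
}

#' Classification head forward pass
#'
#' @param f_out fractal block output, `n x m`.
#' @param head an [init_head()] parameter set.
#' @param cfg the shared [neuron_config()] (the readout soma reuses the
#'   fractal block's constants).
#' @param keep_cache keep intermediates for backpropagation.
#' @return list with `probs` (length-`z`, sums to 1), `logits`, the binary
#'   readout `spikes`, and optionally a `cache`.
#' @export
head_forward <- function(f_out, head, cfg, keep_cache = FALSE) {
  so <- soma_forward(f_out, head$W_readout, cfg, keep_cache = keep_cache)
  y_o <- so$spikes                             # n1 x m, strictly binary
  y_o1 <- head$L1 %*% y_o + head$b1            # 2 n1 x m
  hmat <- leaky_relu(y_o1, head$leaky_slope)
  y_o2 <- head$L2 %*% hmat + head$b2           # z x m
  y_p <- drop(y_o2 %*% head$w_pool)            # z
  probs <- softmax(y_p)
  res <- list(probs = probs, logits = y_p, spikes = y_o)
  if (keep_cache)
    res$cache <- list(soma = so$cache, y_o = y_o, y_o1 = y_o1, hmat = hmat,
                      y_o2 = y_o2)
  res
}

# backward through head_forward given gradient w.r.t. the logits y_p
head_backward <- function(dlogits, f_out, head, cfg, cache) {
  m <- ncol(f_out)
  dy_o2 <- outer(dlogits, head$w_pool)                 # z x m
  dw_pool <- drop(crossprod(cache$y_o2, dlogits))      # m
  dL2 <- dy_o2 %*% t(cache$hmat)
  db2 <- rowSums(dy_o2)
  dh <- crossprod(head$L2, dy_o2)
  dy_o1 <- dh * leaky_relu_grad(cache$y_o1, head$leaky_slope)
  dL1 <- dy_o1 %*% t(cache$y_o)
  db1 <- rowSums(dy_o1)
  dy_o <- crossprod(head$L1, dy_o1)
  sb <- soma_backward(dy_o, cache$soma, cfg)
  list(dW_readout = sb$dw, dL1 = dL1, db1 = db1, dL2 = dL2, db2 = db2,
       dw_pool = dw_pool, df_out = sb$df)
}

#' Initialize a full fractal-SNN model parameter set
#'
#' @param n features per channel, `m` channels, `z` classes.
#' @param m,z see above.
#' @param order fractal order.
#' @param heads attention head count (must divide `n`); `0` disables the
#'   attention module.
#' @param cfg a [neuron_config()].
#' @param n1 readout soma size (default `n`).
#' @param leaky_slope leaky ReLU negative slope.
#' @return list of class `"fsnn_params"` with `attention` (or `NULL`),
#'   `spec` (the fractal structure), `fractal` (soma weights) and `head`.
#' @export
init_model <- function(n, m, z, order = 3, heads = 1, cfg = neuron_config(),
                       n1 = n, leaky_slope = 0.01) {
  spec <- build_fractal(order, n)
  list(
    attention = if (heads > 0) init_attention(n, heads) else NULL,
    spec = spec,
    fractal = init_fractal_params(spec),
    head = init_head(n, m, z, n1 = n1, leaky_slope = leaky_slope),
    n = n, m = m, z = z, cfg = cfg)
}

#' Full scheme forward pass
#'
#' attention -> fractal block -> classification head. Deterministic when
#' `training = FALSE` (no drop-path randomness at test time).
#'
#' @param x `n x m` feature matrix.
#' @param model an [init_model()] parameter set.
#' @param drop a [drop_config()].
#' @param training logical.
#' @param forced_masks optional forced drop masks (see [column_masks()]).
#' @param keep_cache keep intermediates for backpropagation.
#' @return list with `probs`, `logits` and optionally `cache`.
#' @export
scheme_forward <- function(x, model, drop = drop_config(0), training = FALSE,
                           forced_masks = NULL, keep_cache = FALSE) {
  if (nrow(x) != model$n || ncol(x) != model$m)
    stopf("scheme_forward: input is %dx%d, model expects %dx%d",
          nrow(x), ncol(x), model$n, model$m)
  if (!is.null(model$attention)) {
    att <- attention_forward(x, model$attention, keep_cache = keep_cache)
    xa <- att$out
  } else {
    att <- NULL
    xa <- x
  }
  fr <- fractal_forward(xa, model$spec, model$fractal, model$cfg, drop,
                        training, forced_masks, keep_cache = keep_cache)
  hd <- head_forward(fr$out, model$head, model$cfg, keep_cache = keep_cache)
  res <- list(probs = hd$probs, logits = hd$logits)
  if (keep_cache)
    res$cache <- list(att = att, xa = xa, fr = fr, f_out = fr$out, head = hd$cache)
  res
}

# Backward through the full scheme from a gradient on the logits.
# Returns a list of gradients shaped like the model parameters, plus dx.
scheme_backward <- function(dlogits, x, model, cache) {
  hb <- head_backward(dlogits, cache$f_out, model$head, model$cfg, cache$head)
  acc <- new.env()
  acc$soma <- lapply(model$fractal$soma, function(w) w * 0)
  dxa <- fractal_node_backward(model$spec$tree, hb$df_out, cache$fr$cache,
                               model$fractal, model$cfg, acc)
  grads <- list(
    head = list(dW_readout = hb$dW_readout, dL1 = hb$dL1, db1 = hb$db1,
                dL2 = hb$dL2, db2 = hb$db2, dw_pool = hb$dw_pool),
    fractal = list(soma = acc$soma))
  if (!is.null(model$attention)) {
    ab <- attention_backward(dxa, x, model$attention, cache$att$cache)
    grads$attention <- ab[c("dWq", "dWk", "dWv", "dWio")]
    grads$dx <- ab$dx
  } else {
    grads$dx <- dxa
  }
  grads
}

#' Save / load a fitted model
#'
#' A checkpoint is a single RDS file holding all weight matrices and the full
#' configuration; the round trip is bit-exact.
#'
#' @param object a fitted [fsnn()] model (or any model parameter list).
#' @param path file path.
#' @return `load_model()` returns the saved object.
#' @export
save_model <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
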