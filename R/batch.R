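# Batched (n x m x B array) forward/backward internals. The training loop
# runs the whole full-trial batch through these in single BLAS calls; the
# exported single-sample operations in neuron.R / attention.R / head.R are
# the reference implementations of the same arithmetic.

slice2 <- function(x, i) {
  d <- dim(x)
  matrix(x[, i, ], d[1], d[3])
}

axon_fwd_b <- function(x, cfg) {
  d <- dim(x)
  f <- array(0, d)
  f1 <- matrix(0, d[1], d[3])
  f2 <- f1
  for (i in seq_len(d[2])) {
    fi <- cfg$alpha1 * f1 + cfg$alpha2 * f2 + cfg$beta * slice2(x, i)
    f[, i, ] <- fi
    f2 <- f1
    f1 <- fi
  }
  f
}

axon_bwd_b <- function(dout, cfg) {
  ridx <- rev(seq_len(dim(dout)[2]))
  axon_fwd_b(dout[, ridx, , drop = FALSE], cfg)[, ridx, , drop = FALSE]
}

soma_fwd_b <- function(f, w, cfg, keep_cache = FALSE) {
  d <- dim(f)
  n_out <- nrow(w)
  wf <- w %*% matrix(f, d[1], d[2] * d[3])
  dim(wf) <- c(n_out, d[2], d[3])
  out <- array(0, c(n_out, d[2], d[3]))
  vtr <- array(0, c(n_out, d[2], d[3]))
  r <- matrix(0, n_out, d[3])
  for (i in seq_len(d[2])) {
    rt <- cfg$decay_r * r
    vi <- -cfg$lambda * rt + slice2(wf, i)
    yi <- (vi > cfg$v_thre) * 1
    r <- rt + cfg$v_rest * yi
    out[, i, ] <- yi
    vtr[, i, ] <- vi
  }
  res <- list(spikes = out)
  if (keep_cache) res$cache <- list(f = f, w = w, v = vtr)
  res
}

soma_bwd_b <- function(dout, cache, cfg) {
  f <- cache$f; w <- cache$w; v <- cache$v
  d <- dim(dout)
  gv_all <- array(0, d)
  gr <- matrix(0, d[1], d[3])
  for (i in rev(seq_len(d[2]))) {
    gy <- slice2(dout, i) + cfg$v_rest * gr
    gv <- gy * spike_surrogate_grad(slice2(v, i) - cfg$v_thre,
                                    cfg$surrogate_width)
    g_rtil <- -cfg$lambda * gv + gr
    gr <- cfg$decay_r * g_rtil
    gv_all[, i, ] <- gv
  }
  gv_flat <- matrix(gv_all, d[1], d[2] * d[3])
  f_flat <- matrix(f, dim(f)[1], d[2] * d[3])
  df <- crossprod(w, gv_flat)
  dim(df) <- dim(f)
  list(dw = tcrossprod(gv_flat, f_flat), df = df)
}

# The per-sample attention matrices of one (channel, head) pair are packed
# into a single (d*B) x d block-row matrix (block b = sample b), so the
# row-wise softmax and its backward run as single vectorized calls.
attention_fwd_b <- function(x, params, keep_cache = FALSE) {
  d <- dim(x)
  n <- d[1]; m <- d[2]; B <- d[3]
  h <- params$h
  dd <- n %/% h
  bi <- rep(seq_len(B), each = dd)  # block-row -> sample index
  u <- array(0, d)
  cache <- if (keep_cache) vector("list", m)
  for (i in seq_len(m)) {
    ch_cache <- if (keep_cache) vector("list", h)
    for (a in seq_len(h)) {
      idx <- ((a - 1) * dd + 1):(a * dd)
      xp <- matrix(x[idx, i, ], dd, B)
      q <- params$Wq[[a]] %*% xp
      k <- params$Wk[[a]] %*% xp
      v <- params$Wv[[a]] %*% xp
      vbig <- t(v)[bi, , drop = FALSE]
      if (dd == 1) {
        A <- matrix(1, B, 1)
        kbig <- NULL
      } else {
        kbig <- t(k)[bi, , drop = FALSE]
        A <- softmax_rows((as.vector(q) / sqrt(dd)) * kbig)
      }
      u[idx, i, ] <- rowSums(A * vbig)
      if (keep_cache) ch_cache[[a]] <- list(xp = xp, q = q, k = k, v = v,
                                            A = A, vbig = vbig, kbig = kbig)
    }
    if (keep_cache) cache[[i]] <- ch_cache
  }
  out <- params$Wio %*% matrix(u, n, m * B)
  dim(out) <- d
  list(out = out, cache = if (keep_cache) list(u = u, per_channel = cache))
}

attention_bwd_b <- function(dout, x, params, cache) {
  d <- dim(x)
  n <- d[1]; m <- d[2]; B <- d[3]
  h <- params$h
  dd <- n %/% h
  bi <- rep(seq_len(B), each = dd)
  dout_flat <- matrix(dout, n, m * B)
  u_flat <- matrix(cache$u, n, m * B)
  dWio <- tcrossprod(dout_flat, u_flat)
  du <- crossprod(params$Wio, dout_flat)
  dim(du) <- d
  dx <- array(0, d)
  dWq <- lapply(seq_len(h), function(a) matrix(0, dd, dd))
  dWk <- dWq; dWv <- dWq
  for (i in seq_len(m)) {
    for (a in seq_len(h)) {
      idx <- ((a - 1) * dd + 1):(a * dd)
      cc <- cache$per_channel[[i]][[a]]
      duvec <- as.vector(matrix(du[idx, i, ], dd, B))  # length d*B
      dA <- duvec * cc$vbig
      DV <- t(rowsum(cc$A * duvec, bi))                # dd x B
      if (dd > 1) {
        dS <- cc$A * (dA - rowSums(dA * cc$A))
        DQ <- matrix(rowSums(dS * cc$kbig), dd, B) / sqrt(dd)
        DK <- t(rowsum(dS * as.vector(cc$q), bi)) / sqrt(dd)
      } else {
        DQ <- matrix(0, dd, B)
        DK <- DQ
      }
      dWq[[a]] <- dWq[[a]] + tcrossprod(DQ, cc$xp)
      dWk[[a]] <- dWk[[a]] + tcrossprod(DK, cc$xp)
      dWv[[a]] <- dWv[[a]] + tcrossprod(DV, cc$xp)
      dx[idx, i, ] <- crossprod(params$Wq[[a]], DQ) +
        crossprod(params$Wk[[a]], DK) + crossprod(params$Wv[[a]], DV)
    }
  }
  list(dWq = dWq, dWk = dWk, dWv = dWv, dWio = dWio, dx = dx)
}

fractal_node_fwd_b <- function(node, x, params, cfg, drop, training,
                               forced_masks, keep_cache) {
  switch(node$type,
    axon = list(out = axon_fwd_b(x, cfg),
                cache = if (keep_cache) list(type = "axon")),
    soma = {
      sf <- soma_fwd_b(x, params$soma[[node$id]], cfg, keep_cache = keep_cache)
      list(out = sf$spikes,
           cache = if (keep_cache) list(type = "soma", id = node$id,
                                        soma = sf$cache))
    },
    seq = {
      caches <- vector("list", length(node$ops))
      cur <- x
      for (j in seq_along(node$ops)) {
        r <- fractal_node_fwd_b(node$ops[[j]], cur, params, cfg, drop,
                                training, forced_masks, keep_cache)
        cur <- r$out
        caches[[j]] <- r$cache
      }
      list(out = cur, cache = if (keep_cache) list(type = "seq", ops = caches))
    },
    sum = {
      rl <- fractal_node_fwd_b(node$branches$long, x, params, cfg, drop,
                               training, forced_masks, keep_cache)
      rs <- fractal_node_fwd_b(node$branches$short, x, params, cfg, drop,
                               training, forced_masks, keep_cache)
      fm <- if (!is.null(forced_masks)) forced_masks[[as.character(node$id)]]
      B <- dim(x)[3]
      # one independent mask pair per sample (masks are per forward pass of
      # each sample, exactly as in the single-sample evaluator)
      if (!is.null(fm)) {
        kl <- rep(fm[1], B); ks <- rep(fm[2], B)
        scale <- if (training && drop$mode == "inverted" && drop$p > 0)
          1 / (1 - drop$p) else 1
      } else if (!training || drop$mode == "none" || drop$p == 0) {
        kl <- rep(1, B); ks <- rep(1, B); scale <- 1
      } else {
        kl <- rbinom(B, 1, 1 - drop$p)
        ks <- rbinom(B, 1, 1 - drop$p)
        if (drop$redraw) {
          bad <- kl == 0 & ks == 0
          while (any(bad)) {
            kl[bad] <- rbinom(sum(bad), 1, 1 - drop$p)
            ks[bad] <- rbinom(sum(bad), 1, 1 - drop$p)
            bad <- kl == 0 & ks == 0
          }
        }
        scale <- if (drop$mode == "inverted") 1 / (1 - drop$p) else 1
      }
      nm <- prod(dim(rl$out)[1:2])
      out <- rl$out * rep(kl * scale, each = nm) +
        rs$out * rep(ks * scale, each = nm)
      list(out = out,
           cache = if (keep_cache) list(type = "sum", id = node$id,
                                        long = rl$cache, short = rs$cache,
                                        kl = kl, ks = ks, scale = scale,
                                        nm = nm))
    })
}

fractal_node_bwd_b <- function(node, dout, cache, params, cfg, acc) {
  switch(node$type,
    axon = axon_bwd_b(dout, cfg),
    soma = {
      sb <- soma_bwd_b(dout, cache$soma, cfg)
      acc$soma[[cache$id]] <- acc$soma[[cache$id]] + sb$dw
      sb$df
    },
    seq = {
      cur <- dout
      for (j in rev(seq_along(node$ops)))
        cur <- fractal_node_bwd_b(node$ops[[j]], cur, cache$ops[[j]],
                                  params, cfg, acc)
      cur
    },
    sum = {
      dl <- dout * rep(cache$kl * cache$scale, each = cache$nm)
      ds <- dout * rep(cache$ks * cache$scale, each = cache$nm)
      fractal_node_bwd_b(node$branches$long, dl, cache$long, params, cfg, acc) +
        fractal_node_bwd_b(node$branches$short, ds, cache$short, params, cfg, acc)
    })
}

head_fwd_b <- function(f, head, cfg, keep_cache = FALSE) {
  d <- dim(f)
  m <- d[2]; B <- d[3]
  so <- soma_fwd_b(f, head$W_readout, cfg, keep_cache = keep_cache)
  n1 <- nrow(head$W_readout)
  yo_flat <- matrix(so$spikes, n1, m * B)
  y1 <- head$L1 %*% yo_flat + head$b1
  hm <- leaky_relu(y1, head$leaky_slope)
  y2 <- head$L2 %*% hm + head$b2
  z <- nrow(head$L2)
  y2a <- y2
  dim(y2a) <- c(z, m, B)
  logits <- matrix(0, z, B)
  probs <- matrix(0, z, B)
  for (b in seq_len(B)) {
    logits[, b] <- matrix(y2a[, , b], z, m) %*% head$w_pool
    probs[, b] <- softmax(logits[, b])
  }
  res <- list(probs = probs, logits = logits)
  if (keep_cache)
    res$cache <- list(soma = so$cache, yo_flat = yo_flat, y1 = y1, hm = hm,
                      y2a = y2a, dims = d)
  res
}

head_bwd_b <- function(dlogits, head, cfg, cache) {
  d <- cache$dims
  m <- d[2]; B <- d[3]
  z <- nrow(head$L2)
  dy2 <- array(0, c(z, m, B))
  dw_pool <- numeric(m)
  for (b in seq_len(B)) {
    dy2[, , b] <- outer(dlogits[, b], head$w_pool)
    dw_pool <- dw_pool + drop(crossprod(matrix(cache$y2a[, , b], z, m),
                                        dlogits[, b]))
  }
  dy2_flat <- matrix(dy2, z, m * B)
  dL2 <- tcrossprod(dy2_flat, cache$hm)
  db2 <- rowSums(dy2_flat)
  dh <- crossprod(head$L2, dy2_flat)
  dy1 <- dh * leaky_relu_grad(cache$y1, head$leaky_slope)
  dL1 <- tcrossprod(dy1, cache$yo_flat)
  db1 <- rowSums(dy1)
  dyo <- crossprod(head$L1, dy1)
  dim(dyo) <- c(nrow(head$W_readout), m, B)
  sb <- soma_bwd_b(dyo, cache$soma, cfg)
  list(dW_readout = sb$dw, dL1 = dL1, db1 = db1, dL2 = dL2, db2 = db2,
       dw_pool = dw_pool, df_out = sb$df)
}

scheme_fwd_b <- function(x, model, drop = drop_config(0), training = FALSE,
                         forced_masks = NULL, keep_cache = FALSE) {
  if (!is.null(model$attention)) {
    att <- attention_fwd_b(x, model$attention, keep_cache = keep_cache)
    xa <- att$out
  } else {
    att <- NULL
    xa <- x
  }
  fr <- fractal_node_fwd_b(model$spec$tree, xa, model$fractal, model$cfg,
                           drop, training, forced_masks, keep_cache)
  hd <- head_fwd_b(fr$out, model$head, model$cfg, keep_cache = keep_cache)
  res <- list(probs = hd$probs, logits = hd$logits)
  if (keep_cache)
    res$cache <- list(att = att, fr = fr, head = hd$cache)
  res
}

# gradients are summed over the batch
scheme_bwd_b <- function(dlogits, x, model, cache) {
  hb <- head_bwd_b(dlogits, model$head, model$cfg, cache$head)
  acc <- new.env()
  acc$soma <- lapply(model$fractal$soma, function(w) w * 0)
  dxa <- fractal_node_bwd_b(model$spec$tree, hb$df_out, cache$fr$cache,
                            model$fractal, model$cfg, acc)
  grads <- list(
    head = list(dW_readout = hb$dW_readout, dL1 = hb$dL1, db1 = hb$db1,
                dL2 = hb$dL2, db2 = hb$db2, dw_pool = hb$dw_pool),
    fractal = list(soma = acc$soma))
  if (!is.null(model$attention)) {
    ab <- attention_bwd_b(dxa, x, model$attention, cache$att$cache)
    grads$attention <- ab[c("dWq", "dWk", "dWv", "dWio")]
    grads$dx <- ab$dx
  } else {
    grads$dx <- dxa
  }
  grads
}
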