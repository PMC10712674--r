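# ---- parameter flattening (shared by the Adam loop) ----

flat_params <- function(model) {
  out <- list()
  if (!is.null(model$attention)) {
    for (a in seq_len(model$attention$h)) {
      out[[paste0("att_Wq_", a)]] <- model$attention$Wq[[a]]
      out[[paste0("att_Wk_", a)]] <- model$attention$Wk[[a]]
      out[[paste0("att_Wv_", a)]] <- model$attention$Wv[[a]]
    }
    out[["att_Wio"]] <- model$attention$Wio
  }
  for (i in seq_along(model$fractal$soma))
    out[[paste0("soma_", i)]] <- model$fractal$soma[[i]]
  out$W_readout <- model$head$W_readout
  out$L1 <- model$head$L1; out$b1 <- model$head$b1
  out$L2 <- model$head$L2; out$b2 <- model$head$b2
  out$w_pool <- model$head$w_pool
  out
}

unflatten_params <- function(model, flat) {
  if (!is.null(model$attention)) {
    for (a in seq_len(model$attention$h)) {
      model$attention$Wq[[a]] <- flat[[paste0("att_Wq_", a)]]
      model$attention$Wk[[a]] <- flat[[paste0("att_Wk_", a)]]
      model$attention$Wv[[a]] <- flat[[paste0("att_Wv_", a)]]
    }
    model$attention$Wio <- flat[["att_Wio"]]
  }
  for (i in seq_along(model$fractal$soma))
    model$fractal$soma[[i]] <- flat[[paste0("soma_", i)]]
  model$head$W_readout <- flat$W_readout
  model$head$L1 <- flat$L1; model$head$b1 <- flat$b1
  model$head$L2 <- flat$L2; model$head$b2 <- flat$b2
  model$head$w_pool <- flat$w_pool
  model
}

flat_grads <- function(grads, model) {
  out <- list()
  if (!is.null(model$attention)) {
    for (a in seq_len(model$attention$h)) {
      out[[paste0("att_Wq_", a)]] <- grads$attention$dWq[[a]]
      out[[paste0("att_Wk_", a)]] <- grads$attention$dWk[[a]]
      out[[paste0("att_Wv_", a)]] <- grads$attention$dWv[[a]]
    }
    out[["att_Wio"]] <- grads$attention$dWio
  }
  for (i in seq_along(model$fractal$soma))
    out[[paste0("soma_", i)]] <- grads$fractal$soma[[i]]
  out$W_readout <- grads$head$dW_readout
  out$L1 <- grads$head$dL1; out$b1 <- grads$head$db1
  out$L2 <- grads$head$dL2; out$b2 <- grads$head$db2
  out$w_pool <- grads$head$dw_pool
  out
}

# ---- fitting ----

#' Fit a fractal spiking neural network classifier
#'
#' Trains the full scheme (per-channel multi-head self-attention, fractal SNN
#' block, spiking readout and linear classification head) on a set of feature
#' matrices by full-batch Adam on the cross-entropy loss, backpropagating
#' through the spike nonlinearity with a triangular surrogate gradient and
#' regularizing with inverted drop-path at the fractal sum layers.
#'
#' @param x list of `n x m` feature matrices (see [extract_features()]), all
#'   with identical dimensions.
#' @param y class labels, one per matrix (factor or coercible).
#' @param order fractal order `c` of the block (default 3).
#' @param heads attention heads (must divide `n`; `0` disables attention).
#' @param drop a [drop_config()]; default inverted drop-path at rate 0.15.
#' @param neuron a [neuron_config()] shared by all spiking layers.
#' @param epochs,lr,weight_decay Adam training schedule. Weight decay is
#'   applied to weight matrices, not biases or pooling weights.
#' @param n1 readout soma size (default `n`).
#' @param leaky_slope leaky ReLU negative slope in the head.
#' @param seed integer for reproducible initialization and drop-path draws;
#'   the caller's RNG state is restored afterwards.
#' @param verbose print the loss every 10 epochs.
#' @return An object of class `"fsnn"`: the trained model parameters,
#'   `classes`, the per-epoch training `loss` curve, training-set fitted
#'   probabilities, and the training configuration.
#' @seealso [predict.fsnn()], [fsnn_cv()], [saliency()]
#' @export
fsnn <- function(x, y, order = 3, heads = 1,
                 drop = drop_config(0.15, "inverted"),
                 neuron = neuron_config(),
                 epochs = 60, lr = 1e-3, weight_decay = 1e-4,
                 n1 = NULL, leaky_slope = 0.01, seed = NULL,
                 verbose = FALSE) {
  if (is.matrix(x)) x <- list(x)
  if (length(x) != length(y))
    stopf("%d samples but %d labels", length(x), length(y))
  if (length(x) == 0) stopf("empty training set")
  y <- as.factor(y)
  classes <- levels(y)
  yi <- as.integer(y)
  n <- nrow(x[[1]]); m <- ncol(x[[1]])
  for (s in x) if (nrow(s) != n || ncol(s) != m)
    stopf("all feature matrices must share the same n x m shape")
  if (is.null(n1)) n1 <- n
  z <- length(classes)
  if (z < 2) stopf("need at least two classes")

  with_seed(seed, {
    model <- init_model(n, m, z, order = order, heads = heads, cfg = neuron,
                        n1 = n1, leaky_slope = leaky_slope)
    theta <- flat_params(model)
    mom <- lapply(theta, function(p) p * 0)
    vel <- lapply(theta, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    decay_skip <- c("b1", "b2", "w_pool")
    losses <- numeric(epochs)
    step <- 0
    B <- length(x)
    xarr <- array(unlist(x), c(n, m, B))
    target <- matrix(0, z, B)
    target[cbind(yi, seq_len(B))] <- 1
    for (ep in seq_len(epochs)) {
      fw <- scheme_fwd_b(xarr, model, drop = drop, training = TRUE,
                         keep_cache = TRUE)
      p_true <- pmax(fw$probs[cbind(yi, seq_len(B))], 1e-12)
      loss <- -mean(log(p_true))
      dlogits <- fw$probs - target
      gacc <- flat_grads(scheme_bwd_b(dlogits, xarr, model, fw$cache), model)
      if (!is.finite(loss))
        stopf("training diverged at epoch %d (non-finite loss)", ep)
      losses[ep] <- loss
      step <- step + 1
      for (nm in names(theta)) {
        g <- gacc[[nm]] / length(x)
        if (!(nm %in% decay_skip)) g <- g + weight_decay * theta[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      model <- unflatten_params(model, theta)
      if (verbose && ep %% 10 == 0)
        message(sprintf("epoch %3d  loss %.4f", ep, loss))
    }
    fitted_probs <- t(scheme_fwd_b(xarr, model, training = FALSE)$probs)
    colnames(fitted_probs) <- classes
    structure(list(
      model = model, classes = classes, y = y, loss = losses,
      fitted_probs = fitted_probs, drop = drop, neuron = neuron,
      config = list(order = order, heads = heads, epochs = epochs, lr = lr,
                    weight_decay = weight_decay, n1 = n1,
                    leaky_slope = leaky_slope, seed = seed),
      dims = c(n = n, m = m, z = z),
      call = match.call()), class = "fsnn")
  })
}

#' Predict method for fractal-SNN fits
#'
#' @param object a fitted [fsnn()] model.
#' @param newdata a feature matrix or list of feature matrices.
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @param ... unused.
#' @return probability matrix (samples x classes) or factor of labels.
#' @export
predict.fsnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  n <- object$dims["n"]; m <- object$dims["m"]
  xarr <- array(unlist(newdata), c(n, m, length(newdata)))
  probs <- t(scheme_fwd_b(xarr, object$model, training = FALSE)$probs)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

#' @export
print.fsnn <- function(x, ...) {
  cat("Fractal spiking neural network classifier\n")
  cat(sprintf("  F_%d block, %d attention head(s), %d features x %d channels, %d classes\n",
              x$config$order, x$config$heads, x$dims["n"], x$dims["m"], x$dims["z"]))
  cat(sprintf("  drop-path: %s (p = %g); %d epochs, final loss %.4f\n",
              x$drop$mode, x$drop$p, length(x$loss), tail(x$loss, 1)))
  invisible(x)
}

#' @export
summary.fsnn <- function(object, ...) {
  pred <- factor(object$classes[max.col(object$fitted_probs)],
                 levels = object$classes)
  acc <- mean(pred == object$y)
  n_par <- sum(vapply(flat_params(object$model), length, integer(1)))
  out <- list(fit = object, train_accuracy = acc, n_parameters = n_par)
  class(out) <- "summary.fsnn"
  out
}

#' @export
print.summary.fsnn <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d trainable parameters; training accuracy %.3f\n",
              x$n_parameters, x$train_accuracy))
  invisible(x)
}

#' @export
coef.fsnn <- function(object, ...) flat_params(object$model)

#' @export
fitted.fsnn <- function(object, ...) object$fitted_probs

#' @export
residuals.fsnn <- function(object, ...) {
  ind <- matrix(0, nrow(object$fitted_probs), ncol(object$fitted_probs))
  ind[cbind(seq_along(object$y), as.integer(object$y))] <- 1
  ind - object$fitted_probs
}

#' @export
plot.fsnn <- function(x, ...) {
  plot(seq_along(x$loss), x$loss, type = "l", xlab = "epoch",
       ylab = "training cross-entropy", main = "Fractal-SNN training loss", ...)
  invisible(x)
}

#' @export
simulate.fsnn <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    p <- object$fitted_probs
    out <- replicate(nsim, {
      factor(apply(p, 1, function(pr) sample(object$classes, 1, prob = pr)),
             levels = object$classes)
    }, simplify = FALSE)
    if (nsim == 1) out[[1]] else out
  })
}
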