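#' Spiking-neuron hyperparameters
#'
#' Bundles the fixed hyperparameters of the spiking primitives and derives the
#' coefficients of the second-order IIR synapse filter. The recurrence of both
#' the synapse (`Axon`) and reset (`Soma`) filters runs along the EEG *channel*
#' axis: channels play the role of sequence steps, feature rows index
#' synapses/neurons.
#'
#' The synapse filter is
#' \deqn{f[i] = \alpha_1 f[i-1] + \alpha_2 f[i-2] + \beta x[i]}
#' with \eqn{\alpha_1 = e^{-1/\tau_m} + e^{-1/\tau_s}},
#' \eqn{\alpha_2 = -e^{-(\tau_m+\tau_s)/(\tau_m \tau_s)}} and
#' \eqn{\beta = e^{-1/\tau_m} - e^{-1/\tau_s}}; its impulse response is
#' \eqn{a^i - b^i} with \eqn{a = e^{-1/\tau_m}}, \eqn{b = e^{-1/\tau_s}}.
#'
#' @param tau_m,tau_s membrane / synapse time constants (in channel steps),
#'   both positive and distinct (equal constants give a dead filter and are
#'   rejected).
#' @param tau_r reset-filter decay constant (> 0).
#' @param lambda reset coupling strength (>= 0).
#' @param v_thre firing threshold; a neuron spikes when its membrane potential
#'   strictly exceeds this value.
#' @param v_rest reset increment added to the reset filter after each spike.
#' @param surrogate_width width of the triangular surrogate derivative used in
#'   place of the Heaviside derivative during backpropagation.
#'
#' @return An object of class `"neuron_config"`: a list with the six
#'   hyperparameters plus derived filter coefficients `a`, `b`, `alpha1`,
#'   `alpha2`, `beta` and `decay_r` (\eqn{e^{-1/\tau_r}}).
#' @examples
#' cfg <- neuron_config(tau_m = 1 / log(2), tau_s = 1 / log(4))
#' c(cfg$alpha1, cfg$alpha2, cfg$beta)  # 0.75 -0.125 0.25
#' @export
neuron_config <- function(tau_m = 8, tau_s = 2, tau_r = 2, lambda = 1,
                          v_thre = 0, v_rest = 1, surrogate_width = 1) {
  if (tau_m <= 0 || tau_s <= 0 || tau_r <= 0)
    stopf("time constants tau_m, tau_s, tau_r must be positive")
  if (tau_m == tau_s)
    stopf("tau_m and tau_s must differ (equal constants give beta = 0, a dead synapse filter)")
  if (lambda < 0) stopf("lambda must be non-negative")
  if (surrogate_width <= 0) stopf("surrogate_width must be positive")
  co <- derive_coefficients(tau_m, tau_s)
  structure(
    list(tau_m = tau_m, tau_s = tau_s, tau_r = tau_r, lambda = lambda,
         v_thre = v_thre, v_rest = v_rest, surrogate_width = surrogate_width,
         a = co[["a"]], b = co[["b"]],
         alpha1 = co[["alpha1"]], alpha2 = co[["alpha2"]], beta = co[["beta"]],
         decay_r = exp(-1 / tau_r)),
    class = "neuron_config")
}

#' @export
print.neuron_config <- function(x, ...) {
  cat("Spiking neuron configuration\n")
  cat(sprintf("  tau_m = %g, tau_s = %g, tau_r = %g\n", x$tau_m, x$tau_s, x$tau_r))
  cat(sprintf("  lambda = %g, V_thre = %g, V_rest = %g\n", x$lambda, x$v_thre, x$v_rest))
  cat(sprintf("  IIR coefficients: alpha1 = %.6g, alpha2 = %.6g, beta = %.6g\n",
              x$alpha1, x$alpha2, x$beta))
  cat(sprintf("  surrogate width = %g\n", x$surrogate_width))
  invisible(x)
}

#' Second-order IIR synapse filter coefficients
#'
#' @param tau_m,tau_s positive, distinct time constants.
#' @return Named numeric vector with `a`, `b`, `alpha1`, `alpha2`, `beta`.
#' @export
derive_coefficients <- function(tau_m, tau_s) {
  if (tau_m <= 0 || tau_s <= 0) stopf("time constants must be positive")
  if (tau_m == tau_s) stopf("tau_m and tau_s must differ")
  a <- exp(-1 / tau_m)
  b <- exp(-1 / tau_s)
  c(a = a, b = b, alpha1 = a + b, alpha2 = -exp(-(tau_m + tau_s) / (tau_m * tau_s)),
    beta = a - b)
}

#' Axon operation: IIR synapse filtering along the channel axis
#'
#' Filters every row of `x` independently with the second-order recurrence
#' `f[i] = alpha1 f[i-1] + alpha2 f[i-2] + beta x[i]`, state initialized to
#' zero at every call (the channel axis restarts with each EEG sample).
#'
#' @param x numeric matrix (feature rows x channels).
#' @param cfg a [neuron_config()].
#' @return Filtered matrix of the same shape.
#' @export
axon_forward <- function(x, cfg) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (any(!is.finite(x))) stopf("axon_forward: non-finite input")
  m <- ncol(x)
  f <- matrix(0, nrow(x), m)
  f1 <- numeric(nrow(x))  # f[i-1]
  f2 <- numeric(nrow(x))  # f[i-2]
  for (i in seq_len(m)) {
    fi <- cfg$alpha1 * f1 + cfg$alpha2 * f2 + cfg$beta * x[, i]
    f[, i] <- fi
    f2 <- f1
    f1 <- fi
  }
  f
}

# Gradient of axon_forward: the filter is linear and time-invariant, so the
# adjoint is the same filter run on the channel-reversed gradient.
axon_backward <- function(dout, cfg) {
  rev_idx <- rev(seq_len(ncol(dout)))
  axon_forward(dout[, rev_idx, drop = FALSE], cfg)[, rev_idx, drop = FALSE]
}

#' Spike nonlinearity with triangular surrogate derivative
#'
#' Forward pass is the strict Heaviside step (1 iff `x > 0`; `U(0) = 0`).
#' The backward pass substitutes the triangular surrogate
#' `max(0, 1 - |x|/w) / w`.
#'
#' @param x numeric; membrane potential minus threshold.
#' @param width surrogate width `w`.
#' @return `spike_function()` returns 0/1 numerics; `spike_surrogate_grad()`
#'   the surrogate derivative.
#' @export
spike_function <- function(x) {
  (x > 0) * 1
}

#' @rdname spike_function
#' @export
spike_surrogate_grad <- function(x, width = 1) {
  pmax(0, 1 - abs(x) / width) / width
}

#' Soma operation: membrane update, threshold firing, reset filter
#'
#' Per channel step `i`, in order: the reset filter decays
#' (`r_til = exp(-1/tau_r) * r[i-1]`), the membrane potential is computed
#' (`v[i] = -lambda * r_til + W f[i]`), spikes fire where `v[i]` strictly
#' exceeds `V_thre`, and the reset filter is incremented
#' (`r[i] = r_til + V_rest * y[i]`). The decay-first sequencing breaks the
#' mutual dependence of the membrane and reset equations one half-step apart.
#'
#' @param f input matrix (in_rows x channels), typically an axon output.
#' @param w synaptic weight matrix (out_neurons x in_rows), the only learnable
#'   parameter of the operation.
#' @param cfg a [neuron_config()].
#' @param keep_cache keep intermediate state for backpropagation.
#' @return list with `spikes` (binary out_neurons x channels matrix),
#'   `membrane` (the potential trace) and, if requested, a `cache`.
#' @export
soma_forward <- function(f, w, cfg, keep_cache = FALSE) {
  if (ncol(w) != nrow(f)) stopf("soma_forward: W is %dx%d but input has %d rows",
                                nrow(w), ncol(w), nrow(f))
  m <- ncol(f)
  wf <- w %*% f
  out <- matrix(0, nrow(w), m)
  vtrace <- matrix(0, nrow(w), m)
  r_prev <- numeric(nrow(w))
  for (i in seq_len(m)) {
    r_til <- cfg$decay_r * r_prev
    v <- -cfg$lambda * r_til + wf[, i]
    y <- (v > cfg$v_thre) * 1
    r_prev <- r_til + cfg$v_rest * y
    out[, i] <- y
    vtrace[, i] <- v
  }
  res <- list(spikes = out, membrane = vtrace)
  if (keep_cache) res$cache <- list(f = f, w = w, v = vtrace, y = out)
  res
}

# Backpropagation through soma_forward (BPTT along the channel axis).
# dout: gradient w.r.t. the spike matrix. Returns grads w.r.t. W and f.
soma_backward <- function(dout, cache, cfg) {
  f <- cache$f; w <- cache$w; v <- cache$v; y <- cache$y
  m <- ncol(f)
  gv_all <- matrix(0, nrow(w), m)
  gr <- numeric(nrow(w))  # grad w.r.t. r[i] entering step i+1
  for (i in rev(seq_len(m))) {
    gy <- dout[, i] + cfg$v_rest * gr
    gv <- gy * spike_surrogate_grad(v[, i] - cfg$v_thre, cfg$surrogate_width)
    g_rtil <- -cfg$lambda * gv + gr
    gr <- cfg$decay_r * g_rtil
    gv_all[, i] <- gv
  }
  list(dw = gv_all %*% t(f), df = crossprod(w, gv_all))
}
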