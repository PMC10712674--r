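#' Build a fractal SNN block
#'
#' Constructs the recursive structure of an `F_c` block from the expansion
#' rule `F_1(X) = Axon(X)`,
#' `F_(c+1)(X) = Sum{ (F_c o Soma o F_c)(X), Axon(X) }`.
#' The block has `c` columns (sub-paths) whose axon depths are
#' `2^(k-1), k = 1..c`, `2^(c-1) - 1` soma junctions (each owning an unshared
#' `n x n` weight matrix) and `2^(c-1) - 1` sum layers.
#'
#' @param order fractal order `c >= 1`.
#' @param n feature rows per channel (width of every soma weight matrix).
#' @return An object of class `"fractal_spec"`: list with the structure `tree`
#'   (nested nodes of type `axon`, `soma`, `seq`, `sum`), `order`, `n`,
#'   `n_soma`, `n_axon`, `n_sum`.
#' @export
build_fractal <- function(order, n) {
  if (order < 1) stopf("fractal order must be >= 1")
  if (n < 1) stopf("width n must be >= 1")
  env <- new.env()
  env$soma <- 0L
  env$sum <- 0L
  env$axon <- 0L
  rec <- function(c) {
    if (c == 1) {
      env$axon <- env$axon + 1L
      return(list(type = "axon"))
    }
    left <- rec(c - 1)
    env$soma <- env$soma + 1L
    soma_id <- env$soma
    right <- rec(c - 1)
    env$axon <- env$axon + 1L
    env$sum <- env$sum + 1L
    list(type = "sum", id = env$sum,
         branches = list(
           long = list(type = "seq",
                       ops = list(left, list(type = "soma", id = soma_id), right)),
           short = list(type = "axon")))
  }
  tree <- rec(order)
  structure(list(tree = tree, order = order, n = n,
                 n_soma = env$soma, n_axon = env$axon, n_sum = env$sum),
            class = "fractal_spec")
}

#' @export
print.fractal_spec <- function(x, ...) {
  cat(sprintf("Fractal SNN block F_%d (width n = %d)\n", x$order, x$n))
  cat(sprintf("  %d axon ops, %d soma junctions, %d sum layers\n",
              x$n_axon, x$n_soma, x$n_sum))
  cat("  column axon-depths:", paste(enumerate_columns(x), collapse = ", "), "\n")
  invisible(x)
}

#' Column (sub-path) axon depths of a fractal block
#'
#' The aligned expansion gives `F_c` exactly `c` columns; column `k` traverses
#' `2^(k-1)` axon operations.
#'
#' @param spec a [build_fractal()] spec (or an integer order).
#' @return Integer vector of the `c` column depths, shortest first.
#' @export
enumerate_columns <- function(spec) {
  order <- if (inherits(spec, "fractal_spec")) spec$order else as.integer(spec)
  2L^(seq_len(order) - 1L)
}

#' Drop-path configuration for the sum layers
#'
#' During training every input to a sum layer is kept independently with
#' probability `1 - p`; the sum of the kept inputs is rescaled by `1/(1-p)`
#' (inverted drop-path). At test time the plain, unscaled sum is used. `mode
#' = "plain"` applies classic drop-path (no rescaling at train time); `mode =
#' "none"` disables dropping altogether.
#'
#' @param p drop probability in `[0, 1)`.
#' @param mode `"inverted"`, `"plain"` or `"none"`.
#' @param redraw if `TRUE` (default) the masks of a sum layer are redrawn
#'   until at least one input survives, so the block never goes silent; the
#'   small upward expectation bias this introduces disappears with
#'   `redraw = FALSE`.
#' @return list of class `"drop_config"`.
#' @export
drop_config <- function(p = 0.15, mode = c("inverted", "plain", "none"),
                        redraw = TRUE) {
  mode <- match.arg(mode)
  if (p < 0 || p >= 1) stopf("drop probability must lie in [0, 1)")
  if (mode == "none") p <- 0
  structure(list(p = p, mode = mode, redraw = redraw), class = "drop_config")
}

#' Sum layer with inverted drop-path
#'
#' @param inputs non-empty list of equally shaped matrices.
#' @param drop a [drop_config()].
#' @param training logical; masks are drawn (from the current RNG stream) only
#'   when `TRUE`.
#' @param forced_mask optional 0/1 vector overriding the random mask (one
#'   entry per input), used for single-column evaluation.
#' @return list with the summed `out` matrix and the `mask` used (all-ones at
#'   test time).
#' @export
inverted_drop_path <- function(inputs, drop, training = FALSE,
                               forced_mask = NULL) {
  k <- length(inputs)
  if (k < 1) stopf("inverted_drop_path: empty input list")
  if (!is.null(forced_mask)) {
    mask <- forced_mask
  } else if (!training || drop$mode == "none" || drop$p == 0) {
    mask <- rep(1, k)
  } else {
    mask <- rbinom(k, 1, 1 - drop$p)
    if (drop$redraw) {
      while (all(mask == 0)) mask <- rbinom(k, 1, 1 - drop$p)
    }
  }
  out <- NULL
  for (j in seq_len(k)) if (mask[j] == 1)
    out <- if (is.null(out)) inputs[[j]] else out + inputs[[j]]
  if (is.null(out)) out <- inputs[[1]] * 0
  scale <- if (training && drop$mode == "inverted" && drop$p > 0) 1 / (1 - drop$p) else 1
  list(out = out * scale, mask = mask, scale = scale)
}

# Recursive forward pass through a fractal tree node.
# params$soma is the list of soma weight matrices (by id).
# forced_masks: optional named list sum_id -> c(long, short) 0/1 masks.
fractal_node_forward <- function(node, x, params, cfg, drop, training,
                                 forced_masks = NULL, keep_cache = FALSE) {
  switch(node$type,
    axon = {
      out <- axon_forward(x, cfg)
      list(out = out, cache = if (keep_cache) list(type = "axon"))
    },
    soma = {
      sf <- soma_forward(x, params$soma[[node$id]], cfg, keep_cache = keep_cache)
      list(out = sf$spikes,
           cache = if (keep_cache) list(type = "soma", id = node$id, soma = sf$cache))
    },
    seq = {
      caches <- vector("list", length(node$ops))
      cur <- x
      for (j in seq_along(node$ops)) {
        r <- fractal_node_forward(node$ops[[j]], cur, params, cfg, drop,
                                  training, forced_masks, keep_cache)
        cur <- r$out
        caches[[j]] <- r$cache
      }
      list(out = cur, cache = if (keep_cache) list(type = "seq", ops = caches))
    },
    sum = {
      rl <- fractal_node_forward(node$branches$long, x, params, cfg, drop,
                                 training, forced_masks, keep_cache)
      rs <- fractal_node_forward(node$branches$short, x, params, cfg, drop,
                                 training, forced_masks, keep_cache)
      fm <- if (!is.null(forced_masks)) forced_masks[[as.character(node$id)]]
      dp <- inverted_drop_path(list(rl$out, rs$out), drop, training, fm)
      list(out = dp$out,
           cache = if (keep_cache) list(type = "sum", id = node$id,
                                        long = rl$cache, short = rs$cache,
                                        mask = dp$mask, scale = dp$scale))
    },
    stopf("unknown fractal node type '%s'", node$type))
}

# Recursive backward pass mirroring fractal_node_forward. Accumulates soma
# weight gradients into acc$soma (an environment) and returns dX.
fractal_node_backward <- function(node, dout, cache, params, cfg, acc) {
  switch(node$type,
    axon = axon_backward(dout, cfg),
    soma = {
      sb <- soma_backward(dout, cache$soma, cfg)
      acc$soma[[cache$id]] <- acc$soma[[cache$id]] + sb$dw
      sb$df
    },
    seq = {
      cur <- dout
      for (j in rev(seq_along(node$ops))) {
        cur <- fractal_node_backward(node$ops[[j]], cur, cache$ops[[j]],
                                     params, cfg, acc)
      }
      cur
    },
    sum = {
      mask <- cache$mask
      scale <- cache$scale
      dl <- if (mask[1] == 1) dout * scale else dout * 0
      ds <- if (mask[2] == 1) dout * scale else dout * 0
      fractal_node_backward(node$branches$long, dl, cache$long, params, cfg, acc) +
        fractal_node_backward(node$branches$short, ds, cache$short, params, cfg, acc)
    })
}

#' Forward pass through a fractal block
#'
#' @param x numeric `n x m` matrix (feature rows x channels).
#' @param spec a [build_fractal()] spec.
#' @param params list with element `soma`: list of `n x n` weight matrices,
#'   one per soma id (see [init_fractal_params()]).
#' @param cfg a [neuron_config()].
#' @param drop a [drop_config()].
#' @param training logical; drop-path masks are drawn only when `TRUE`, and
#'   the test-time pass is fully deterministic.
#' @param forced_masks optional named list (names = sum-layer ids as
#'   characters) of length-2 0/1 vectors `(long, short)` forcing the drop
#'   masks; see [column_masks()].
#' @param keep_cache keep intermediates for backpropagation.
#' @return list with `out` (`n x m` matrix) and optionally `cache`.
#' @export
fractal_forward <- function(x, spec, params, cfg, drop = drop_config(0),
                            training = FALSE, forced_masks = NULL,
                            keep_cache = FALSE) {
  if (nrow(x) != spec$n)
    stopf("input has %d rows but the block was built for n = %d", nrow(x), spec$n)
  fractal_node_forward(spec$tree, x, params, cfg, drop, training,
                       forced_masks, keep_cache)
}

#' Initialize unshared soma weight matrices for a fractal block
#'
#' @param spec a [build_fractal()] spec.
#' @param sd weight standard deviation; the default `1/sqrt(n)` keeps membrane
#'   potentials of order one for order-one inputs.
#' @return list with element `soma`.
#' @export
init_fractal_params <- function(spec, sd = NULL) {
  n <- spec$n
  if (is.null(sd)) sd <- 1 / sqrt(n)
  list(soma = lapply(seq_len(spec$n_soma),
                     function(i) matrix(rnorm(n * n, 0, sd), n, n)))
}

#' Forced drop masks selecting a single column
#'
#' Returns the per-sum-layer masks that keep exactly column `k` (depth
#' `2^(k-1)`) of the block active, supporting single-sub-network evaluation.
#'
#' @param spec a [build_fractal()] spec.
#' @param k column index, `1` = shortest (single axon) path.
#' @return named list suitable for the `forced_masks` argument of
#'   [fractal_forward()].
#' @export
column_masks <- function(spec, k) {
  if (k < 1 || k > spec$order) stopf("column index must be in 1..%d", spec$order)
  masks <- list()
  walk <- function(node, keep) {
    # keep = column index to retain inside this subtree (1 = shortest)
    if (node$type != "sum") return()
    if (keep == 1) {
      masks[[as.character(node$id)]] <<- c(0, 1)  # keep the short axon branch
      # still give the (dropped) long branch consistent masks
      walk_seq(node$branches$long, 1)
    } else {
      masks[[as.character(node$id)]] <<- c(1, 0)
      walk_seq(node$branches$long, keep - 1)
    }
  }
  walk_seq <- function(seq_node, keep) {
    for (op in seq_node$ops) walk(op, keep)
  }
  walk(spec$tree, k)
  masks
}

#' Hand-coded forward pass of the order-2 block
#'
#' Explicit two-path computation
#' `F_2(X) = Axon(X) + Axon(Soma(Axon(X)))`, written out independently of the
#' generic recursive evaluator and used as its oracle.
#'
#' @param x `n x m` input matrix.
#' @param w_bd the `n x n` soma weight matrix.
#' @param cfg a [neuron_config()].
#' @return `n x m` output matrix.
#' @export
f2_forward_explicit <- function(x, w_bd, cfg) {
  o_b <- axon_forward(x, cfg)                      # Path-1 first axon
  x_d <- soma_forward(o_b, w_bd, cfg)$spikes       # Path-1 soma spikes
  o_d <- axon_forward(x_d, cfg)                    # Path-1 second axon
  o_b2 <- axon_forward(x, cfg)                     # Path-2 single axon
  o_d + o_b2
}
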