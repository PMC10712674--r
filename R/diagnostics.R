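#' Gradient saliency map
#'
#' Backpropagates the pre-softmax classification score of a chosen class to
#' the input feature matrix (through the spike nonlinearities via surrogate
#' gradients), takes the absolute value and min-max normalizes to `[0, 1]`.
#' A constant (all-zero) gradient yields an all-zero map with a warning.
#'
#' @param object a fitted [fsnn()] model.
#' @param x input feature matrix (`n x m`).
#' @param class_idx index (or class name) of the class score to explain.
#' @param ... unused.
#' @return `n x m` matrix in `[0, 1]` of class `"saliency_map"` with
#'   attribute `class_idx`.
#' @export
saliency <- function(object, x, class_idx = 1, ...) UseMethod("saliency")

#' @rdname saliency
#' @export
saliency.fsnn <- function(object, x, class_idx = 1, ...) {
  if (is.character(class_idx)) class_idx <- match(class_idx, object$classes)
  fw <- scheme_forward(x, object$model, training = FALSE, keep_cache = TRUE)
  g <- scheme_backward(onehot(class_idx, object$dims["z"]), x, object$model,
                       fw$cache)$dx
  saliency_map(g, class_idx)
}

#' Normalize a raw input gradient into a saliency map
#'
#' @param grad raw gradient matrix of the class score w.r.t. the input.
#' @param class_idx class index stored as metadata.
#' @return min-max normalized `|grad|` (all zeros if the gradient vanishes
#'   everywhere, with a warning).
#' @export
saliency_map <- function(grad, class_idx = NA) {
  a <- abs(grad)
  rng <- range(a)
  if (rng[2] == rng[1]) {
    if (rng[2] == 0) warning("zero gradient everywhere; returning all-zero map")
    out <- a * 0
  } else {
    out <- (a - rng[1]) / (rng[2] - rng[1])
  }
  attr(out, "class_idx") <- class_idx
  class(out) <- c("saliency_map", class(out))
  out
}

#' Reliability (calibration) table
#'
#' For every class, each sample's predicted probability of that class is
#' assigned to one of four bins `[0,.25)`, `[.25,.5)`, `[.5,.75)`, `[.75,1]`;
#' the table reports per class and bin the sample count, the mean predicted
#' probability, and the empirical frequency of the class among the samples in
#' the bin. Empty bins keep count 0 and `NA` statistics (flagged, never
#' fabricated). Bin counts sum to the number of predictions per class.
#'
#' @param probs matrix of predicted probabilities (samples x classes; column
#'   names are the class labels, rows sum to 1).
#' @param labels true labels.
#' @return data.frame of class `"reliability_table"` with columns `class`,
#'   `bin`, `count`, `mean_pred`, `accuracy`.
#' @export
reliability <- function(probs, labels) {
  if (is.null(colnames(probs))) colnames(probs) <- seq_len(ncol(probs))
  labels <- as.character(labels)
  edges <- c(0, 0.25, 0.5, 0.75, 1)
  bin_names <- c("[0,0.25)", "[0.25,0.5)", "[0.5,0.75)", "[0.75,1]")
  out <- do.call(rbind, lapply(colnames(probs), function(cl) {
    p <- probs[, cl]
    bin <- findInterval(p, edges, rightmost.closed = TRUE)
    do.call(rbind, lapply(1:4, function(b) {
      sel <- bin == b
      data.frame(class = cl, bin = bin_names[b], count = sum(sel),
                 mean_pred = if (any(sel)) mean(p[sel]) else NA_real_,
                 accuracy = if (any(sel)) mean(labels[sel] == cl) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("reliability_table", class(out))
  out
}

#' Plot a reliability table
#'
#' Mean predicted probability against empirical accuracy per bin, one panel
#' overlay per class, with the perfect-calibration diagonal.
#'
#' @param x a [reliability()] table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reliability_table <- function(x, ...) {
  plot(c(0, 1), c(0, 1), type = "n", xlab = "mean predicted probability",
       ylab = "empirical accuracy", main = "Reliability diagram", ...)
  abline(0, 1, lty = 2)
  classes <- unique(x$class)
  for (i in seq_along(classes)) {
    sub <- x[x$class == classes[i] & x$count > 0, ]
    lines(sub$mean_pred, sub$accuracy, type = "b", col = i, pch = 19)
  }
  legend("topleft", legend = classes, col = seq_along(classes), pch = 19,
         bty = "n")
  invisible(x)
}
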