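#' Binarize an affect rating at the scale midpoint
#'
#' A rating not less than the midpoint is labelled `"high"`, otherwise
#' `"low"` (e.g. midpoint 3 on a 1-5 valence scale, 5 on a 1-9 scale).
#'
#' @param rating numeric rating(s).
#' @param middle the scale midpoint used as threshold.
#' @return factor with levels `c("low", "high")`.
#' @export
binarize_rating <- function(rating, middle) {
  factor(ifelse(rating >= middle, "high", "low"), levels = c("low", "high"))
}

#' Cross-validation fold construction
#'
#' `kind = "kfold"`: samples are shuffled (seeded) and split into `k`
#' near-equal disjoint test sets that exhaust the data (18 samples with k = 9
#' give test sets of 2; 40 with k = 10 give 4). `kind = "loso"`: one fold per
#' subject, testing on all of that subject's samples.
#'
#' @param n_samples number of samples.
#' @param kind `"kfold"` or `"loso"`.
#' @param k fold count for `"kfold"`.
#' @param subjects subject id per sample, required for `"loso"`.
#' @param seed shuffle seed for `"kfold"`.
#' @return list of folds, each a list with `train` and `test` index vectors.
#' @export
make_folds <- function(n_samples, kind = c("kfold", "loso"), k = 9,
                       subjects = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (n_samples < 1) stopf("empty dataset")
  if (kind == "kfold") {
    if (k > n_samples) stopf("k = %d exceeds the sample count %d", k, n_samples)
    idx <- with_seed(seed, sample.int(n_samples))
    groups <- unname(split(idx, cut(seq_len(n_samples), breaks = k,
                                    labels = FALSE)))
    lapply(groups, function(test)
      list(train = sort(setdiff(seq_len(n_samples), test)), test = sort(test)))
  } else {
    if (is.null(subjects) || length(subjects) != n_samples)
      stopf("loso folds need one subject id per sample")
    lapply(unique(subjects), function(s) {
      test <- which(subjects == s)
      list(train = setdiff(seq_len(n_samples), test), test = test,
           subject = s)
    })
  }
}

#' Classification metrics from predictions
#'
#' @param pred predicted labels.
#' @param truth true labels (same levels).
#' @return list with `accuracy` and the `confusion` matrix (rows = truth,
#'   columns = prediction; row sums equal per-class support).
#' @export
classification_metrics <- function(pred, truth) {
  if (length(pred) == 0) stopf("empty prediction set")
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  list(accuracy = mean(pred == truth),
       confusion = table(truth = truth, predicted = pred))
}

#' Evaluate a fitted model on labelled data
#'
#' @param object a fitted [fsnn()] model.
#' @param x list of feature matrices.
#' @param y true labels.
#' @return list with `accuracy` and `confusion` (see
#'   [classification_metrics()]).
#' @export
evaluate <- function(object, x, y) {
  classification_metrics(predict(object, x, type = "class"), y)
}

#' Remove (disable) channels from feature matrices
#'
#' Drops the columns of the masked channels; the model width `m` of anything
#' fitted downstream adjusts accordingly. Channel metadata round-trips: the
#' remaining column names are the undisabled channels in their original order.
#'
#' @param x a [feature_matrix()] or list of them.
#' @param disable channel names (or indices) to remove.
#' @return the masked matrix / list.
#' @export
mask_channels <- function(x, disable) {
  if (is.list(x) && !is.matrix(x))
    return(lapply(x, mask_channels, disable = disable))
  chans <- colnames(x)
  keep <- if (is.character(disable)) {
    bad <- setdiff(disable, chans)
    if (length(bad)) stopf("unknown channel(s): %s", paste(bad, collapse = ", "))
    !(chans %in% disable)
  } else {
    !(seq_along(chans) %in% disable)
  }
  if (!any(keep)) stopf("cannot disable all channels")
  feature_matrix(unclass(x)[, keep, drop = FALSE], attr(x, "layout"),
                 chans[keep])
}

#' Cross-validated training and evaluation
#'
#' Fits one model per fold (each re-initialized from its own seed derived
#' from `seed + fold`) and reports per-fold test accuracy. With subject ids,
#' accuracies are first averaged within subject, then across subjects.
#'
#' @param x list of feature matrices.
#' @param y labels.
#' @param kind,k,subjects,seed passed to [make_folds()].
#' @param ... passed on to [fsnn()] (order, drop, epochs, ...).
#' @return object of class `"fsnn_cv"`: per-fold accuracies, their mean and
#'   sd, fold definitions and the per-fold loss curves.
#' @export
fsnn_cv <- function(x, y, kind = c("kfold", "loso"), k = 9, subjects = NULL,
                    seed = 1, ...) {
  kind <- match.arg(kind)
  folds <- make_folds(length(x), kind, k = k, subjects = subjects, seed = seed)
  accs <- numeric(length(folds))
  losses <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fit <- fsnn(x[folds[[f]]$train], y[folds[[f]]$train],
                seed = seed + f, ...)
    accs[f] <- evaluate(fit, x[folds[[f]]$test], y[folds[[f]]$test])$accuracy
    losses[[f]] <- fit$loss
  }
  per_subject <- NULL
  if (kind == "loso") {
    per_subject <- accs
    names(per_subject) <- vapply(folds, function(f) as.character(f$subject),
                                 character(1))
  }
  structure(list(fold_accuracy = accs, mean_accuracy = mean(accs),
                 sd_accuracy = sd(accs), folds = folds, kind = kind,
                 per_subject = per_subject, loss_curves = losses),
            class = "fsnn_cv")
}

#' @export
print.fsnn_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation over %d folds\n",
              toupper(x$kind), length(x$fold_accuracy)))
  cat(sprintf("  accuracy: mean %.3f, sd %.3f\n", x$mean_accuracy,
              if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy))
  cat("  per fold:", paste(sprintf("%.2f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}
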