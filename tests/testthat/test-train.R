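test_that("rating binarization uses the not-less-than-midpoint rule", {
  expect_equal(as.character(binarize_rating(3, 3)), "high")
  expect_equal(as.character(binarize_rating(2, 3)), "low")
  expect_equal(as.character(binarize_rating(5, 5)), "high")
  expect_equal(as.character(binarize_rating(c(1, 4.9, 5, 9), 5)),
               c("low", "low", "high", "high"))
})

test_that("k-fold splits partition the data with the protocol fold sizes", {
  f9 <- make_folds(18, "kfold", k = 9, seed = 3)
  expect_length(f9, 9)
  expect_true(all(vapply(f9, function(f) length(f$test), integer(1)) == 2))
  expect_true(all(vapply(f9, function(f) length(f$train), integer(1)) == 16))
  expect_equal(sort(unlist(lapply(f9, `[[`, "test"))), 1:18)

  f10 <- make_folds(40, "kfold", k = 10, seed = 3)
  expect_true(all(vapply(f10, function(f) length(f$test), integer(1)) == 4))
  expect_true(all(vapply(f10, function(f) length(f$train), integer(1)) == 36))
  for (f in f10) expect_length(intersect(f$train, f$test), 0)

  expect_error(make_folds(5, "kfold", k = 9), "exceeds")
  expect_identical(make_folds(18, "kfold", k = 9, seed = 3),
                   make_folds(18, "kfold", k = 9, seed = 3))
})

test_that("LOSO covers every subject exactly once", {
  subj <- rep(1:5, each = 4)
  fl <- make_folds(20, "loso", subjects = subj)
  expect_length(fl, 5)
  expect_equal(sort(unlist(lapply(fl, `[[`, "test"))), 1:20)
  for (f in fl) {
    expect_length(unique(subj[f$test]), 1)
    expect_false(any(subj[f$train] == subj[f$test][1]))
  }
  expect_error(make_folds(20, "loso"), "subject")
})

test_that("metrics: accuracy and confusion counts are consistent", {
  truth <- factor(rep(c("a", "b"), each = 4))
  pred <- factor(c("a", "a", "a", "b", "b", "b", "a", "b"),
                 levels = c("a", "b"))
  met <- classification_metrics(pred, truth)
  expect_equal(met$accuracy, 6 / 8)
  expect_equal(sum(met$confusion), 8)
  expect_equal(unname(rowSums(met$confusion)), c(4, 4))
  expect_identical(classification_metrics(truth, truth)$accuracy, 1)
  expect_error(classification_metrics(factor(), factor()), "empty")

  # uniform random predictions over 4 classes sit near accuracy 1/4
  set.seed(61)
  n <- 4000
  truth4 <- factor(sample(letters[1:4], n, replace = TRUE))
  pred4 <- factor(sample(letters[1:4], n, replace = TRUE),
                  levels = levels(truth4))
  acc <- classification_metrics(pred4, truth4)$accuracy
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(acc - 0.25), 3 * se)
})

test_that("channel masking drops columns and keeps metadata consistent", {
  ds <- tiny_dataset(m = 6)
  masked <- mask_channels(ds$x, c("ch2", "ch5"))
  expect_equal(ncol(masked[[1]]), 4)
  expect_equal(colnames(masked[[1]]), c("ch1", "ch3", "ch4", "ch6"))
  expect_identical(mask_channels(ds$x[[1]], character(0)), ds$x[[1]])
  expect_error(mask_channels(ds$x[[1]], paste0("ch", 1:6)), "all channels")
  expect_error(mask_channels(ds$x[[1]], "nope"), "unknown")
  # masking by index then refitting adjusts the model width
  fit <- fsnn(mask_channels(ds$x, 1), ds$y, order = 1, epochs = 2, seed = 1)
  expect_equal(unname(fit$dims["m"]), 5)
})

test_that("training reduces the loss on separable data and is seed-reproducible", {
  ds <- tiny_dataset()
  f1 <- fsnn(ds$x, ds$y, order = 2, epochs = 15, seed = 7)
  expect_lt(tail(f1$loss, 1), f1$loss[1])
  f2 <- fsnn(ds$x, ds$y, order = 2, epochs = 15, seed = 7)
  expect_identical(f1$loss, f2$loss)
  expect_identical(coef(f1), coef(f2))
  # fitted object surface
  expect_s3_class(f1, "fsnn")
  expect_equal(dim(fitted(f1)), c(8, 2))
  expect_equal(rowSums(fitted(f1)), rep(1, 8), tolerance = 1e-9)
  expect_equal(dim(residuals(f1)), dim(fitted(f1)))
  pr <- predict(f1, ds$x, type = "class")
  expect_s3_class(pr, "factor")
  sim <- simulate(f1, seed = 1)
  expect_length(sim, 8)
})

test_that("cross-validation reports per-fold accuracy and their mean", {
  ds <- tiny_dataset(n_per_class = 6)
  cv <- fsnn_cv(ds$x, ds$y, kind = "kfold", k = 4, seed = 2, order = 1,
                epochs = 10)
  expect_length(cv$fold_accuracy, 4)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
})
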