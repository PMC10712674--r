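test_that("expansion rule yields the expected operation counts and columns", {
  for (c_ord in 1:5) {
    spec <- build_fractal(c_ord, 4)
    expect_equal(spec$n_soma, 2^(c_ord - 1) - 1)
    expect_equal(spec$n_sum, 2^(c_ord - 1) - 1)
    # axon count satisfies A(1) = 1, A(c+1) = 2 A(c) + 1  =>  2^c - 1
    expect_equal(spec$n_axon, 2^c_ord - 1)
    depths <- enumerate_columns(spec)
    expect_length(depths, c_ord)
    expect_equal(depths, 2^(seq_len(c_ord) - 1))
    expect_false(any(duplicated(depths)))
  }
  expect_error(build_fractal(0, 4), "order")
})

test_that("generic order-2 forward is bit-identical to the explicit two-path form", {
  cfg <- neuron_config()
  spec <- build_fractal(2, 6)
  set.seed(41)
  params <- init_fractal_params(spec)
  for (i in 1:100) {
    x <- matrix(rnorm(6 * 8), 6)
    a <- fractal_forward(x, spec, params, cfg)$out
    b <- f2_forward_explicit(x, params$soma[[1]], cfg)
    expect_identical(a, b)
  }
})

test_that("order-1 block is a bare axon; zero input gives zero output", {
  cfg <- neuron_config()
  spec <- build_fractal(1, 3)
  set.seed(42)
  params <- init_fractal_params(spec)
  x <- matrix(rnorm(3 * 7), 3)
  expect_equal(fractal_forward(x, spec, params, cfg)$out, axon_forward(x, cfg))

  spec3 <- build_fractal(3, 3)
  p3 <- init_fractal_params(spec3)
  expect_equal(fractal_forward(x * 0, spec3, p3, cfg)$out, x * 0)
})

test_that("inverted drop-path follows the masked, rescaled sum rule", {
  i2 <- matrix(2, 1, 1); i4 <- matrix(4, 1, 1)
  dp <- drop_config(0.5)
  # forced mask (keep, drop): (1*2 + 0*4) / (1 - 0.5) = 4
  out <- inverted_drop_path(list(i2, i4), dp, training = TRUE,
                            forced_mask = c(1, 0))
  expect_equal(out$out[1, 1], 4)
  # p = 0: exact sum regardless of mode/phase
  expect_equal(inverted_drop_path(list(i2, i4), drop_config(0),
                                  training = TRUE)$out[1, 1], 6)
  # test phase: plain unscaled sum
  expect_equal(inverted_drop_path(list(i2, i4), dp, training = FALSE)$out[1, 1], 6)
  expect_error(drop_config(1), "\\[0, 1\\)")
  expect_error(inverted_drop_path(list(), dp), "empty")
})

test_that("drop-path is unbiased without the redraw guard", {
  set.seed(43)
  dp <- drop_config(0.3, redraw = FALSE)
  draws <- replicate(1e5,
    inverted_drop_path(list(i2 = matrix(2, 1, 1), i4 = matrix(4, 1, 1)),
                       dp, training = TRUE)$out[1, 1])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 6), 3 * se)
})

test_that("training-time fractal passes are seed-reproducible; test-time ones deterministic", {
  cfg <- neuron_config()
  spec <- build_fractal(3, 5)
  set.seed(44)
  params <- init_fractal_params(spec)
  x <- matrix(rnorm(5 * 9), 5)
  dp <- drop_config(0.4)
  set.seed(99); a <- fractal_forward(x, spec, params, cfg, dp, training = TRUE)$out
  set.seed(99); b <- fractal_forward(x, spec, params, cfg, dp, training = TRUE)$out
  expect_identical(a, b)
  e1 <- fractal_forward(x, spec, params, cfg, dp, training = FALSE)$out
  e2 <- fractal_forward(x, spec, params, cfg, dp, training = FALSE)$out
  expect_identical(e1, e2)
})

test_that("forcing the shortest column reduces the block to a rescaled axon", {
  cfg <- neuron_config()
  spec <- build_fractal(3, 4)
  set.seed(45)
  params <- init_fractal_params(spec)
  x <- matrix(rnorm(4 * 6), 4)
  p <- 0.15
  masks <- column_masks(spec, 1)
  out <- fractal_forward(x, spec, params, cfg, drop_config(p), training = TRUE,
                         forced_masks = masks)$out
  expect_equal(out, axon_forward(x, cfg) / (1 - p), tolerance = 1e-12)
})

test_that("every single column supports a valid forward pass", {
  cfg <- neuron_config()
  spec <- build_fractal(3, 4)
  set.seed(46)
  params <- init_fractal_params(spec)
  x <- matrix(rnorm(4 * 6), 4)
  outs <- lapply(1:3, function(k)
    fractal_forward(x, spec, params, cfg, drop_config(0.15), training = FALSE,
                    forced_masks = column_masks(spec, k))$out)
  for (o in outs) expect_true(all(is.finite(o)))
  # columns are genuinely different sub-networks
  expect_gt(max(abs(outs[[1]] - outs[[2]])), 0)
  # column 1 at test time is the bare axon, unscaled
  expect_equal(outs[[1]], axon_forward(x, cfg))
})
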