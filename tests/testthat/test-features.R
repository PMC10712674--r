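test_that("preprocess z-scores every channel and rejects degenerate input", {
  rec <- tone_record(c(6, 10, 20), noise_sd = 0.2)
  out <- preprocess(rec, 4, 60)
  expect_equal(apply(out$data, 1, mean), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(out$data, 1, sd), rep(1, 3), tolerance = 1e-8)

  const <- signal_record(rbind(sin(2 * pi * 6 * (1:512) / 128), rep(2, 512)), 128)
  expect_error(preprocess(const, 4, 60), "degenerate")
  expect_error(preprocess(tone_record(6, fs = 100), 4, 60), "invalid band")
  expect_error(bandpass(tone_record(6, fs = 100), 4, 60), "Nyquist")
})

test_that("bandpass attenuates out-of-band content", {
  # pure 2 Hz tone, 4-60 Hz band: residual power under 5% of input power
  rec <- tone_record(2, fs = 128, duration = 10)
  filt <- bandpass(rec, 4, 60)
  p_in <- oracle_band_power(rec$data[1, ], 128, 0, 64)
  p_out <- oracle_band_power(filt$data[1, ], 128, 0, 64)
  expect_lt(p_out / p_in, 0.05)

  # mixed tone: after full preprocessing the 2 Hz line is negligible
  # next to the in-band 10 Hz line
  t_axis <- (1:1280) / 128
  mixed <- signal_record(matrix(sin(2 * pi * 2 * t_axis) +
                                  sin(2 * pi * 10 * t_axis), 1), 128)
  pp <- preprocess(mixed, 4, 60)
  expect_lt(oracle_band_power(pp$data[1, ], 128, 1, 3),
            0.05 * oracle_band_power(pp$data[1, ], 128, 9, 11))
})

test_that("sliding-window count follows floor((duration - win)/step) + 1", {
  cases <- list(c(60, 1, 0.5, 119), c(1, 1, 0.5, 1), c(60, 1, 1, 60),
                c(10, 2, 0.5, 17), c(6, 1, 0.5, 11))
  for (cs in cases) {
    rec <- signal_record(matrix(rnorm(2 * cs[1] * 128), 2), 128)
    wins <- segment(rec, cs[2], cs[3])
    expect_length(wins, cs[4])
    expect_true(all(vapply(wins, ncol, integer(1)) == cs[2] * 128))
  }
  rec1 <- signal_record(matrix(rnorm(128), 1), 128)
  expect_error(segment(rec1, 2, 0.5), "empty")
  expect_error(segment(rec1, 1, 0), "step")
})

test_that("differential entropy follows the Gaussian closed form and its scaling law", {
  set.seed(11)
  w <- rnorm(10000)                      # sigma^2 = 1
  bf <- band_features(w, 128, c(14, 30))
  expect_equal(bf[["de"]], 0.5 * log(2 * pi * exp(1)), tolerance = 0.05)

  # de(c x) - de(x) = log|c|; psd scales with c^2
  for (cc in c(2, 0.5, -3)) {
    b1 <- band_features(w, 128, c(14, 30))
    b2 <- band_features(cc * w, 128, c(14, 30))
    expect_equal(b2[["de"]] - b1[["de"]], log(abs(cc)), tolerance = 1e-6)
    expect_equal(b2[["psd"]] / b1[["psd"]], cc^2, tolerance = 1e-9)
  }

  zf <- band_features(numeric(128), 128, c(14, 30), de_floor = -20)
  expect_identical(zf[["psd"]], 0)
  expect_identical(zf[["de"]], -20)
  expect_error(band_features(w, 128, c(30, 70)), "invalid band")
})

test_that("feature matrix assembly orders band blocks as configured", {
  rec <- tone_record(c(6, 20), duration = 3, noise_sd = 0.3)
  pp <- preprocess(rec, 4, 60)
  fm <- extract_features(pp, win_s = 1, step_s = 0.5, kinds = c("psd", "de"))
  lay <- attr(fm, "layout")
  expect_equal(nrow(fm), 4 * 2 * 5)      # bands x kinds x windows
  expect_equal(ncol(fm), 2)
  expect_equal(unique(lay$band), c("theta", "alpha", "beta", "gamma"))
  # band blocks contiguous, psd sub-block before de, windows in order
  beta <- lay[lay$band == "beta", ]
  expect_equal(beta$kind, rep(c("psd", "de"), each = 5))
  expect_equal(beta$window, rep(1:5, 2))
  expect_equal(which(lay$band == "beta"), 21:30)

  # column permutation of channels permutes columns identically
  rec2 <- signal_record(pp$data[2:1, ], pp$fs, pp$channel_names[2:1])
  fm2 <- extract_features(rec2, win_s = 1, step_s = 0.5, kinds = c("psd", "de"))
  expect_equal(unclass(fm2)[, 1], unclass(fm)[, 2], ignore_attr = TRUE)

  # DE-only layout: n = bands x windows
  fm3 <- extract_features(pp, win_s = 1, step_s = 0.5, kinds = "de")
  expect_equal(nrow(fm3), 20)
})

test_that("tone with 3x amplitude raises in-band psd and de by the expected amounts", {
  rec_lo <- tone_record(20, duration = 4)
  rec_hi <- signal_record(3 * rec_lo$data, 128)
  f_lo <- extract_features(rec_lo, kinds = c("psd", "de"))
  f_hi <- extract_features(rec_hi, kinds = c("psd", "de"))
  lay <- attr(f_lo, "layout")
  psd_rows <- which(lay$band == "beta" & lay$kind == "psd")
  de_rows <- which(lay$band == "beta" & lay$kind == "de")
  expect_equal(mean(unclass(f_hi)[psd_rows, 1] / unclass(f_lo)[psd_rows, 1]),
               9, tolerance = 1e-6)
  expect_equal(mean(unclass(f_hi)[de_rows, 1] - unclass(f_lo)[de_rows, 1]),
               log(3), tolerance = 1e-6)
})

test_that("feature matrices and signals round-trip through disk bit-exactly", {
  rec <- tone_record(c(6, 20), duration = 2, noise_sd = 0.5)
  fm <- extract_features(preprocess(rec, 4, 60))
  path <- tempfile(fileext = ".tsv")
  write_features(fm, path)
  fm2 <- read_features(path)
  expect_identical(unclass(fm2)[, ], unclass(fm)[, ])
  expect_identical(attr(fm2, "layout"), attr(fm, "layout"))
  expect_identical(colnames(fm2), colnames(fm))

  sp <- tempfile(fileext = ".txt")
  write_signal(rec, sp)
  rec2 <- read_signal(sp)
  expect_identical(rec2$data, rec$data)
  expect_identical(rec2$fs, rec$fs)
  expect_identical(rec2$channel_names, rec$channel_names)
})

test_that("last_seconds keeps the trailing interval", {
  rec <- signal_record(matrix(1:1280, 1), 128)
  out <- last_seconds(rec, 2)
  expect_equal(ncol(out$data), 256)
  expect_equal(out$data[1, 256], 1280)
})
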