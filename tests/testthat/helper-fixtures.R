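# shared in-code fixtures

# sinusoid-plus-noise record: one tone per channel at the given frequencies
tone_record <- function(freqs, fs = 128, duration = 4, noise_sd = 0,
                        seed = 42) {
  t_axis <- seq_len(fs * duration) / fs
  dat <- t(vapply(freqs, function(f)
    sin(2 * pi * f * t_axis), numeric(length(t_axis))))
  if (noise_sd > 0) {
    set.seed(seed)
    dat <- dat + matrix(rnorm(length(dat), 0, noise_sd), nrow(dat))
  }
  signal_record(dat, fs)
}

# total power of a signal via the raw periodogram (independent oracle for
# band-attenuation checks)
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- abs(fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  sum(sp[freq >= lo & freq <= hi & freq <= fs / 2])
}

# small random feature dataset for fast model-fitting tests
tiny_dataset <- function(n = 12, m = 5, n_per_class = 4, shift = 2, seed = 1) {
  set.seed(seed)
  lay <- data.frame(band = rep("beta", n), kind = "de", window = seq_len(n))
  x <- list(); y <- character(0)
  for (cl in 1:2) {
    for (s in seq_len(n_per_class)) {
      mat <- matrix(rnorm(n * m), n, m)
      if (cl == 2) mat[1:4, ] <- mat[1:4, ] + shift
      x[[length(x) + 1]] <- feature_matrix(mat, lay, paste0("ch", 1:m))
      y <- c(y, paste0("c", cl))
    }
  }
  list(x = x, y = factor(y))
}
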