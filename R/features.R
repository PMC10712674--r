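#' Multichannel EEG signal record
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names optional channel labels (defaults `ch1..chK`).
#' @return object of class `"signal_record"` with fields `data`, `fs`,
#'   `channel_names`, `duration` (seconds).
#' @export
signal_record <- function(data, fs, channel_names = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (fs <= 0) stopf("sampling rate must be positive")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stopf("data has %d rows but %d channel names were given",
          nrow(data), length(channel_names))
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 duration = ncol(data) / fs),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("EEG signal record: %d channels x %d samples (%.3g s at %g Hz)\n",
              nrow(x$data), ncol(x$data), x$duration, x$fs))
  invisible(x)
}

#' Default EEG frequency bands
#'
#' theta 4-8 Hz, alpha 8-14 Hz, beta 14-30 Hz, gamma 30-45 Hz; feature blocks
#' are emitted in this order.
#'
#' @return named list of `c(lo, hi)` bounds in Hz.
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 14), beta = c(14, 30), gamma = c(30, 45))
}

#' Zero-phase Butterworth bandpass
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt]), so the
#' output is phase-free. Standard EEG practice.
#'
#' @param record a [signal_record()].
#' @param lo,hi passband bounds in Hz; requires `hi < fs/2`.
#' @return filtered [signal_record()].
#' @export
bandpass <- function(record, lo = 4, hi = 60) {
  if (lo <= 0 || hi <= lo) stopf("need 0 < lo < hi")
  if (hi >= record$fs / 2)
    stopf("invalid band: hi = %g Hz is not below the Nyquist frequency %g Hz",
          hi, record$fs / 2)
  bf <- signal::butter(4, c(lo, hi) / (record$fs / 2), type = "pass")
  out <- t(apply(record$data, 1, function(ch) signal::filtfilt(bf, ch)))
  signal_record(out, record$fs, record$channel_names)
}

#' Preprocess raw EEG: bandpass then per-channel z-score
#'
#' Applies [bandpass()] and then standardizes every channel over the whole
#' record (mean 0, unit sample variance).
#'
#' @inheritParams bandpass
#' @return preprocessed [signal_record()]; each channel has mean 0 and sample
#'   standard deviation 1.
#' @export
preprocess <- function(record, lo = 4, hi = 60) {
  if (record$fs <= 2 * hi)
    stopf("invalid band: sampling rate %g Hz must exceed 2*hi = %g Hz",
          record$fs, 2 * hi)
  if (ncol(record$data) < 2) stopf("need at least 2 samples per channel")
  sds <- apply(record$data, 1, sd)
  if (any(sds == 0))
    stopf("degenerate input: channel(s) %s are constant (zero variance)",
          paste(record$channel_names[sds == 0], collapse = ", "))
  filt <- bandpass(record, lo, hi)
  z <- t(apply(filt$data, 1, function(ch) {
    s <- sd(ch)
    if (s == 0) stopf("degenerate input: a channel is constant after filtering")
    (ch - mean(ch)) / s
  }))
  signal_record(z, record$fs, record$channel_names)
}

#' Keep only the trailing seconds of a record
#'
#' @param record a [signal_record()].
#' @param seconds tail length to keep; records shorter than `seconds` are
#'   returned unchanged.
#' @export
last_seconds <- function(record, seconds = 60) {
  keep <- min(ncol(record$data), round(seconds * record$fs))
  idx <- (ncol(record$data) - keep + 1):ncol(record$data)
  signal_record(record$data[, idx, drop = FALSE], record$fs, record$channel_names)
}

#' Sliding-window segmentation
#'
#' Window count is `floor((duration - win_s) / step_s) + 1`; windows that
#' would overrun the record are dropped, never padded.
#'
#' @param record a [signal_record()].
#' @param win_s window length in seconds.
#' @param step_s step size in seconds (> 0).
#' @return list of channels-x-samples matrices, one per window.
#' @export
segment <- function(record, win_s = 1, step_s = 0.5) {
  if (step_s <= 0) stopf("step size must be positive")
  win_n <- round(win_s * record$fs)
  step_n <- round(step_s * record$fs)
  s <- ncol(record$data)
  if (win_n > s)
    stopf("empty output: window (%g s) exceeds record duration (%g s)",
          win_s, record$duration)
  n_win <- (s - win_n) %/% step_n + 1L
  lapply(seq_len(n_win), function(w) {
    start <- (w - 1L) * step_n + 1L
    record$data[, start:(start + win_n - 1L), drop = FALSE]
  })
}

# Hann-tapered periodogram density of a single window
periodogram <- function(x, fs) {
  L <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)  # Hann taper
  xw <- (x - mean(x)) * w
  spec <- abs(fft(xw))^2 / (sum(w^2) * fs)
  nf <- floor(L / 2) + 1
  freq <- (seq_len(nf) - 1) * fs / L
  dens <- spec[seq_len(nf)]
  dens[-c(1, if (L %% 2 == 0) nf)] <- 2 * dens[-c(1, if (L %% 2 == 0) nf)]
  list(freq = freq, density = dens)
}

#' Band-limited PSD and differential entropy of one window
#'
#' `window` is expected to be already band-limited to `band` (the pipeline
#' filters whole channels per band before windowing). The PSD value is the
#' mean Hann-tapered periodogram density within the band; the DE value is the
#' Gaussian closed form `0.5 * log(2 * pi * e * var(window))`, the convention
#' of the public EEG-emotion feature sets distributed as DE matrices.
#'
#' @param window numeric vector (>= 2 samples).
#' @param fs sampling rate (Hz).
#' @param band `c(lo, hi)` bounds in Hz, valid for `fs`.
#' @param de_floor lower clip for the DE value of (near-)zero-variance
#'   windows, which would otherwise be `-Inf`.
#' @param psd_log report PSD on a log scale (`log(psd + 1e-12)`).
#' @return named numeric vector `c(psd, de)`.
#' @export
band_features <- function(window, fs, band, de_floor = -20, psd_log = FALSE) {
  if (length(window) < 2) stopf("window must have at least 2 samples")
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stopf("invalid band [%g, %g] for fs = %g", band[1], band[2], fs)
  pg <- periodogram(window, fs)
  sel <- pg$freq >= band[1] & pg$freq <= band[2]
  psd <- mean(pg$density[sel])
  if (psd_log) psd <- log(psd + 1e-12)
  v <- var(window)
  de <- if (v > 0) 0.5 * log(2 * pi * exp(1) * v) else -Inf
  if (de < de_floor) de <- de_floor
  c(psd = psd, de = de)
}

#' Assemble per-band window features into a feature matrix
#'
#' Rows are grouped by band in the given order; within a band, feature kinds
#' form contiguous sub-blocks (PSD first, then DE when both are requested),
#' each ordered by window index. Column `i` is channel `i`.
#'
#' @param values numeric array `[band, kind, window, channel]` or a list as
#'   built internally by [extract_features()]; users normally call
#'   [extract_features()] directly.
#' @param band_names,kinds,channel_names row/column metadata.
#' @return a `"feature_matrix"`: numeric matrix with attribute `layout`
#'   (data.frame of `band`, `kind`, `window` per row) and channel column
#'   names.
#' @export
assemble_feature_matrix <- function(values, band_names, kinds, channel_names) {
  stopifnot(length(dim(values)) == 4)
  n_band <- dim(values)[1]; n_kind <- dim(values)[2]
  n_win <- dim(values)[3]; m <- dim(values)[4]
  rows <- n_band * n_kind * n_win
  mat <- matrix(0, rows, m)
  layout <- data.frame(band = character(rows), kind = character(rows),
                       window = integer(rows), stringsAsFactors = FALSE)
  r <- 0L
  for (b in seq_len(n_band)) {
    for (k in seq_len(n_kind)) {
      for (w in seq_len(n_win)) {
        r <- r + 1L
        mat[r, ] <- values[b, k, w, ]
        layout$band[r] <- band_names[b]
        layout$kind[r] <- kinds[k]
        layout$window[r] <- w
      }
    }
  }
  feature_matrix(mat, layout, channel_names)
}

#' Feature matrix container
#'
#' @param values numeric `n x m` matrix (features x channels).
#' @param layout data.frame with one row per feature row: `band`, `kind`,
#'   `window`.
#' @param channel_names channel labels for the `m` columns.
#' @return classed matrix with `layout` attribute.
#' @export
feature_matrix <- function(values, layout, channel_names) {
  if (nrow(layout) != nrow(values))
    stopf("layout has %d rows but values has %d", nrow(layout), nrow(values))
  if (length(channel_names) != ncol(values))
    stopf("channel name count does not match column count")
  colnames(values) <- channel_names
  attr(values, "layout") <- layout
  class(values) <- c("feature_matrix", class(values))
  values
}

#' @export
print.feature_matrix <- function(x, ...) {
  lay <- attr(x, "layout")
  cat(sprintf("Feature matrix: %d features x %d channels\n", nrow(x), ncol(x)))
  cat(sprintf("  bands: %s; kinds: %s; windows: %d\n",
              paste(unique(lay$band), collapse = ", "),
              paste(unique(lay$kind), collapse = ", "),
              max(lay$window)))
  invisible(x)
}

#' Temporal-spectral-spatial feature extraction pipeline
#'
#' Converts a (preprocessed) record into the working feature representation:
#' every channel is band-filtered once per band, segmented with a sliding
#' window, and per-window PSD and/or DE values are stacked band-block by
#' band-block into an `n x m` matrix
#' (`n = bands x kinds x windows`).
#'
#' @param record a [signal_record()], typically the output of [preprocess()].
#' @param bands named list of `c(lo, hi)` bounds (default [default_bands()]).
#' @param win_s,step_s sliding-window length and step in seconds.
#' @param kinds feature kinds to emit: subset of `c("psd", "de")`.
#' @param de_floor,psd_log passed to [band_features()].
#' @return a [feature_matrix()].
#' @export
extract_features <- function(record, bands = default_bands(), win_s = 1,
                             step_s = 0.5, kinds = c("psd", "de"),
                             de_floor = -20, psd_log = FALSE) {
  kinds <- match.arg(kinds, c("psd", "de"), several.ok = TRUE)
  m <- nrow(record$data)
  # band-filter whole channels once, then window
  per_band <- lapply(bands, function(b) bandpass(record, b[1], b[2]))
  wins <- segment(per_band[[1]], win_s, step_s)
  n_win <- length(wins)
  vals <- array(0, c(length(bands), length(kinds), n_win, m))
  for (b in seq_along(bands)) {
    bwins <- segment(per_band[[b]], win_s, step_s)
    for (w in seq_len(n_win)) {
      for (ch in seq_len(m)) {
        bf <- band_features(bwins[[w]][ch, ], record$fs, bands[[b]],
                            de_floor = de_floor, psd_log = psd_log)
        for (k in seq_along(kinds)) vals[b, k, w, ch] <- bf[[kinds[k]]]
      }
    }
  }
  assemble_feature_matrix(vals, names(bands), kinds, record$channel_names)
}

#' Row indices of a band block
#'
#' @param x a [feature_matrix()].
#' @param band band name as in the layout.
#' @return integer vector of row indices belonging to the band.
#' @export
band_rows <- function(x, band) {
  which(attr(x, "layout")$band == band)
}
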