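#' Read / write a raw EEG record as delimited text
#'
#' The signal is stored channels x samples in a tab-delimited file; a YAML
#' sidecar (`<path>.meta.yaml`) carries the sampling rate and channel names.
#'
#' @param record a [signal_record()].
#' @param path data file path; the sidecar is written next to it.
#' @return `read_signal()` returns a [signal_record()].
#' @export
write_signal <- function(record, path) {
  write.table(format_full(record$data), path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = record$fs, channel_names = record$channel_names),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  dat <- as.matrix(read.table(path, sep = "\t", colClasses = "numeric"))
  dimnames(dat) <- NULL
  signal_record(dat, meta$fs, unlist(meta$channel_names))
}

# full-precision decimal formatting: round-trips doubles bit-exactly
format_full <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  dim(out) <- dim(x)
  out
}

#' Read / write a feature matrix as delimited text
#'
#' Tab-separated values with `#`-prefixed header lines carrying the channel
#' names, then one row per feature with the layout columns (`band`, `kind`,
#' `window`) followed by the per-channel values at full precision (`%.17g`),
#' so the write/read round trip is bit-exact.
#'
#' @param x a [feature_matrix()].
#' @param path file path.
#' @return `read_features()` returns a [feature_matrix()].
#' @export
write_features <- function(x, path) {
  lay <- attr(x, "layout")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# channels\t", paste(colnames(x), collapse = "\t")), con)
  writeLines(paste0("band\tkind\twindow\t", paste(colnames(x), collapse = "\t")), con)
  vals <- format_full(unclass(x))
  for (r in seq_len(nrow(x))) {
    writeLines(paste(c(lay$band[r], lay$kind[r], lay$window[r], vals[r, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  chan_line <- strsplit(sub("^# channels\t", "", lines[1]), "\t")[[1]]
  body <- read.table(text = lines[-1], sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE)
  lay <- data.frame(band = body$band, kind = body$kind,
                    window = as.integer(body$window), stringsAsFactors = FALSE)
  vals <- as.matrix(body[, -(1:3), drop = FALSE])
  dimnames(vals) <- NULL
  feature_matrix(vals, lay, chan_line)
}
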