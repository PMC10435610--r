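#' Multichannel time series container
#'
#' Region-level oscillatory data: a numeric matrix with one column per
#' region, plus the sampling frequency and region labels.
#'
#' @param samples Numeric matrix, time in rows, regions in columns.
#' @param fs Sampling frequency in Hz, `> 0`.
#' @param region_labels Character vector of region names; defaults to
#'   existing column names or `R1..RN`.
#' @return A `time_series` object.
#' @export
time_series <- function(samples, fs, region_labels = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (ncol(samples) < 2L) stop("need at least 2 regions, got ", ncol(samples))
  if (nrow(samples) < 1L) stop("need at least 1 sample")
  if (anyNA(samples)) stop("time series contains missing values")
  if (is.null(region_labels)) {
    region_labels <- colnames(samples)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(samples)))
  }
  if (length(region_labels) != ncol(samples)) {
    stop("region_labels length (", length(region_labels),
         ") != number of regions (", ncol(samples), ")")
  }
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  colnames(samples) <- region_labels
  structure(list(samples = samples, fs = fs,
                 region_labels = as.character(region_labels)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples x %d regions @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' Cut a recording into fixed-length epochs
#'
#' Takes the first `min(max_epochs, floor(T / epoch_length))` consecutive,
#' non-overlapping segments in temporal order. Defaults correspond to
#' 60 epochs of 4096 samples (3.28 s at 1250 Hz).
#'
#' @param ts A [time_series].
#' @param epoch_length Samples per epoch (default 4096).
#' @param max_epochs Maximum number of epochs to keep (default 60).
#' @return List of epoch matrices (`epoch_length` x regions), with the
#'   region labels carried as column names.
#' @export
segment_epochs <- function(ts, epoch_length = 4096L, max_epochs = 60L) {
  stopifnot(inherits(ts, "time_series"))
  epoch_length <- as.integer(epoch_length)
  max_epochs <- as.integer(max_epochs)
  stopifnot(epoch_length >= 1L, max_epochs >= 1L)
  n <- nrow(ts$samples)
  if (n < epoch_length) {
    stop("cannot epoch: need ", epoch_length, " samples per epoch but only ",
         n, " available")
  }
  k <- min(max_epochs, n %/% epoch_length)
  lapply(seq_len(k), function(i) {
    ts$samples[((i - 1L) * epoch_length + 1L):(i * epoch_length), , drop = FALSE]
  })
}
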