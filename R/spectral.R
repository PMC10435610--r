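# Band filtering, analytic phase, and the phase lag index.

# Two-sided DFT bin frequencies for a length-n signal at sampling rate fs:
# bin k (0-based) maps to min(k, n-k) * fs / n.
dft_bin_freqs <- function(n, fs) {
  k <- 0:(n - 1L)
  pmin(k, n - k) * fs / n
}

#' FFT band-pass filter for one epoch
#'
#' Mean-centers each channel, zeroes every DFT bin whose frequency lies
#' outside the half-open interval `[f_lo, f_hi)`, and inverse-transforms.
#' The mask is applied symmetrically to positive and negative frequencies
#' so the output is real; the imaginary residue is asserted to be below
#' 1e-9 of the signal norm before being discarded.
#'
#' @param epoch Numeric matrix (samples x regions).
#' @param band A [band_definition].
#' @param fs Sampling frequency in Hz; `band$f_hi` must not exceed the
#'   Nyquist frequency `fs/2`.
#' @return Filtered real matrix of identical shape.
#' @export
bandpass_fft <- function(epoch, band, fs) {
  epoch <- as.matrix(epoch)
  stopifnot(inherits(band, "band_definition"), is.numeric(fs), fs > 0)
  if (band$f_hi > fs / 2) {
    stop("band '", band$name, "' upper edge ", band$f_hi,
         " Hz exceeds Nyquist frequency ", fs / 2, " Hz")
  }
  n <- nrow(epoch)
  centered <- sweep(epoch, 2L, colMeans(epoch))
  f <- dft_bin_freqs(n, fs)
  mask <- f >= band$f_lo & f < band$f_hi
  x <- stats::mvfft(centered)
  x[!mask, ] <- 0
  y <- stats::mvfft(x, inverse = TRUE) / n
  resid <- sqrt(sum(Im(y)^2))
  # relative to the input norm: an all-out-of-band signal has a near-zero
  # output whose roundoff-level imaginary part is harmless
  nrm <- max(sqrt(sum(centered^2)), sqrt(sum(Mod(y)^2)))
  if (nrm > 0 && resid > 1e-9 * nrm) {
    stop("band filter produced non-real output (imaginary residue ",
         format(resid / nrm), ")")
  }
  out <- Re(y)
  dimnames(out) <- dimnames(epoch)
  out
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert analytic signal of each channel by FFT (no
#' padding) and returns its argument, wrapped to `(-pi, pi]`.
#'
#' @param epoch Numeric matrix (samples x regions); every channel must be
#'   non-constant.
#' @return Matrix of phases in radians, same shape as `epoch`.
#' @export
instantaneous_phase <- function(epoch) {
  epoch <- as.matrix(epoch)
  n <- nrow(epoch)
  sds <- apply(epoch, 2L, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad)) {
    nm <- colnames(epoch)
    lab <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop("constant (zero-variance) channel(s): ", paste(lab, collapse = ", "),
         "; phase undefined")
  }
  # analytic-signal multiplier: keep DC and Nyquist, double positive freqs
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::mvfft(stats::mvfft(epoch) * h, inverse = TRUE) / n
  ph <- Arg(z)
  ph[ph <= -pi] <- pi  # wrap the branch point into (-pi, pi]
  dimnames(ph) <- dimnames(epoch)
  ph
}

#' Phase lag index of two phase sequences
#'
#' `PLI = | mean_t sign( sin(phi_a(t) - phi_b(t)) ) |`. An exactly zero
#' phase difference contributes 0 to the mean (it dilutes the index rather
#' than counting as a lag), so identical signals give PLI 0 and a constant
#' nonzero lag gives PLI 1. The index is bounded in `[0, 1]`, symmetric in
#' its arguments, and blind to amplitude.
#'
#' @param phi_a,phi_b Numeric vectors of phases (radians), equal length.
#' @return PLI value in `[0, 1]`.
#' @export
pli_pair <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b)) {
    stop("phase sequences differ in length: ", length(phi_a), " vs ",
         length(phi_b))
  }
  if (length(phi_a) < 1L) stop("empty phase sequences")
  abs(mean(sign(sin(phi_a - phi_b))))
}

#' Connectivity matrix container
#'
#' @param weights Symmetric nonnegative matrix with zero diagonal, entries
#'   in `[0, 1]`.
#' @param band The [band_definition] the matrix belongs to (or `NULL`).
#' @param n_epochs_averaged Number of epochs averaged.
#' @param region_labels Optional labels; defaults to dimnames.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(weights, band = NULL, n_epochs_averaged = 1L,
                                region_labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("connectivity matrix must be square")
  if (max(abs(weights - t(weights))) > 1e-9) stop("connectivity matrix must be symmetric")
  if (any(diag(weights) != 0)) stop("connectivity matrix must have zero diagonal")
  if (min(weights) < 0 || max(weights) > 1 + 1e-12) {
    stop("connectivity entries must lie in [0, 1]")
  }
  if (is.null(region_labels)) {
    region_labels <- rownames(weights)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, band = band,
                 n_epochs_averaged = as.integer(n_epochs_averaged),
                 region_labels = as.character(region_labels)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  bn <- if (is.null(x$band)) "?" else x$band$name
  cat(sprintf("<connectivity_matrix> %d x %d, band %s, %d epoch(s) averaged\n",
              nrow(x$weights), ncol(x$weights), bn, x$n_epochs_averaged))
  invisible(x)
}

#' Epoch-averaged PLI connectivity for one frequency band
#'
#' For each epoch: band-filter, extract the analytic phase, and evaluate
#' [pli_pair] for every unordered region pair; then average the per-epoch
#' matrices. The result is symmetric with zero diagonal and entries in
#' `[0, 1]`.
#'
#' @param epochs List of numeric matrices of identical shape.
#' @param band A [band_definition].
#' @param fs Sampling frequency in Hz.
#' @return A [connectivity_matrix].
#' @export
pli_matrix <- function(epochs, band, fs) {
  if (!is.list(epochs) || length(epochs) == 0L) {
    stop("epochs must be a non-empty list of matrices")
  }
  dims <- vapply(epochs, dim, integer(2L))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    stop("all epochs must share the same shape")
  }
  n_regions <- dims[2, 1]
  labels <- colnames(epochs[[1]])
  acc <- matrix(0, n_regions, n_regions)
  for (ep in epochs) {
    filtered <- bandpass_fft(ep, band, fs)
    ph <- instantaneous_phase(filtered)
    # exp(i phi) once; sin(phi_a - phi_b) = Im(z_a * Conj(z_b))
    z <- exp(1i * ph)
    for (a in seq_len(n_regions - 1L)) {
      s <- sign(Im(z[, a] * Conj(z[, (a + 1L):n_regions, drop = FALSE])))
      v <- abs(colMeans(s))
      acc[a, (a + 1L):n_regions] <- acc[a, (a + 1L):n_regions] + v
    }
  }
  acc <- acc / length(epochs)
  w <- acc + t(acc)
  connectivity_matrix(w, band = band, n_epochs_averaged = length(epochs),
                      region_labels = labels)
}
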