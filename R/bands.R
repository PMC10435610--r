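#' Frequency band definition
#'
#' A band is a half-open frequency interval `[f_lo, f_hi)` in Hz. Half-open
#' intervals guarantee that a DFT bin falling exactly on a shared edge
#' (e.g. 8 Hz between theta and lower alpha) belongs to exactly one band:
#' the higher one.
#'
#' @param name Band label.
#' @param f_lo Lower edge in Hz (inclusive), `>= 0`.
#' @param f_hi Upper edge in Hz (exclusive), `> f_lo`.
#' @return A `band_definition` object.
#' @export
#' @examples
#' band_definition("alpha1", 8, 10)
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  f_lo <- as.numeric(f_lo); f_hi <- as.numeric(f_hi)
  if (!(f_lo >= 0 && f_lo < f_hi)) {
    stop("band '", name, "': need 0 <= f_lo < f_hi, got [", f_lo, ", ", f_hi, ")")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: [%g, %g) Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Default six-band catalogue
#'
#' The canonical resting-state MEG decomposition: delta (0.5-4 Hz), theta
#' (4-8 Hz), lower alpha (8-10 Hz), upper alpha (10-13 Hz), beta
#' (13-30 Hz) and gamma (30-48 Hz).
#'
#' @return Named list of six [band_definition] objects, in layer order.
#' @export
default_bands <- function() {
  defs <- list(
    delta  = c(0.5, 4),
    theta  = c(4, 8),
    alpha1 = c(8, 10),
    alpha2 = c(10, 13),
    beta   = c(13, 30),
    gamma  = c(30, 48)
  )
  out <- lapply(names(defs), function(nm) {
    band_definition(nm, defs[[nm]][1], defs[[nm]][2])
  })
  names(out) <- names(defs)
  out
}
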