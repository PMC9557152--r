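#' @include AllClasses.R
NULL

#' Spectral-analysis configuration
#'
#' Parameters of the Welch periodogram used for dominant-frequency (DF)
#' estimation: 2-s Hamming windows with 50% overlap, zero-padded to a
#' 4096-point FFT, and a DF search band of 3-12 Hz covering the canonical
#' atrial fibrillatory range.
#'
#' @param welchWindowS Welch window length in seconds (default 2).
#' @param nfft FFT length per window (default 4096); must be at least the
#'   window length in samples.
#' @param overlapFrac fractional window overlap in [0, 1) (default 0.5).
#' @param dfBandHz numeric length-2, DF search band in Hz (default c(3, 12)).
#' @return A list of class `SpectralConfig`.
#' @export
spectralConfig <- function(welchWindowS = 2, nfft = 4096, overlapFrac = 0.5,
                           dfBandHz = c(3, 12)) {
  stopifnot(welchWindowS > 0, overlapFrac >= 0, overlapFrac < 1,
            length(dfBandHz) == 2L, dfBandHz[1L] < dfBandHz[2L])
  structure(list(welchWindowS = welchWindowS, nfft = as.integer(nfft),
                 overlapFrac = overlapFrac, dfBandHz = dfBandHz),
            class = "SpectralConfig")
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0L, n - 1L) / (n - 1L))

#' Welch power spectral density
#'
#' Averaged modified periodogram (Welch) estimate with a Hamming taper.
#' Accepts a single lead (vector) or a samples-by-leads matrix, in which case
#' all leads are transformed in one multivariate FFT call. One-sided density
#' scaling is used, so integrating the PSD over frequency approximates the
#' signal variance.
#'
#' @param x numeric vector or m x L matrix of signals.
#' @param fs sampling rate in Hz.
#' @param cfg a [spectralConfig()].
#' @return A list with `freq` (Hz) and `psd` (vector, or nfreq x L matrix for
#'   matrix input), density units power/Hz.
#' @examples
#' t <- seq(0, 5, by = 1 / 1000)
#' psd <- welchPsd(sin(2 * pi * 6 * t), fs = 1000)
#' psd$freq[which.max(psd$psd)]  # ~6 Hz
#' @export
welchPsd <- function(x, fs, cfg = spectralConfig()) {
  isVec <- is.null(dim(x))
  x <- as.matrix(x)
  m <- nrow(x); L <- ncol(x)
  wlen <- round(cfg$welchWindowS * fs)
  if (m < wlen)
    stop(sprintf("signal too short for Welch estimation: %d samples < %d window",
                 m, wlen))
  nfft <- cfg$nfft
  if (nfft < wlen)
    stop("nfft must be at least the Welch window length in samples")
  hop <- max(1L, round(wlen * (1 - cfg$overlapFrac)))
  starts <- seq.int(1L, m - wlen + 1L, by = hop)
  w <- .hamming(wlen)
  scale <- fs * sum(w^2)
  nf <- nfft %/% 2L + 1L
  acc <- matrix(0, nf, L)
  seg <- matrix(0, nfft, L)
  for (s in starts) {
    seg[seq_len(wlen), ] <- x[s:(s + wlen - 1L), , drop = FALSE] * w
    sp <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + (Mod(sp)^2) / scale
  }
  psd <- acc / length(starts)
  ## one-sided: double everything except DC and Nyquist
  psd[2:(nf - 1L), ] <- 2 * psd[2:(nf - 1L), ]
  freq <- (seq_len(nf) - 1L) * fs / nfft
  list(freq = freq, psd = if (isVec) psd[, 1L] else psd)
}

#' Dominant frequency of a signal
#'
#' The DF is the frequency of the highest Welch power-spectrum peak within
#' the configured search band (default 3-12 Hz). Ties break toward the lower
#' frequency. A flat in-band spectrum (all values equal within 1e-12) yields
#' `NA` (undefined DF).
#'
#' @inheritParams welchPsd
#' @param x numeric vector, a single-lead signal.
#' @return DF in Hz, or `NA_real_` if undefined.
#' @export
dominantFrequency <- function(x, fs, cfg = spectralConfig()) {
  as.numeric(dfMap(matrix(as.numeric(x), ncol = 1L), fs, cfg))
}

#' Per-lead dominant-frequency map
#'
#' Applies [dominantFrequency()] to every lead of a multichannel window,
#' giving the body-surface distribution of the atrial DF. Undefined DFs
#' (flat in-band spectra) propagate as `NA`.
#'
#' @param x an m x L matrix, or an \linkS4class{AASegment}.
#' @inheritParams welchPsd
#' @return Numeric vector of length L, DF per lead in Hz (`NA` = undefined).
#' @export
dfMap <- function(x, fs = NULL, cfg = spectralConfig()) {
  if (is(x, "AASegment")) {
    if (is.null(fs)) fs <- samplingRate(x)
    x <- signalMatrix(x)
  }
  if (is.null(fs)) stop("fs is required for matrix input")
  x <- as.matrix(x)
  p <- welchPsd(x, fs, cfg)
  band <- p$freq >= cfg$dfBandHz[1L] & p$freq <= cfg$dfBandHz[2L]
  if (!any(band)) stop("DF search band contains no frequency bins")
  fb <- p$freq[band]
  pb <- p$psd[band, , drop = FALSE]
  vapply(seq_len(ncol(pb)), function(l) {
    v <- pb[, l]
    if (max(v) - min(v) < 1e-12) return(NA_real_)  # flat spectrum: DF undefined
    fb[which.max(v)]                               # first max = lower frequency
  }, numeric(1L))
}
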