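#' @include AllClasses.R spectral.R geometry.R
NULL

#' Synthetic-recording configuration
#'
#' Parameters of the synthetic body-surface AF signal generator. The defaults
#' emulate the canonical acquisition: a 252-lead vest sampled at 1 kHz for
#' 1-min segments, quasi-periodic atrial f-waves with a smooth spatial
#' dominant-frequency gradient from 5 to 7 Hz, superimposed QRST complexes at
#' irregular (log-normal) RR intervals roughly eight times the atrial
#' amplitude, plus baseline wander and broadband noise. Two regimes are
#' generated: `"organized"` (temporally stable source-to-lead mixing) and
#' `"disorganized"` (the mixing takes an independent relative step of
#' `mixingDrift` at each 5-s analysis-window boundary and the source
#' fundamentals are jittered by up to `dfJitterHz`).
#'
#' @param nLeads number of vest leads (default 252).
#' @param fs sampling rate in Hz (default 1000).
#' @param durationS segment duration in seconds (default 60).
#' @param regime `"organized"` or `"disorganized"`.
#' @param dfField per-lead target dominant frequency in Hz; default a smooth
#'   spatial gradient from 5 to 7 Hz across leads.
#' @param nSources number of atrial sources (default 4).
#' @param mixingDrift per-window relative mixing change; default 0 for the
#'   organized regime, 0.3 for the disorganized regime.
#' @param dfJitterHz per-window uniform jitter of the source fundamentals;
#'   default 0 (organized) or 0.5 Hz (disorganized).
#' @param meanRrS mean RR interval in seconds (default 0.7).
#' @param rrCv coefficient of variation of the RR intervals (default 0.25).
#' @param qrstAmp ventricular-to-atrial relative amplitude (default 8).
#' @param noiseStd broadband noise level relative to the atrial amplitude
#'   (default 0.1).
#' @param baselineAmp,baselineFreq baseline-wander relative amplitude and
#'   frequency in Hz (defaults 0.2 and 0.3).
#' @param detailAmp amplitude of the weak per-lead sinusoid at the target DF
#'   field (default 0.08), adding per-lead spectral texture while keeping the
#'   organized regime effectively low-rank.
#' @param windowLenS analysis-window length the disorganized drift is aligned
#'   to (default 5).
#' @param seed integer RNG seed.
#' @return A list of class `SynthConfig`.
#' @export
synthConfig <- function(nLeads = 252L, fs = 1000, durationS = 60,
                        regime = c("organized", "disorganized"),
                        dfField = NULL, nSources = 4L, mixingDrift = NULL,
                        dfJitterHz = NULL, meanRrS = 0.7, rrCv = 0.25,
                        qrstAmp = 8, noiseStd = 0.1, baselineAmp = 0.2,
                        baselineFreq = 0.3, detailAmp = 0.08, windowLenS = 5,
                        seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(dfField)) dfField <- seq(5, 7, length.out = nLeads)
  if (length(dfField) == 1L) dfField <- rep(dfField, nLeads)
  stopifnot(length(dfField) == nLeads, all(dfField > 3), all(dfField < 12),
            rrCv >= 0, qrstAmp >= 0, noiseStd >= 0, baselineAmp >= 0,
            detailAmp >= 0, meanRrS > 0, fs > 0, durationS > 0)
  if (is.null(mixingDrift))
    mixingDrift <- if (regime == "organized") 0 else 0.3
  if (is.null(dfJitterHz))
    dfJitterHz <- if (regime == "organized") 0 else 0.5
  structure(list(nLeads = as.integer(nLeads), fs = fs, durationS = durationS,
                 regime = regime, dfField = dfField,
                 nSources = as.integer(nSources), mixingDrift = mixingDrift,
                 dfJitterHz = dfJitterHz, meanRrS = meanRrS, rrCv = rrCv,
                 qrstAmp = qrstAmp, noiseStd = noiseStd,
                 baselineAmp = baselineAmp, baselineFreq = baselineFreq,
                 detailAmp = detailAmp, windowLenS = windowLenS,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

## Median per-lead standard deviation, the generator's atrial amplitude unit.
.aaScale <- function(x) {
  mu <- colMeans(x)
  sqrt(stats::median(colMeans(x^2) - mu^2))
}

## Fast per-lead z-normalization (zero mean, unit variance columns).
.zscore <- function(x) {
  m <- nrow(x)
  x <- x - rep(colMeans(x), each = m)
  sdv <- sqrt(colSums(x^2) / (m - 1L))
  sdv[sdv < 1e-300] <- 1
  x / rep(sdv, each = m)
}

## Column-normalized frequency-proximity mixing matrix (nSources x nLeads).
.baseMixing <- function(srcF, dfField, colNorm = 0.9) {
  M <- exp(-outer(srcF, dfField, function(f, g) (f - g)^2) / (2 * 0.35^2))
  M * rep(colNorm / sqrt(colSums(M^2)), each = nrow(M))
}

## f-wave synthesis on an already-seeded RNG stream.
.genFWaves <- function(cfg, computeDf = TRUE) {
  m <- round(cfg$durationS * cfg$fs)
  tvec <- (seq_len(m) - 1L) / cfg$fs
  wlen <- round(cfg$windowLenS * cfg$fs)
  nwin <- max(1L, ceiling(m / wlen))
  rngF <- range(cfg$dfField)
  srcF <- if (diff(rngF) < 1e-12) rep(rngF[1L], cfg$nSources)
          else seq(rngF[1L], rngF[2L], length.out = cfg$nSources)
  harmAmp <- c(1, 0.5, 0.25)
  modPhase <- stats::runif(cfg$nSources, 0, 2 * pi)
  ## per-window fundamentals (phase-continuous frequency steps)
  fW <- matrix(rep(srcF, each = nwin), nwin, cfg$nSources)
  if (cfg$dfJitterHz > 0)
    fW <- fW + matrix(stats::runif(nwin * cfg$nSources, -cfg$dfJitterHz,
                                   cfg$dfJitterHz), nwin, cfg$nSources)
  winOf <- pmin((seq_len(m) - 1L) %/% wlen + 1L, nwin)
  S <- matrix(0, m, cfg$nSources)
  for (s in seq_len(cfg$nSources)) {
    finst <- fW[winOf, s]
    phase <- 2 * pi * cumsum(finst) / cfg$fs
    pmod <- 0.3 * sin(2 * pi * 0.1 * tvec + modPhase[s])  # slow phase wobble
    for (h in seq_along(harmAmp))
      S[, s] <- S[, s] + harmAmp[h] * sin(h * (phase + pmod))
  }
  M0 <- .baseMixing(srcF, cfg$dfField)
  X <- matrix(0, m, cfg$nLeads)
  M <- M0
  mixFirst <- M0
  for (w in seq_len(nwin)) {
    if (w > 1L && cfg$mixingDrift > 0) {
      step <- matrix(stats::rnorm(length(M)), nrow(M), ncol(M))
      step <- step * rep(cfg$mixingDrift * sqrt(colSums(M^2)) /
                           sqrt(colSums(step^2)), each = nrow(M))
      M <- M + step
      M <- M * rep(0.9 / sqrt(colSums(M^2)), each = nrow(M))
    }
    rows <- ((w - 1L) * wlen + 1L):min(w * wlen, m)
    X[rows, ] <- S[rows, , drop = FALSE] %*% M
  }
  if (cfg$detailAmp > 0) {
    theta <- stats::runif(cfg$nLeads, 0, 2 * pi)
    ph <- outer(tvec, 2 * pi * cfg$dfField)
    ph <- ph + rep(theta, each = m)
    X <- X + cfg$detailAmp * sin(ph)
  }
  dfRealized <- if (computeDf) dfMap(X, cfg$fs) else rep(NA_real_, cfg$nLeads)
  list(aa = X, dfField = dfRealized, sourceFreqs = srcF, mixing = mixFirst)
}

#' Generate ground-truth atrial f-waves
#'
#' Synthesizes the clean multichannel atrial activity: each source is a
#' harmonic series (fundamental f with harmonics 2f, 3f at amplitudes 1, 1/2,
#' 1/4) with slow phase modulation; lead signals are source mixtures (via a
#' frequency-proximity mixing matrix) plus a weak per-lead sinusoid at the
#' target DF field. In the organized regime the mixing is constant over time;
#' in the disorganized regime it takes an independent relative step of
#' `mixingDrift` at each analysis-window boundary and the fundamentals are
#' jittered by `dfJitterHz`.
#'
#' @param cfg a [synthConfig()].
#' @return A list with `aa` (m x n clean atrial matrix), `dfField` (realized
#'   per-lead dominant frequency of the clean matrix, the generator's DF
#'   ground truth), `sourceFreqs` and `mixing` (first-window mixing matrix).
#' @export
generateFWaves <- function(cfg = synthConfig()) {
  set.seed(cfg$seed)
  .genFWaves(cfg)
}

## Analytic QRST template: narrow Gaussians for Q/R/S plus a wide T wave,
## total ~400 ms at unit R amplitude.
.qrstTemplate <- function(fs) {
  tt <- seq(0, 0.4, by = 1 / fs)
  g <- function(a, mu, sd) a * exp(-(tt - mu)^2 / (2 * sd^2))
  g(-0.15, 0.040, 0.010) + g(1, 0.060, 0.009) + g(-0.25, 0.085, 0.012) +
    g(0.35, 0.250, 0.045)
}

#' Generate a full synthetic BSPM recording
#'
#' Adds to the ground-truth f-waves a QRST complex train at irregular RR
#' intervals (log-normal with mean `meanRrS` and coefficient of variation
#' `rrCv`), scaled to `qrstAmp` times the atrial amplitude and spatially
#' distributed by a smooth random lead pattern, plus sinusoidal baseline
#' wander and white noise. The returned ground truth enables direct testing
#' of QRST cancellation and DF recovery.
#'
#' @param cfg a [synthConfig()].
#' @return A list with `recording` (a \linkS4class{BspmRecording}) and
#'   `groundTruth`: a list with `aa` (clean atrial matrix), `rPeaks`
#'   (true R-peak sample indices), `dfField`, and `vaPattern` (per-lead QRST
#'   amplitude scaling).
#' @export
generateRecording <- function(cfg = synthConfig()) {
  if (cfg$qrstAmp > 0 && cfg$durationS < cfg$meanRrS + 0.4)
    stop("duration too short to place a single beat")
  set.seed(cfg$seed)
  ## DF ground truth needs at least one Welch window
  fw <- .genFWaves(cfg, computeDf = cfg$durationS >= 2)
  m <- nrow(fw$aa); n <- ncol(fw$aa)
  aaScale <- .aaScale(fw$aa)
  x <- fw$aa
  ## --- QRST train ---
  rPeaks <- integer(0)
  if (cfg$qrstAmp > 0) {
    tmpl <- .qrstTemplate(cfg$fs)
    if (cfg$durationS < cfg$meanRrS + 0.4)
      stop("duration too short to place a single beat")
    sdlog <- sqrt(log(1 + cfg$rrCv^2))
    mulog <- log(cfg$meanRrS) - sdlog^2 / 2
    onsets <- numeric(0)
    tcur <- stats::runif(1L, 0, cfg$meanRrS)
    while (tcur + 0.4 < cfg$durationS) {
      onsets <- c(onsets, tcur)
      tcur <- tcur + stats::rlnorm(1L, mulog, sdlog)
    }
    if (!length(onsets)) stop("duration too short to place a single beat")
    geom <- defaultVestGeometry(n)
    xy <- scale(geom@positions)
    vaPattern <- as.numeric(1 + 0.4 * xy[, 1L] * stats::rnorm(1L) +
                              0.4 * xy[, 2L] * stats::rnorm(1L))
    beatAmp <- 1 + 0.05 * stats::rnorm(length(onsets))
    scaleVA <- cfg$qrstAmp * aaScale
    for (b in seq_along(onsets)) {
      i0 <- round(onsets[b] * cfg$fs) + 1L
      idx <- i0:min(i0 + length(tmpl) - 1L, m)
      x[idx, ] <- x[idx, ] + (scaleVA * beatAmp[b]) *
        tmpl[seq_along(idx)] %o% vaPattern
    }
    rPeaks <- as.integer(round(onsets * cfg$fs) + round(0.060 * cfg$fs) + 1L)
    rPeaks <- rPeaks[rPeaks <= m]
  } else vaPattern <- rep(0, n)
  ## --- baseline wander + broadband noise ---
  tvec <- (seq_len(m) - 1L) / cfg$fs
  if (cfg$baselineAmp > 0) {
    bphase <- stats::runif(n, 0, 2 * pi)
    x <- x + (cfg$baselineAmp * aaScale) *
      sin(outer(tvec, rep(2 * pi * cfg$baselineFreq, n)) +
            matrix(bphase, m, n, byrow = TRUE))
  }
  if (cfg$noiseStd > 0)
    x <- x + matrix(stats::rnorm(m * n, sd = cfg$noiseStd * aaScale), m, n)
  rec <- BspmRecording(x, fs = cfg$fs)
  list(recording = rec,
       groundTruth = list(aa = fw$aa, rPeaks = rPeaks, dfField = fw$dfField,
                          vaPattern = vaPattern))
}

#' Generate a clean synthetic atrial-activity segment
#'
#' Convenience wrapper producing a normalized \linkS4class{AASegment} ready
#' for index computation: f-waves plus measurement noise (no ventricular
#' activity or baseline wander), per-lead z-normalized. This emulates the
#' output of the preprocessing chain on a recording whose QRST complexes were
#' cancelled perfectly, and is the unit the index-level simulations operate
#' on.
#'
#' @param cfg a [synthConfig()].
#' @return An \linkS4class{AASegment} (normalized).
#' @export
generateAASegment <- function(cfg = synthConfig()) {
  set.seed(cfg$seed)
  fw <- .genFWaves(cfg, computeDf = FALSE)
  x <- fw$aa
  if (cfg$noiseStd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = cfg$noiseStd * .aaScale(x)),
                    nrow(x), ncol(x))
  x <- .zscore(x)
  AASegment(x, fs = cfg$fs, windowLenS = cfg$windowLenS, normalized = TRUE)
}
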