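#' @include AllClasses.R geometry.R
NULL

#' Interpolate bad leads from their neighbors
#'
#' Replaces each bad-quality lead by the inverse-distance-weighted average of
#' its `K` nearest good leads on the vest grid. Good leads are untouched and
#' the quality flags are preserved in the output (so downstream stages still
#' know which leads were estimated).
#'
#' @param rec a \linkS4class{BspmRecording}.
#' @param K number of nearest good leads to average (default 4).
#' @return A \linkS4class{BspmRecording} with bad-lead signals replaced.
#' @export
interpolateBadLeads <- function(rec, K = 4L) {
  stopifnot(is(rec, "BspmRecording"))
  bad <- which(!rec@leadQuality)
  if (!length(bad)) return(rec)
  good <- which(rec@leadQuality)
  if (length(good) < ncol(rec@samples) / 2)
    stop("more than 50% of leads are bad: recording quality insufficient")
  pos <- rec@geometry@positions
  x <- rec@samples
  for (b in bad) {
    d <- sqrt(rowSums((pos[good, , drop = FALSE] -
                         matrix(pos[b, ], length(good), 2L, byrow = TRUE))^2))
    nn <- good[order(d)][seq_len(min(K, length(good)))]
    dd <- d[order(d)][seq_len(min(K, length(good)))]
    w <- if (any(dd < 1e-12)) as.numeric(dd < 1e-12) else 1 / dd
    w <- w / sum(w)
    x[, b] <- x[, nn, drop = FALSE] %*% w
  }
  BspmRecording(x, fs = rec@fs, geometry = rec@geometry,
                leadQuality = rec@leadQuality, rPeaks = rec@rPeaks)
}

## Zero-phase Butterworth filtering of every column of a matrix.
.filtfiltMat <- function(x, filt) {
  apply(x, 2L, function(col) signal::filtfilt(filt, col))
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass, implemented as a
#' high-pass / low-pass cascade for numerical robustness at the very low
#' normalized corner frequency (1 Hz at 1 kHz sampling). Removes baseline
#' drift below `lowHz` and high-frequency noise above `highHz`.
#'
#' @param rec a \linkS4class{BspmRecording}.
#' @param lowHz,highHz band edges in Hz (defaults 1 and 30).
#' @param order Butterworth order of each cascade stage before the
#'   forward-backward pass (defaults 2 high-pass, 4 low-pass).
#' @return The filtered \linkS4class{BspmRecording}.
#' @export
bandpassRecording <- function(rec, lowHz = 1, highHz = 30, order = c(2L, 4L)) {
  stopifnot(is(rec, "BspmRecording"))
  if (rec@fs <= 2 * highHz)
    stop("sampling rate must exceed twice the upper band edge")
  hp <- signal::butter(order[1L], lowHz / (rec@fs / 2), type = "high")
  lp <- signal::butter(order[2L], highHz / (rec@fs / 2), type = "low")
  x <- .filtfiltMat(rec@samples, hp)
  x <- .filtfiltMat(x, lp)
  BspmRecording(x, fs = rec@fs, geometry = rec@geometry,
                leadQuality = rec@leadQuality, rPeaks = rec@rPeaks)
}

#' Detect R-peaks on a reference lead
#'
#' Pan-Tompkins-style energy detector: the reference lead (highest-RMS lead
#' by default) is differentiated, squared, and integrated over a 150-ms
#' moving window; local maxima of the integrated energy separated by a
#' refractory period of at least 200 ms and exceeding an adaptive threshold
#' (40% of the median of the strongest candidate peaks) mark beats. Each
#' detection is refined to the absolute-amplitude maximum of the reference
#' lead within +/- 80 ms. Expects a band-passed recording.
#'
#' @param rec a \linkS4class{BspmRecording} (band-pass filtered).
#' @param refLead reference lead index; default the highest-RMS lead.
#' @param refractoryS minimum inter-beat spacing in seconds (default 0.2).
#' @return Strictly increasing integer vector of R-peak sample indices;
#'   empty (with a warning on long recordings) if no beats are found.
#' @export
detectRPeaks <- function(rec, refLead = NULL, refractoryS = 0.2) {
  stopifnot(is(rec, "BspmRecording"))
  x <- rec@samples
  fs <- rec@fs
  if (is.null(refLead))
    refLead <- which.max(sqrt(colMeans(x^2)))
  sig <- x[, refLead]
  if (max(abs(sig)) < 1e-12) return(integer(0))
  energy <- c(0, diff(sig))^2
  intLen <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / intLen, intLen),
                                    sides = 2L))
  integ[is.na(integ)] <- 0
  refr <- max(1L, round(refractoryS * fs))
  ## local maxima with minimum spacing (greedy by amplitude)
  ord <- order(integ, decreasing = TRUE)
  taken <- logical(length(integ))
  cand <- integer(0)
  for (i in ord) {
    if (integ[i] <= 0) break
    if (taken[i]) next
    cand <- c(cand, i)
    lo <- max(1L, i - refr); hi <- min(length(integ), i + refr)
    taken[lo:hi] <- TRUE
    if (length(cand) > 2 * (nrow(x) / fs) / refractoryS) break
  }
  if (!length(cand)) {
    if (nrow(x) / fs >= 10) warning("no beats detected")
    return(integer(0))
  }
  topAmp <- stats::median(integ[cand][seq_len(min(10L, length(cand)))])
  thr <- 0.4 * topAmp
  peaks <- sort(cand[integ[cand] >= thr])
  if (!length(peaks)) {
    if (nrow(x) / fs >= 10) warning("no beats detected")
    return(integer(0))
  }
  ## refine to the reference-lead absolute maximum within +/- 80 ms
  half <- round(0.080 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(length(sig), p + half)
    as.integer(lo + which.max(abs(sig[lo:hi])) - 1L)
  }, integer(1L))
  refined <- sort(unique(refined))
  ## enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refr)
  }
  as.integer(refined)
}

#' Delineate and cluster QRST complexes
#'
#' Extracts a fixed window around each R-peak (default -80 ms to +400 ms;
#' beats whose window does not fit inside the recording are dropped),
#' clusters beats by the correlation distance of their concatenated
#' multi-lead shapes (hierarchical, complete linkage, cut to `nClusters`),
#' merges clusters with fewer than `minBeats` members into the nearest
#' cluster, and computes per-cluster, per-lead ensemble-average templates.
#'
#' @param rec a band-passed \linkS4class{BspmRecording}.
#' @param rPeaks integer R-peak sample indices (>= 2 beats).
#' @param nClusters target number of shape clusters (default 2).
#' @param preMs,postMs window extent around the R-peak in ms (defaults 80 and
#'   400).
#' @param minBeats minimum cluster size before merging (default 3).
#' @param mergeCorr clusters whose ensemble templates correlate above this
#'   are collapsed into one (default 0.9), so a single beat morphology yields
#'   a single effective cluster; genuinely distinct morphologies (ectopy,
#'   polarity flips) correlate far below this.
#' @return A list of class `BeatSet`: `rPeaks`, `qrstWindows` (beats x 2
#'   onset/offset matrix, untrimmed), `clusterLabels`, `templates` (list of
#'   window-length x leads matrices), `preSamples`.
#' @export
delineateAndCluster <- function(rec, rPeaks, nClusters = 2L, preMs = 80,
                                postMs = 400, minBeats = 3L,
                                mergeCorr = 0.9) {
  stopifnot(is(rec, "BspmRecording"))
  if (length(rPeaks) < 2L) stop("delineation requires at least 2 beats")
  fs <- rec@fs
  pre <- round(preMs / 1000 * fs); post <- round(postMs / 1000 * fs)
  m <- nrow(rec@samples)
  keep <- rPeaks - pre >= 1L & rPeaks + post <= m
  rPeaks <- rPeaks[keep]
  if (length(rPeaks) < 2L) stop("fewer than 2 complete beats inside the recording")
  wlen <- pre + post + 1L
  nb <- length(rPeaks)
  n <- ncol(rec@samples)
  beats <- array(0, c(wlen, n, nb))
  for (b in seq_len(nb))
    beats[, , b] <- rec@samples[(rPeaks[b] - pre):(rPeaks[b] + post), ]
  feat <- matrix(beats, wlen * n, nb)  # concatenated multi-lead shapes
  nClusters <- min(nClusters, nb)
  if (nClusters <= 1L) {
    labels <- rep(1L, nb)
  } else {
    C <- suppressWarnings(stats::cor(feat))
    C[!is.finite(C)] <- 0
    labels <- stats::cutree(stats::hclust(stats::as.dist(1 - C),
                                          method = "complete"), k = nClusters)
  }
  ## merge clusters smaller than minBeats into the nearest (by template
  ## correlation) larger cluster
  repeat {
    sizes <- table(labels)
    small <- as.integer(names(sizes)[sizes < minBeats])
    big <- as.integer(names(sizes)[sizes >= minBeats])
    if (!length(small) || !length(big)) break
    tmplOf <- function(cl) rowMeans(feat[, labels == cl, drop = FALSE])
    s <- small[1L]
    sims <- vapply(big, function(cl)
      suppressWarnings(stats::cor(tmplOf(s), tmplOf(cl))), numeric(1L))
    sims[!is.finite(sims)] <- -1
    labels[labels == s] <- big[which.max(sims)]
  }
  ## merge clusters whose ensemble templates are effectively the same shape
  ## (correlation > mergeCorr): forcing distinct ensembles for one morphology
  ## would only dilute each average with coherent atrial activity. The
  ## comparison is restricted to the high-amplitude samples of the pooled
  ## template (ventricular-dominated, least contaminated by retained atrial
  ## signal); genuinely distinct morphologies differ exactly there.
  pooled <- abs(rowMeans(feat))
  mask <- pooled >= stats::quantile(pooled, 0.7)
  if (sum(mask) < 100L) mask <- rep(TRUE, length(pooled))
  repeat {
    cls <- sort(unique(labels))
    if (length(cls) <= 1L) break
    tm <- vapply(cls, function(cl)
      rowMeans(feat[mask, labels == cl, drop = FALSE]), numeric(sum(mask)))
    TC <- suppressWarnings(stats::cor(tm))
    TC[!is.finite(TC)] <- 0
    diag(TC) <- -1
    top <- which(TC == max(TC), arr.ind = TRUE)[1L, ]
    if (TC[top[1L], top[2L]] <= mergeCorr) break
    labels[labels == cls[top[2L]]] <- cls[top[1L]]
  }
  labels <- as.integer(factor(labels))
  templates <- lapply(seq_len(max(labels)), function(cl) {
    idx <- which(labels == cl)
    matrix(rowMeans(feat[, idx, drop = FALSE]), wlen, n)
  })
  structure(list(rPeaks = rPeaks,
                 qrstWindows = cbind(onset = rPeaks - pre,
                                     offset = rPeaks + post),
                 clusterLabels = labels, templates = templates,
                 preSamples = pre),
            class = "BeatSet")
}

#' Spatiotemporal QRST cancellation
#'
#' For each beat, the cluster's ensemble-average template is aligned to the
#' observed multi-lead complex by an integer time-shift search (+/- 20 ms)
#' and fitted by a least-squares spatial transform, then subtracted. The
#' default spatial transform is a per-lead scalar scale
#' (`a_l = <x_l, t_l> / <t_l, t_l>`); with `spatialOrder > 1` each lead is
#' instead fitted on the leading `spatialOrder` temporal principal components
#' of the template, a low-order lead-mixing generalization. Beat windows are
#' trimmed at the next beat's onset so subtractions never overlap; a beat
#' whose trimmed window is shorter than half the template is skipped with a
#' warning.
#'
#' @param rec a band-passed \linkS4class{BspmRecording}.
#' @param beats a `BeatSet` from [delineateAndCluster()].
#' @param spatialOrder order of the spatial fit (default 1 = per-lead scale).
#' @param maxShiftMs time-shift search half-range in ms (default 20).
#' @param details if TRUE, return a list with the segment and a per-beat fit
#'   table (`beat`, `shift`, `medianScale`).
#' @return An \linkS4class{AASegment} (not yet normalized) covering the same
#'   samples as the input, or a list when `details = TRUE`.
#' @export
cancelQRST <- function(rec, beats, spatialOrder = 1L, maxShiftMs = 20,
                       details = FALSE) {
  stopifnot(is(rec, "BspmRecording"), inherits(beats, "BeatSet"))
  x <- rec@samples
  fs <- rec@fs
  maxShift <- round(maxShiftMs / 1000 * fs)
  nb <- length(beats$rPeaks)
  fits <- data.frame(beat = integer(0), shift = integer(0),
                     medianScale = numeric(0))
  for (b in seq_len(nb)) {
    tmpl <- beats$templates[[beats$clusterLabels[b]]]
    wlen <- nrow(tmpl)
    onset <- beats$qrstWindows[b, 1L]
    limit <- if (b < nb) beats$qrstWindows[b + 1L, 1L] - 1L else nrow(x)
    ## shift search: maximize the per-lead-scale explained energy
    best <- NULL
    for (sh in -maxShift:maxShift) {
      i0 <- onset + sh
      i1 <- min(i0 + wlen - 1L, limit, nrow(x))
      if (i0 < 1L) next
      len <- i1 - i0 + 1L
      if (len < wlen / 2) next
      xw <- x[i0:i1, , drop = FALSE]
      tw <- tmpl[seq_len(len), , drop = FALSE]
      num <- colSums(xw * tw)
      den <- colSums(tw^2)
      ok <- den > 1e-24
      gain <- sum(num[ok]^2 / den[ok])
      if (is.null(best) || gain > best$gain)
        best <- list(gain = gain, i0 = i0, i1 = i1, len = len)
    }
    if (is.null(best)) {
      warning(sprintf("beat %d skipped: template does not fit the inter-beat interval", b))
      next
    }
    xw <- x[best$i0:best$i1, , drop = FALSE]
    tw <- tmpl[seq_len(best$len), , drop = FALSE]
    if (spatialOrder <= 1L) {
      den <- colSums(tw^2)
      a <- ifelse(den > 1e-24, colSums(xw * tw) / den, 0)
      x[best$i0:best$i1, ] <- xw - tw * rep(a, each = best$len)
      med <- stats::median(a)
    } else {
      sv <- svd(tw, nu = spatialOrder, nv = 0L)
      U <- sv$u
      x[best$i0:best$i1, ] <- xw - U %*% crossprod(U, xw)
      med <- NA_real_
    }
    fits <- rbind(fits, data.frame(beat = b, shift = best$i0 - onset,
                                   medianScale = med))
  }
  seg <- AASegment(x, fs = fs, normalized = FALSE)
  if (details) list(segment = seg, fits = fits) else seg
}

#' Normalize and smooth an atrial-activity segment
#'
#' Per-lead z-normalization over the full segment, followed by a zero-phase
#' 10th-order Butterworth low-pass at `cutoffHz` (default 30 Hz) to remove
#' discontinuities introduced by template subtraction, and a final
#' re-standardization so each lead ends with exactly zero mean and unit
#' variance. Constant-valued
#' (zero-variance) leads are left at zero and flagged; the call errors if
#' more than 10% of leads are constant.
#'
#' @param seg an \linkS4class{AASegment} after cancellation.
#' @param cutoffHz low-pass cutoff in Hz (default 30).
#' @return A normalized \linkS4class{AASegment}. Constant-lead indices, if
#'   any, are recorded in the `constantLeads` attribute.
#' @export
finalizeSegment <- function(seg, cutoffHz = 30) {
  stopifnot(is(seg, "AASegment"))
  x <- seg@samples
  sds <- apply(x, 2L, stats::sd)
  const <- which(sds < 1e-12)
  if (length(const) > 0.1 * ncol(x))
    stop("more than 10% of leads are constant-valued")
  live <- setdiff(seq_len(ncol(x)), const)
  x[, live] <- scale(x[, live, drop = FALSE])
  x[, const] <- 0
  ## order-5 forward-backward pass = 10th-order zero-phase magnitude response
  lp <- signal::butter(5L, cutoffHz / (seg@fs / 2), type = "low")
  x <- .filtfiltMat(x, lp)
  ## re-standardize: the low-pass removes a little out-of-band power, so a
  ## second pass restores the exact zero-mean / unit-variance contract
  x[, live] <- .zscore(x[, live, drop = FALSE])
  x[, const] <- 0
  out <- AASegment(x, fs = seg@fs, windowLenS = seg@windowLenS,
                   normalized = TRUE)
  attr(out, "constantLeads") <- const
  out
}

#' Full preprocessing chain
#'
#' Convenience wrapper running bad-lead interpolation, 1-30 Hz band-pass
#' filtering, R-peak detection, QRST delineation/clustering, spatiotemporal
#' QRST cancellation, and final normalization, yielding an analysis-ready
#' atrial-activity segment.
#'
#' @param rec a raw \linkS4class{BspmRecording}.
#' @param nClusters beat-shape clusters for the ensemble averages (default 2).
#' @param spatialOrder spatial fit order for cancellation (default 1).
#' @return A normalized \linkS4class{AASegment}.
#' @export
preprocessRecording <- function(rec, nClusters = 2L, spatialOrder = 1L) {
  rec <- interpolateBadLeads(rec)
  rec <- bandpassRecording(rec)
  peaks <- detectRPeaks(rec)
  if (length(peaks) >= 2L) {
    beats <- delineateAndCluster(rec, peaks, nClusters = nClusters)
    seg <- cancelQRST(rec, beats, spatialOrder = spatialOrder)
  } else {
    seg <- AASegment(rec@samples, fs = rec@fs)
  }
  finalizeSegment(seg)
}
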