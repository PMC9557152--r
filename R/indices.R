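#' @include AllClasses.R reconstruct.R windows.R
NULL

#' Index-computation configuration
#'
#' Settings for the segment-level spatiotemporal indices: the analysis window
#' length, which electrode subsets to evaluate, the number of principal
#' components defining the NDI, and the admissible greedy-subset size range.
#'
#' @param windowLenS analysis window length in seconds; `NULL` (default)
#'   inherits the segment's own window length (5 s for canonical segments).
#' @param subsetKinds character vector from `c("SEQ8", "SEQ11", "ECG8",
#'   "ECG11")` (all by default); `"SEQk"` entries like `"SEQ15"` are also
#'   accepted.
#' @param ndiComponents principal components retained by the NDI (default 3).
#' @param seqKRange admissible greedy-subset sizes, default `c(8, 30)`.
#' @return A list of class `IndexConfig`.
#' @export
indexConfig <- function(windowLenS = NULL,
                        subsetKinds = c("SEQ8", "SEQ11", "ECG8", "ECG11"),
                        ndiComponents = 3L, seqKRange = c(8L, 30L)) {
  stopifnot(is.null(windowLenS) || windowLenS > 0, ndiComponents >= 1L)
  structure(list(windowLenS = windowLenS, subsetKinds = subsetKinds,
                 ndiComponents = as.integer(ndiComponents),
                 seqKRange = as.integer(seqKRange)),
            class = "IndexConfig")
}

## Resolve a subset kind label ("SEQ8", "ECG11", ...) to (family, k).
.parseKind <- function(label) {
  if (label == "ECG8") return(list(family = "ECG8", k = 8L))
  if (label == "ECG11") return(list(family = "ECG11", k = 11L))
  if (grepl("^SEQ[0-9]+$", label))
    return(list(family = "SEQ", k = as.integer(sub("SEQ", "", label))))
  stop("unknown subset kind: ", label)
}

## Anchor-window machinery shared by the two ER indices: select the subset
## (greedy for SEQ, fixed leads for ECG) on window 1 and fit A there.
.anchorSubset <- function(wins, family, k, geometry) {
  X1 <- wins[[1L]]
  if (family == "SEQ") {
    sub <- sequentialSelect(X1, k)
    attr(sub, "stepErrors") <- NULL
    sub
  } else {
    idx <- if (family == "ECG8") geometry@ecg8 else geometry@ecg11
    if (length(idx) != k)
      stop(sprintf("%s subset must contain %d leads", family, k))
    ElectrodeSubset(idx, kind = family, mixing = pinvFit(X1, idx))
  }
}

#' Segment-level temporal error-ratio index ER_NRMSE
#'
#' On the first 5-s window of the segment, the electrode subset is selected
#' (greedy SEQ) or fixed (ECG analogues) and the least-squares mixing matrix
#' `A1` is fitted. On each subsequent window `i`, the index is the ratio of
#' the anchored subset-reconstruction error to that window's optimal rank-k
#' PCA error,
#' `ER_NRMSE_i = ||X_i - Xhat_i||_F / ||X_i - X_k,i||_F`,
#' averaged over windows 2..W. By the Eckart-Young theorem the ratio is
#' always >= 1; values near 1 indicate temporally stable AF dynamics (the
#' anchor-window subset keeps reconstructing later windows near-optimally),
#' larger values indicate instability.
#'
#' @param segment an \linkS4class{AASegment} with at least 2 windows.
#' @param subsetKind `"SEQ"`, `"ECG8"` or `"ECG11"`.
#' @param k subset size (forced to 8/11 for the ECG kinds).
#' @param geometry \linkS4class{VestGeometry} for the ECG-analogue leads;
#'   default matches the segment.
#' @param cfg an [indexConfig()].
#' @return A list with `value` (mean over windows), `perWindow`,
#'   `excludedWindows` (indices with a degenerate PCA denominator) and
#'   `subset` (the fitted \linkS4class{ElectrodeSubset}).
#' @export
erNrmseSegment <- function(segment, subsetKind = "SEQ", k = 8L,
                           geometry = NULL, cfg = indexConfig()) {
  stopifnot(is(segment, "AASegment"))
  family <- match.arg(subsetKind, c("SEQ", "ECG8", "ECG11"))
  if (family == "ECG8") k <- 8L else if (family == "ECG11") k <- 11L
  k <- as.integer(k)
  if (family == "SEQ" && (k < cfg$seqKRange[1L] || k > cfg$seqKRange[2L]))
    stop(sprintf("SEQ subset size must lie in [%d, %d]",
                 cfg$seqKRange[1L], cfg$seqKRange[2L]))
  wins <- segmentWindows(segment, cfg$windowLenS)
  if (length(wins) < 2L) stop("segment must contain at least 2 windows")
  if (is.null(geometry)) geometry <- defaultVestGeometry(numLeads(segment))
  sub <- .anchorSubset(wins, family, k, geometry)
  ratios <- rep(NA_real_, length(wins) - 1L)
  for (i in 2:length(wins)) {
    Xi <- wins[[i]]
    num <- sqrt(sum((Xi - Xi[, sub@leadIndices, drop = FALSE] %*% sub@mixing)^2))
    den <- .pcaFrobError(sort(.sigma2(Xi), decreasing = TRUE), k)
    if (den < 1e-12) next  # degenerate denominator: exclude this window
    ratios[i - 1L] <- num / den
  }
  ok <- !is.na(ratios)
  if (!any(ok))
    stop("ER_NRMSE undefined: all windows had a degenerate PCA denominator")
  list(value = mean(ratios[ok]), perWindow = ratios,
       excludedWindows = which(!ok) + 1L, subset = sub)
}

#' Segment-level dominant-frequency error-ratio index ER_ABSE
#'
#' Same anchoring protocol as [erNrmseSegment()], but the per-window ratio
#' compares dominant-frequency errors: the sum over leads of
#' `|DF(X_i) - DF(Xhat_i)|` for the anchored subset reconstruction, divided
#' by the same sum for the rank-k PCA reconstruction, averaged over windows
#' 2..W. Leads with an undefined DF in any of the three matrices are excluded
#' from both sums. A window with zero denominator and zero numerator scores
#' ratio 1; a window with zero denominator and positive numerator is excluded
#' and counted. If every window is excluded the index is `NA` (flagged
#' absent).
#'
#' @inheritParams erNrmseSegment
#' @param spectral a [spectralConfig()] for the DF estimation.
#' @return A list with `value` (possibly `NA`), `perWindow`,
#'   `excludedWindows` and `subset`.
#' @export
erAbseSegment <- function(segment, subsetKind = "SEQ", k = 8L,
                          geometry = NULL, cfg = indexConfig(),
                          spectral = spectralConfig()) {
  stopifnot(is(segment, "AASegment"))
  family <- match.arg(subsetKind, c("SEQ", "ECG8", "ECG11"))
  if (family == "ECG8") k <- 8L else if (family == "ECG11") k <- 11L
  k <- as.integer(k)
  wins <- segmentWindows(segment, cfg$windowLenS)
  if (length(wins) < 2L) stop("segment must contain at least 2 windows")
  if (is.null(geometry)) geometry <- defaultVestGeometry(numLeads(segment))
  fs <- samplingRate(segment)
  sub <- .anchorSubset(wins, family, k, geometry)
  ratios <- rep(NA_real_, length(wins) - 1L)
  for (i in 2:length(wins)) {
    Xi <- wins[[i]]
    xHatSub <- Xi[, sub@leadIndices, drop = FALSE] %*% sub@mixing
    V <- .topRightVectors(Xi, k)
    xHatPca <- Xi %*% V %*% t(V)
    dfX <- dfMap(Xi, fs, spectral)
    dfS <- dfMap(xHatSub, fs, spectral)
    dfP <- dfMap(xHatPca, fs, spectral)
    ok <- !is.na(dfX) & !is.na(dfS) & !is.na(dfP)
    if (!any(ok)) next
    num <- sum(abs(dfX[ok] - dfS[ok]))
    den <- sum(abs(dfX[ok] - dfP[ok]))
    if (den == 0) {
      if (num == 0) ratios[i - 1L] <- 1  # both DF-perfect: ratio 1 by policy
      next                               # else excluded, counted
    }
    ratios[i - 1L] <- num / den
  }
  ok <- !is.na(ratios)
  list(value = if (any(ok)) mean(ratios[ok]) else NA_real_,
       perWindow = ratios, excludedWindows = which(!ok) + 1L, subset = sub)
}

#' Non-dipolar component index (NDI)
#'
#' Per 5-s window, the fraction of signal variance not captured by the first
#' `ndiComponents` (default 3) principal components of the column-centered
#' window matrix:
#' `NDI_w = 1 - sum_{j<=3} sigma_j^2 / sum_j sigma_j^2`.
#' The segment NDI is the mean over windows; it lies in [0, 1], is
#' subset-independent, and is invariant to lead permutation and global
#' amplitude scaling.
#'
#' @inheritParams erNrmseSegment
#' @return A list with `value`, `perWindow` and `excludedWindows`
#'   (zero-energy windows).
#' @export
ndiSegment <- function(segment, cfg = indexConfig()) {
  stopifnot(is(segment, "AASegment"))
  wins <- segmentWindows(segment, cfg$windowLenS)
  p <- cfg$ndiComponents
  vals <- rep(NA_real_, length(wins))
  for (i in seq_along(wins)) {
    Xc <- scale(wins[[i]], center = TRUE, scale = FALSE)
    s2 <- sort(.sigma2(Xc), decreasing = TRUE)
    tot <- sum(s2)
    if (tot < 1e-24) next  # zero-energy window: exclude
    vals[i] <- 1 - sum(s2[seq_len(min(p, length(s2)))]) / tot
  }
  ok <- !is.na(vals)
  if (!any(ok)) stop("NDI undefined: all windows have zero energy")
  list(value = mean(vals[ok]), perWindow = vals, excludedWindows = which(!ok))
}

#' Compute all segment-level indices
#'
#' Evaluates ER_NRMSE and (optionally) ER_ABSE for every requested subset
#' kind, plus the subset-independent NDI, returning one table row per subset
#' kind. The NDI column repeats the shared segment value on every row.
#'
#' @inheritParams erNrmseSegment
#' @param patientId,segmentId opaque labels copied into the output rows.
#' @param outcome outcome label: `"SR"`, `"AR"` or `"UNKNOWN"`.
#' @param computeAbse compute ER_ABSE as well (slower; default TRUE).
#' @param spectral a [spectralConfig()].
#' @return data.frame with columns `patient_id`, `segment_id`, `subset_kind`,
#'   `k`, `er_nrmse`, `er_abse`, `ndi`, `outcome`.
#' @export
computeAllIndices <- function(segment, cfg = indexConfig(), geometry = NULL,
                              patientId = "p1", segmentId = "s1",
                              outcome = "UNKNOWN", computeAbse = TRUE,
                              spectral = spectralConfig()) {
  stopifnot(is(segment, "AASegment"))
  if (is.null(geometry)) geometry <- defaultVestGeometry(numLeads(segment))
  ndi <- ndiSegment(segment, cfg)$value
  rows <- lapply(cfg$subsetKinds, function(label) {
    pk <- .parseKind(label)
    ern <- erNrmseSegment(segment, pk$family, pk$k, geometry, cfg)$value
    era <- if (computeAbse)
      erAbseSegment(segment, pk$family, pk$k, geometry, cfg, spectral)$value
    else NA_real_
    data.frame(patient_id = patientId, segment_id = segmentId,
               subset_kind = label, k = pk$k, er_nrmse = ern, er_abse = era,
               ndi = ndi, outcome = outcome, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
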