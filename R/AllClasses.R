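#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## VestGeometry
## ---------------------------------------------------------------------------

#' Electrode-vest geometry
#'
#' Describes a body-surface mapping vest: the number of unipolar electrodes
#' (leads), their 2-D coordinates on an unrolled anterior+posterior torso grid
#' (arbitrary units), and the lead indices of the standard-ECG-analogue subsets
#' ECG8 (precordial V1-V6 analogues plus two limb-equivalent leads) and ECG11
#' (ECG8 plus three posterior leads, V8/V9/V10 analogues). Lead indices are
#' 1-based throughout, matching vest lead labels.
#'
#' @slot nLeads integer, number of leads (252 for the default vest).
#' @slot positions numeric matrix, nLeads x 2, per-lead (x, y) coordinates.
#' @slot ecg8 integer vector of 8 unique lead indices.
#' @slot ecg11 integer vector of 11 unique lead indices; a superset of ecg8.
#'
#' @seealso [defaultVestGeometry()], [readGeometry()]
#' @export
setClass("VestGeometry",
  representation(
    nLeads = "integer",
    positions = "matrix",
    ecg8 = "integer",
    ecg11 = "integer"
  )
)

setValidity("VestGeometry", function(object) {
  msg <- character()
  n <- object@nLeads
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "nLeads must be a single positive integer")
  if (!is.numeric(object@positions) || ncol(object@positions) != 2L ||
      nrow(object@positions) != n)
    msg <- c(msg, "positions must be an nLeads x 2 numeric matrix")
  if (!(length(object@ecg8) %in% c(0L, 8L)) || anyDuplicated(object@ecg8))
    msg <- c(msg, "ecg8 must hold 8 unique lead indices (or be empty)")
  if (!(length(object@ecg11) %in% c(0L, 11L)) || anyDuplicated(object@ecg11))
    msg <- c(msg, "ecg11 must hold 11 unique lead indices (or be empty)")
  idx <- c(object@ecg8, object@ecg11)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    msg <- c(msg, "ECG-analogue lead indices must lie in [1, nLeads]")
  if (!all(object@ecg8 %in% object@ecg11))
    msg <- c(msg, "ecg8 must be a subset of ecg11")
  if (length(msg)) msg else TRUE
})

#' @describeIn VestGeometry lead count.
#' @param object a `VestGeometry`.
#' @export
setMethod("numLeads", "VestGeometry", function(object) object@nLeads)

setMethod("show", "VestGeometry", function(object) {
  cat("VestGeometry:", object@nLeads, "leads\n")
  cat("  ECG8 analogue leads: ", paste(object@ecg8, collapse = ", "), "\n")
  cat("  ECG11 analogue leads:", paste(object@ecg11, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## BspmRecording
## ---------------------------------------------------------------------------

#' A raw multichannel body-surface recording
#'
#' Holds an m-samples by n-leads signal matrix (millivolt scale), the sampling
#' rate, per-lead quality flags, the vest geometry, and optional beat
#' annotations (R-peak sample indices).
#'
#' @slot samples numeric matrix, m x n.
#' @slot fs sampling rate in Hz.
#' @slot leadQuality logical vector of length n; TRUE = good lead.
#' @slot geometry a \linkS4class{VestGeometry} with nLeads == n.
#' @slot rPeaks integer vector of R-peak sample indices (possibly empty).
#'
#' @seealso [BspmRecording()], [readRecording()], [generateRecording()]
#' @export
setClass("BspmRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    leadQuality = "logical",
    geometry = "VestGeometry",
    rPeaks = "integer"
  )
)

setValidity("BspmRecording", function(object) {
  msg <- character()
  m <- nrow(object@samples); n <- ncol(object@samples)
  if (m < 1L) msg <- c(msg, "recording must contain at least one sample")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (n != object@geometry@nLeads)
    msg <- c(msg, sprintf("lead count %d does not match geometry (%d leads)",
                          n, object@geometry@nLeads))
  if (length(object@leadQuality) != n)
    msg <- c(msg, "leadQuality must have one flag per lead")
  if (length(object@rPeaks) &&
      (min(object@rPeaks) < 1L || max(object@rPeaks) > m))
    msg <- c(msg, "annotation indices must lie within the recording")
  if (length(msg)) msg else TRUE
})

#' Construct a BspmRecording
#'
#' @param samples numeric matrix, time samples x leads.
#' @param fs sampling rate in Hz (default 1000).
#' @param geometry a \linkS4class{VestGeometry}; default built to match the
#'   lead count (the canonical 252-lead vest when `ncol(samples) == 252`).
#' @param leadQuality logical per-lead quality flags; default all good.
#' @param rPeaks optional integer R-peak sample indices.
#' @return A \linkS4class{BspmRecording}.
#' @export
BspmRecording <- function(samples, fs = 1000, geometry = NULL,
                          leadQuality = NULL, rPeaks = integer()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(geometry)) geometry <- defaultVestGeometry(ncol(samples))
  if (is.null(leadQuality)) leadQuality <- rep(TRUE, ncol(samples))
  new("BspmRecording", samples = samples, fs = as.numeric(fs),
      leadQuality = as.logical(leadQuality), geometry = geometry,
      rPeaks = as.integer(rPeaks))
}

#' @describeIn BspmRecording the m x n signal matrix.
#' @param object a `BspmRecording`.
#' @export
setMethod("signalMatrix", "BspmRecording", function(object) object@samples)

#' @describeIn BspmRecording sampling rate in Hz.
#' @export
setMethod("samplingRate", "BspmRecording", function(object) object@fs)

#' @describeIn BspmRecording number of leads.
#' @export
setMethod("numLeads", "BspmRecording", function(object) ncol(object@samples))

setMethod("show", "BspmRecording", function(object) {
  m <- nrow(object@samples)
  cat(sprintf("BspmRecording: %d leads, %.1f s @ %g Hz\n",
              ncol(object@samples), m / object@fs, object@fs))
  nbad <- sum(!object@leadQuality)
  if (nbad) cat("  bad leads:", nbad, "\n")
  if (length(object@rPeaks)) cat("  annotated R-peaks:", length(object@rPeaks), "\n")
})

## ---------------------------------------------------------------------------
## AASegment
## ---------------------------------------------------------------------------

#' An atrial-activity segment
#'
#' A ventricular-activity-free (post-QRST-cancellation) multichannel segment,
#' canonically 1 minute long, analyzed in non-overlapping windows (default
#' 5 s). After [finalizeSegment()] each lead has zero mean and unit variance
#' over the full segment (`normalized = TRUE`).
#'
#' @slot samples numeric matrix, m x n atrial-activity signals.
#' @slot fs sampling rate in Hz.
#' @slot windowLenS analysis window length in seconds (default 5).
#' @slot normalized logical; TRUE once per-lead z-normalization was applied.
#'
#' @seealso [AASegment()], [cancelQRST()], [finalizeSegment()],
#'   [segmentWindows()]
#' @export
setClass("AASegment",
  representation(
    samples = "matrix",
    fs = "numeric",
    windowLenS = "numeric",
    normalized = "logical"
  )
)

setValidity("AASegment", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@windowLenS) != 1L || object@windowLenS <= 0)
    msg <- c(msg, "windowLenS must be a single positive number")
  if (isTRUE(object@normalized)) {
    mu <- colMeans(object@samples)
    if (max(abs(mu)) >= 1e-9)
      msg <- c(msg, "normalized segment must have per-lead |mean| < 1e-9")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AASegment
#'
#' @param samples numeric matrix of atrial-activity signals, samples x leads.
#' @param fs sampling rate in Hz (default 1000).
#' @param windowLenS analysis window length in seconds (default 5).
#' @param normalized whether per-lead z-normalization has been applied.
#' @return An \linkS4class{AASegment}.
#' @export
AASegment <- function(samples, fs = 1000, windowLenS = 5, normalized = FALSE) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  new("AASegment", samples = samples, fs = as.numeric(fs),
      windowLenS = as.numeric(windowLenS), normalized = isTRUE(normalized))
}

#' @describeIn AASegment the m x n atrial-activity matrix.
#' @param object an `AASegment`.
#' @export
setMethod("signalMatrix", "AASegment", function(object) object@samples)

#' @describeIn AASegment sampling rate in Hz.
#' @export
setMethod("samplingRate", "AASegment", function(object) object@fs)

#' @describeIn AASegment number of leads.
#' @export
setMethod("numLeads", "AASegment", function(object) ncol(object@samples))

setMethod("show", "AASegment", function(object) {
  cat(sprintf("AASegment: %d leads, %.1f s @ %g Hz (%d windows of %g s)%s\n",
              ncol(object@samples), nrow(object@samples) / object@fs,
              object@fs,
              nrow(object@samples) %/% round(object@windowLenS * object@fs),
              object@windowLenS,
              if (object@normalized) ", normalized" else ""))
})

## ---------------------------------------------------------------------------
## ElectrodeSubset
## ---------------------------------------------------------------------------

#' An electrode subset with its anchor-window mixing matrix
#'
#' An ordered set of k vest leads, chosen greedily from the data (kind "SEQ")
#' or fixed at standard/posterior-augmented ECG-analogue positions ("ECG8",
#' "ECG11"), together with the least-squares mixing matrix A fitted on the
#' anchor window so that the subset signals S reconstruct the full matrix as
#' S A.
#'
#' @slot leadIndices ordered integer vector of k unique 1-based lead indices.
#' @slot kind one of "SEQ", "ECG8", "ECG11".
#' @slot mixing numeric k x n mixing matrix (may have 0 rows before fitting).
#' @slot anchorWindow index of the window the mixing was fitted on (1).
#'
#' @seealso [sequentialSelect()], [pinvFit()], [subsetReconstruct()]
#' @export
setClass("ElectrodeSubset",
  representation(
    leadIndices = "integer",
    kind = "character",
    mixing = "matrix",
    anchorWindow = "integer"
  )
)

setValidity("ElectrodeSubset", function(object) {
  msg <- character()
  k <- length(object@leadIndices)
  if (k < 1L || anyDuplicated(object@leadIndices) || min(object@leadIndices) < 1L)
    msg <- c(msg, "leadIndices must be unique positive integers")
  if (!(object@kind %in% c("SEQ", "ECG8", "ECG11")))
    msg <- c(msg, "kind must be one of SEQ, ECG8, ECG11")
  if (nrow(object@mixing) > 0L && nrow(object@mixing) != k)
    msg <- c(msg, "mixing must have one row per subset lead")
  if (length(msg)) msg else TRUE
})

#' Construct an ElectrodeSubset
#'
#' @param leadIndices ordered integer lead indices (1-based vest labels).
#' @param kind subset provenance: "SEQ", "ECG8" or "ECG11".
#' @param mixing optional k x n mixing matrix fitted on the anchor window.
#' @param anchorWindow window index the mixing was fitted on (default 1).
#' @return An \linkS4class{ElectrodeSubset}.
#' @export
ElectrodeSubset <- function(leadIndices, kind = "SEQ", mixing = NULL,
                            anchorWindow = 1L) {
  if (is.null(mixing)) mixing <- matrix(numeric(), 0L, 0L)
  new("ElectrodeSubset", leadIndices = as.integer(leadIndices),
      kind = kind, mixing = mixing, anchorWindow = as.integer(anchorWindow))
}

#' @describeIn ElectrodeSubset ordered lead indices.
#' @param object an `ElectrodeSubset`.
#' @export
setMethod("leadIndices", "ElectrodeSubset", function(object) object@leadIndices)

#' @describeIn ElectrodeSubset the fitted k x n mixing matrix.
#' @export
setMethod("mixingMatrix", "ElectrodeSubset", function(object) object@mixing)

setMethod("show", "ElectrodeSubset", function(object) {
  cat(sprintf("ElectrodeSubset (%s, k = %d): leads %s\n", object@kind,
              length(object@leadIndices),
              paste(object@leadIndices, collapse = ", ")))
  if (nrow(object@mixing))
    cat(sprintf("  mixing fitted on window %d (%d x %d)\n",
                object@anchorWindow, nrow(object@mixing), ncol(object@mixing)))
})

## ---------------------------------------------------------------------------
## CvReport
## ---------------------------------------------------------------------------

#' Cross-validated classification report
#'
#' Per-fold AUCs of a univariate logistic-regression classifier under
#' group-wise (patient-level) cross-validation, plus sensitivity and
#' specificity at the Youden-optimal threshold of the pooled ROC. Arrhythmia
#' recurrence (AR) is the positive class.
#'
#' @slot foldAucs numeric vector of per-fold AUCs in [0, 1].
#' @slot aucMean,aucStd mean and standard deviation over folds.
#' @slot sensitivity,specificity percentages at the pooled-ROC Youden optimum.
#' @slot foldSensitivities,foldSpecificities per-fold values at the same
#'   threshold (percent).
#' @slot foldPvalues per-fold p-values from the fold-wise significance test
#'   (empty if not computed).
#' @slot rocPoints data.frame with columns `fpr`, `tpr` (pooled ROC).
#' @slot skippedFolds indices of folds skipped for degenerate test sets.
#'
#' @seealso [univariateRoc()]
#' @export
setClass("CvReport",
  representation(
    foldAucs = "numeric",
    aucMean = "numeric",
    aucStd = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    foldSensitivities = "numeric",
    foldSpecificities = "numeric",
    foldPvalues = "numeric",
    rocPoints = "data.frame",
    skippedFolds = "integer"
  )
)

setValidity("CvReport", function(object) {
  msg <- character()
  if (length(object@foldAucs) &&
      (min(object@foldAucs) < 0 || max(object@foldAucs) > 1))
    msg <- c(msg, "fold AUCs must lie in [0, 1]")
  for (s in c("sensitivity", "specificity")) {
    v <- slot(object, s)
    if (length(v) && (v < 0 || v > 100))
      msg <- c(msg, sprintf("%s must be a percentage in [0, 100]", s))
  }
  rp <- object@rocPoints
  if (nrow(rp)) {
    if (!all(c("fpr", "tpr") %in% names(rp)))
      msg <- c(msg, "rocPoints must have fpr and tpr columns")
    else if (is.unsorted(rp$fpr) || is.unsorted(rp$tpr))
      msg <- c(msg, "ROC points must be monotone nondecreasing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport: AUC %.3f +/- %.3f over %d folds\n",
              object@aucMean, object@aucStd, length(object@foldAucs)))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%% (Youden threshold)\n",
              object@sensitivity, object@specificity))
  if (length(object@skippedFolds))
    cat("  skipped folds:", paste(object@skippedFolds, collapse = ", "), "\n")
})
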