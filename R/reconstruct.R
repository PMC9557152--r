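#' @include AllClasses.R spectral.R
NULL

## Moore-Penrose pseudoinverse with the package-wide rank tolerance:
## singular values below relTol * sigma_max are treated as zero.
.pinv <- function(S, relTol = 1e-10) {
  sv <- svd(S)
  keep <- sv$d > relTol * sv$d[1L]
  if (!any(keep)) return(list(pinv = matrix(0, ncol(S), nrow(S)),
                              rankDeficient = TRUE))
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(pinv = pinv, rankDeficient = !all(keep))
}

#' Least-squares mixing matrix for an electrode subset
#'
#' Solves `min_A || X - S A ||_F` for the subset signal matrix
#' `S = X[, leadIdx]`, via the Moore-Penrose pseudoinverse: `A = pinv(S) X`.
#' The residual `X - S A` is orthogonal to the column space of `S`. When `S`
#' is rank-deficient (singular values below `1e-10 * sigma_max`), the
#' minimum-norm solution is returned and flagged via the `rankDeficient`
#' attribute.
#'
#' @param X numeric m x n signal matrix.
#' @param leadIdx integer vector of k column (lead) indices, k < n, m >= k.
#' @return The k x n mixing matrix `A`, with logical attribute
#'   `rankDeficient`.
#' @examples
#' X <- diag(2)
#' pinvFit(X, 1L)  # c(1, 0): only the first column is representable
#' @export
pinvFit <- function(X, leadIdx) {
  X <- as.matrix(X)
  leadIdx <- as.integer(leadIdx)
  k <- length(leadIdx)
  if (k < 1L) stop("subset must contain at least one lead")
  if (k >= ncol(X)) stop("subset size k must be smaller than the lead count")
  if (nrow(X) < k) stop("need at least k time samples to fit k columns")
  S <- X[, leadIdx, drop = FALSE]
  p <- .pinv(S)
  A <- p$pinv %*% X
  attr(A, "rankDeficient") <- p$rankDeficient
  A
}

#' Normalized root-mean-square reconstruction error
#'
#' `NRMSE = ||X - Xhat||_F / ||X||_F`.
#'
#' @param X,Xhat equal-shaped numeric matrices.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(X, Xhat) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat)
  if (!all(dim(X) == dim(Xhat))) stop("X and Xhat must have equal shapes")
  nx <- sqrt(sum(X^2))
  if (nx <= 0) stop("NRMSE undefined: X has zero Frobenius norm")
  sqrt(sum((X - Xhat)^2)) / nx
}

#' Dominant-frequency reconstruction error (ABSE)
#'
#' Mean absolute difference, across leads, between the per-lead dominant
#' frequencies of the original and reconstructed matrices. Leads whose DF is
#' undefined in either matrix are excluded from the mean and counted in the
#' `nExcluded` attribute.
#'
#' @inheritParams nrmse
#' @param fs sampling rate in Hz.
#' @param cfg a [spectralConfig()].
#' @return Mean absolute DF difference in Hz, with attribute `nExcluded`.
#' @export
abse <- function(X, Xhat, fs, cfg = spectralConfig()) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat)
  if (!all(dim(X) == dim(Xhat))) stop("X and Xhat must have equal shapes")
  dfX <- dfMap(X, fs, cfg)
  dfH <- dfMap(Xhat, fs, cfg)
  ok <- !is.na(dfX) & !is.na(dfH)
  if (!any(ok)) stop("ABSE undefined: DF undefined on every lead")
  out <- mean(abs(dfX[ok] - dfH[ok]))
  attr(out, "nExcluded") <- sum(!ok)
  out
}

#' Rank-k PCA reconstruction
#'
#' The best rank-k approximation of `X` in the Frobenius norm (truncated SVD,
#' `X_k = U_k D_k V_k'`); by the Eckart-Young theorem its error equals the
#' root-sum-square of the discarded singular values, and it lower-bounds the
#' error of any k-electrode subset reconstruction.
#'
#' @param X numeric m x n matrix.
#' @param k target rank, `1 <= k <= min(m, n)`.
#' @return A list with `xHat` (m x n), `nrmse`, `frobError` and
#'   `singularValues`.
#' @export
pcaReconstruct <- function(X, k) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(X)))
    stop("rank k must lie in [1, min(m, n)]")
  sv <- svd(X)
  xHat <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  err <- if (k < length(sv$d)) sqrt(sum(sv$d[-seq_len(k)]^2)) else 0
  nx <- sqrt(sum(X^2))
  list(xHat = xHat, nrmse = if (nx > 0) err / nx else NA_real_,
       frobError = err, singularValues = sv$d)
}

## Squared singular values of X via the (n x n) cross-product eigenproblem;
## much cheaper than a full SVD when m >> n. Clipped at zero.
.sigma2 <- function(X) {
  ev <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}

## Frobenius error of the best rank-k approximation, from squared singular
## values.
.pcaFrobError <- function(sigma2, k) {
  if (k >= length(sigma2)) return(0)
  sqrt(sum(sigma2[(k + 1L):length(sigma2)]))
}

## Leading k right singular vectors of X (for forming X V_k V_k').
.topRightVectors <- function(X, k) {
  eigen(crossprod(X), symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
}

#' Reconstruct a window from an electrode subset
#'
#' Forms `Xhat = X[, subset leads] %*% A`, using the window's own samples on
#' the subset leads but the mixing matrix `A` fitted on the subset's anchor
#' window. When the window is the anchor window itself this reduces to the
#' plain least-squares fit `S pinv(S) X`.
#'
#' @param X numeric m x n window matrix.
#' @param subset an \linkS4class{ElectrodeSubset} with a fitted mixing matrix.
#' @return A list with `xHat` and `nrmse`.
#' @export
subsetReconstruct <- function(X, subset) {
  stopifnot(is(subset, "ElectrodeSubset"))
  X <- as.matrix(X)
  A <- subset@mixing
  if (!nrow(A)) stop("subset has no fitted mixing matrix; call pinvFit() first")
  if (ncol(A) != ncol(X))
    stop(sprintf("mixing matrix is for %d leads but window has %d",
                 ncol(A), ncol(X)))
  if (max(subset@leadIndices) > ncol(X))
    stop("subset lead indices exceed the window lead count")
  xHat <- X[, subset@leadIndices, drop = FALSE] %*% A
  list(xHat = xHat, nrmse = nrmse(X, xHat))
}

#' Greedy sequential electrode selection
#'
#' Chooses k columns (electrodes) of `X` one at a time, at each step adding
#' the column that minimizes the Frobenius reconstruction error
#' `|| X - S pinv(S) X ||_F` of the enlarged subset. Implemented by
#' incremental orthogonalization: the residual matrix `E` is deflated by the
#' normalized residual of each chosen column, so each step's error reduction
#' for candidate `j` is `||e_j' E||^2 / ||e_j||^2` — algebraically identical
#' to refitting the pseudoinverse from scratch (asserted in the test suite).
#' Ties break toward the lowest lead index; columns whose residual energy has
#' been exhausted (e.g. exact duplicates of already-chosen leads) are never
#' selected while informative columns remain.
#'
#' @param X numeric m x n matrix (an analysis window).
#' @param k number of electrodes to select, `1 <= k < n`.
#' @param fitMixing if TRUE (default) fit the mixing matrix `A = pinv(S) X`
#'   on `X` after selection.
#' @return An \linkS4class{ElectrodeSubset} of kind "SEQ", with numeric
#'   attribute `stepErrors`: the Frobenius reconstruction error after each
#'   greedy step (so `stepErrors[j]` is the fit error of the size-j prefix).
#' @export
sequentialSelect <- function(X, k, fitMixing = TRUE) {
  X <- as.matrix(X)
  n <- ncol(X)
  k <- as.integer(k)
  if (k >= n) stop("subset size k must be smaller than the lead count")
  if (k < 1L) stop("subset size k must be positive")
  E <- X
  total0 <- sum(X^2)
  tol <- 1e-12 * max(colSums(X^2), .Machine$double.eps)
  chosen <- integer(0L)
  stepErr <- numeric(k)
  remaining <- total0
  for (step in seq_len(k)) {
    G <- crossprod(E)
    d <- diag(G)
    score <- rowSums(G^2) / ifelse(d > tol, d, Inf)
    score[d <= tol] <- -Inf
    if (length(chosen)) score[chosen] <- -Inf
    if (all(!is.finite(score))) {
      ## X is exhausted: every remaining column lies in the chosen span.
      ## Fill deterministically with the lowest unchosen indices.
      fill <- setdiff(seq_len(n), chosen)[seq_len(k - length(chosen))]
      chosen <- c(chosen, fill)
      stepErr[step:k] <- sqrt(max(remaining, 0))
      break
    }
    j <- which.max(score)  # first maximum = lowest lead index on ties
    chosen <- c(chosen, j)
    u <- E[, j] / sqrt(d[j])
    E <- E - u %*% crossprod(u, E)
    remaining <- remaining - score[j]
    stepErr[step] <- sqrt(max(remaining, 0))
  }
  mix <- if (fitMixing) pinvFit(X, chosen) else matrix(numeric(), 0L, 0L)
  out <- ElectrodeSubset(chosen, kind = "SEQ", mixing = mix, anchorWindow = 1L)
  attr(out, "stepErrors") <- stepErr
  out
}

#' Per-window reconstruction-error profile of electrode subsets
#'
#' For each 5-s window of a segment, computes the NRMSE (and optionally the
#' dominant-frequency ABSE) of reconstructions from greedy SEQ subsets of
#' sizes `kRange`, the fixed ECG8/ECG11 analogue subsets, and the rank-k PCA
#' reconstruction, then averages over windows. Subsets are fit within each
#' window (`mode = "perwindow"`) or selected and fitted on the first window
#' only (`mode = "anchored"`).
#'
#' @param segment an \linkS4class{AASegment}.
#' @param kinds character subset of `c("SEQ", "ECG8", "ECG11", "PCA")`.
#' @param kRange integer vector of subset sizes / PCA ranks for SEQ and PCA.
#' @param geometry \linkS4class{VestGeometry} supplying the ECG-analogue
#'   leads; default matches the segment lead count.
#' @param mode `"perwindow"` (default) or `"anchored"`.
#' @param computeAbse also compute ABSE (slower; default FALSE).
#' @param cfg a [spectralConfig()] for ABSE.
#' @return data.frame with columns `kind`, `k`, `nrmse` and (if requested)
#'   `abse`, averaged over windows.
#' @export
subsetErrorProfile <- function(segment,
                               kinds = c("SEQ", "ECG8", "ECG11", "PCA"),
                               kRange = 8:30, geometry = NULL,
                               mode = c("perwindow", "anchored"),
                               computeAbse = FALSE, cfg = spectralConfig()) {
  stopifnot(is(segment, "AASegment"))
  mode <- match.arg(mode)
  kinds <- match.arg(kinds, several.ok = TRUE)
  wins <- segmentWindows(segment)
  if (length(wins) < 2L) stop("segment must contain at least 2 windows")
  if (is.null(geometry)) geometry <- defaultVestGeometry(numLeads(segment))
  fs <- samplingRate(segment)
  kmax <- max(kRange)
  rows <- list()
  addRow <- function(kind, k, nr, ab) {
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, k = k, nrmse = nr,
                                             abse = ab)
  }
  ## anchored mode: select/fit everything on window 1
  anchorSeq <- NULL; anchorEcg <- list()
  if (mode == "anchored") {
    anchorSeq <- sequentialSelect(wins[[1L]], kmax)
    for (kk in intersect(kinds, c("ECG8", "ECG11"))) {
      idx <- if (kk == "ECG8") geometry@ecg8 else geometry@ecg11
      anchorEcg[[kk]] <- ElectrodeSubset(idx, kind = kk,
                                         mixing = pinvFit(wins[[1L]], idx))
    }
  }
  perKind <- function(kind) {
    ks <- if (kind %in% c("SEQ", "PCA")) kRange
          else if (kind == "ECG8") 8L else 11L
    errN <- matrix(0, length(wins), length(ks))
    errA <- matrix(NA_real_, length(wins), length(ks))
    for (w in seq_along(wins)) {
      Xw <- wins[[w]]
      nx <- sqrt(sum(Xw^2))
      if (kind == "PCA") {
        s2 <- sort(.sigma2(Xw), decreasing = TRUE)
        for (j in seq_along(ks))
          errN[w, j] <- .pcaFrobError(s2, ks[j]) / nx
        if (computeAbse) {
          for (j in seq_along(ks)) {
            V <- .topRightVectors(Xw, ks[j])
            errA[w, j] <- as.numeric(abse(Xw, Xw %*% V %*% t(V), fs, cfg))
          }
        }
      } else if (kind == "SEQ") {
        if (mode == "perwindow") {
          sel <- sequentialSelect(Xw, kmax, fitMixing = FALSE)
          errN[w, ] <- attr(sel, "stepErrors")[ks] / nx
          if (computeAbse) {
            for (j in seq_along(ks)) {
              idx <- leadIndices(sel)[seq_len(ks[j])]
              A <- pinvFit(Xw, idx)
              errA[w, j] <- as.numeric(
                abse(Xw, Xw[, idx, drop = FALSE] %*% A, fs, cfg))
            }
          }
        } else {
          for (j in seq_along(ks)) {
            idx <- leadIndices(anchorSeq)[seq_len(ks[j])]
            sub <- ElectrodeSubset(idx, "SEQ",
                                   mixing = pinvFit(wins[[1L]], idx))
            rec <- subsetReconstruct(Xw, sub)
            errN[w, j] <- rec$nrmse
            if (computeAbse)
              errA[w, j] <- as.numeric(abse(Xw, rec$xHat, fs, cfg))
          }
        }
      } else {  # ECG8 / ECG11
        idx <- if (kind == "ECG8") geometry@ecg8 else geometry@ecg11
        sub <- if (mode == "anchored") anchorEcg[[kind]]
               else ElectrodeSubset(idx, kind, mixing = pinvFit(Xw, idx))
        rec <- subsetReconstruct(Xw, sub)
        errN[w, 1L] <- rec$nrmse
        if (computeAbse)
          errA[w, 1L] <- as.numeric(abse(Xw, rec$xHat, fs, cfg))
      }
    }
    for (j in seq_along(ks))
      addRow(kind, ks[j], mean(errN[, j]),
             if (computeAbse) mean(errA[, j]) else NA_real_)
  }
  for (kind in kinds) perKind(kind)
  out <- do.call(rbind, rows)
  if (!computeAbse) out$abse <- NULL
  rownames(out) <- NULL
  out
}
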