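# Shared fixture builders. Small problem sizes keep unit tests fast; the
# acceptance tests run the canonical 252-lead / 60-s conditions.

# A reduced synthetic configuration: fewer leads and a shorter segment, all
# other signal properties at their defaults.
smallSynthConfig <- function(..., nLeads = 36L, durationS = 15, seed = 1L) {
  synthConfig(nLeads = nLeads, durationS = durationS, seed = seed, ...)
}

# A deterministic random matrix.
randMat <- function(m, n, seed) {
  set.seed(seed)
  matrix(rnorm(m * n), m, n)
}

# A sinusoidal multichannel matrix with prescribed per-lead frequencies.
toneMatrix <- function(freqs, fs = 1000, durationS = 6, amp = 1) {
  t <- seq(0, durationS - 1 / fs, by = 1 / fs)
  sapply(freqs, function(f) amp * sin(2 * pi * f * t))
}

# Exhaustive-search oracle: best single column (k = 1) by reconstruction
# error, independent of the greedy implementation.
bruteBestColumn <- function(X) {
  errs <- vapply(seq_len(ncol(X)), function(j) {
    A <- pinvFit(X, j)
    sqrt(sum((X - X[, j, drop = FALSE] %*% A)^2))
  }, numeric(1L))
  which.min(errs)
}

# Exhaustive-search oracle: best pair of columns.
bruteBestPairError <- function(X) {
  pairs <- utils::combn(ncol(X), 2L)
  min(apply(pairs, 2L, function(idx) {
    A <- pinvFit(X, idx)
    sqrt(sum((X - X[, idx, drop = FALSE] %*% A)^2))
  }))
}

# A matrix with prescribed singular values and zero column means (so the
# column-centering inside the NDI preserves the spectrum): the left factor is
# built inside the orthogonal complement of the all-ones vector.
matrixWithSingularValues <- function(d, m = 24L, seed = 7L) {
  n <- length(d)
  set.seed(seed)
  A <- scale(matrix(rnorm(m * n), m, n), center = TRUE, scale = FALSE)
  U <- qr.Q(qr(A))
  V <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  U %*% diag(d) %*% t(V)
}

# A labeled synthetic index table (no signal generation): patient-level
# class-shifted Gaussian values, for testing the CV machinery in isolation.
syntheticIndexTable <- function(nPatients = 11L, segmentsPerPatient = 7L,
                                nAR = 6L, shift = 0, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(nPatients), function(p) {
    outcome <- if (p <= nAR) "AR" else "SR"
    data.frame(patient_id = sprintf("p%02d", p),
               segment_id = sprintf("s%02d", seq_len(segmentsPerPatient)),
               value = rnorm(segmentsPerPatient,
                             mean = if (outcome == "AR") shift else 0),
               outcome = outcome, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
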