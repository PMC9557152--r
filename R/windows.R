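#' @include AllClasses.R
NULL

#' Split a segment into analysis windows
#'
#' Cuts the segment into non-overlapping, contiguous windows of
#' `windowLenS` seconds (the slot default, 5 s). A tail shorter than one
#' window is dropped, so a canonical 60-s segment yields 12 clean windows.
#'
#' @param segment an \linkS4class{AASegment}.
#' @param windowLenS optional window length override in seconds.
#' @return A list of m_w x n matrices, one per window.
#' @export
segmentWindows <- function(segment, windowLenS = NULL) {
  stopifnot(is(segment, "AASegment"))
  if (is.null(windowLenS)) windowLenS <- segment@windowLenS
  wlen <- round(windowLenS * segment@fs)
  m <- nrow(segment@samples)
  nwin <- m %/% wlen
  if (nwin < 1L)
    stop("segment is shorter than one analysis window")
  lapply(seq_len(nwin), function(i)
    segment@samples[((i - 1L) * wlen + 1L):(i * wlen), , drop = FALSE])
}
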