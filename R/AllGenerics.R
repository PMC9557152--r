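#' @include AllGenerics.R
NULL

#' Extract the signal matrix
#'
#' Returns the samples-by-leads signal matrix held by a recording or
#' atrial-activity segment.
#'
#' @param object A \linkS4class{BspmRecording} or \linkS4class{AASegment}.
#' @return A numeric matrix with time samples in rows and leads in columns.
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' Sampling rate accessor
#'
#' @param object A \linkS4class{BspmRecording} or \linkS4class{AASegment}.
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Number of leads
#'
#' @param object A \linkS4class{VestGeometry}, \linkS4class{BspmRecording}
#'   or \linkS4class{AASegment}.
#' @return Integer lead count.
#' @export
setGeneric("numLeads", function(object) standardGeneric("numLeads"))

#' Lead indices of an electrode subset
#'
#' @param object An \linkS4class{ElectrodeSubset}.
#' @return Ordered integer vector of 1-based vest lead indices.
#' @export
setGeneric("leadIndices", function(object) standardGeneric("leadIndices"))

#' Anchor-window mixing matrix of an electrode subset
#'
#' @param object An \linkS4class{ElectrodeSubset}.
#' @return The k-by-n least-squares mixing matrix fitted on the anchor window.
#' @export
setGeneric("mixingMatrix", function(object) standardGeneric("mixingMatrix"))
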