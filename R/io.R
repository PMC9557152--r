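#' @include AllClasses.R geometry.R
NULL

.sidecarPath <- function(path) paste0(path, ".json")

#' Read a multichannel recording from disk
#'
#' Reads a samples-by-leads signal matrix together with its JSON sidecar
#' (`<path>.json`, or an explicit `sidecar` path) declaring at least `fs_hz`
#' and `n_leads`, and optionally `lead_labels` and `bad_leads` (1-based).
#' Two matrix encodings are supported: tab-delimited text (one row per time
#' sample) and flat little-endian binary doubles in row-major (sample-major)
#' order.
#'
#' @param path path to the matrix file.
#' @param format `"text"` or `"binary"`; default guesses from the sidecar's
#'   `format` field, falling back to `"text"`.
#' @param sidecar optional explicit sidecar path.
#' @param geometry optional \linkS4class{VestGeometry}; default matches the
#'   declared lead count.
#' @return A \linkS4class{BspmRecording}.
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = NULL, sidecar = .sidecarPath(path),
                          geometry = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs_hz", "n_leads"))
    if (is.null(meta[[f]]))
      stop("malformed sidecar ", sidecar, ": missing field '", f, "'")
  n <- as.integer(meta$n_leads)
  if (is.null(format)) format <- if (is.null(meta$format)) "text" else meta$format
  format <- match.arg(format, c("text", "binary"))
  if (format == "text") {
    x <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                     colClasses = "numeric"))
    dimnames(x) <- NULL
  } else {
    sz <- file.info(path)$size
    vals <- readBin(path, "double", n = sz %/% 8L, size = 8L,
                    endian = "little")
    if (length(vals) %% n != 0L)
      stop("binary recording length is not a multiple of the declared lead count")
    x <- matrix(vals, ncol = n, byrow = TRUE)
  }
  if (ncol(x) != n)
    stop(sprintf("lead-count mismatch: file has %d columns, sidecar declares %d",
                 ncol(x), n))
  quality <- rep(TRUE, n)
  if (!is.null(meta$bad_leads) && length(meta$bad_leads))
    quality[as.integer(meta$bad_leads)] <- FALSE
  BspmRecording(x, fs = as.numeric(meta$fs_hz), geometry = geometry,
                leadQuality = quality)
}

#' Write a multichannel recording to disk
#'
#' Writes the signal matrix plus a JSON sidecar (`<path>.json`). Text output
#' uses 17 significant digits so read/write round-trips are exact to double
#' precision; binary output is lossless by construction.
#'
#' @param rec a \linkS4class{BspmRecording}.
#' @param path destination for the matrix file.
#' @param format `"text"` (tab-delimited) or `"binary"` (flat doubles).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("text", "binary")) {
  stopifnot(is(rec, "BspmRecording"))
  format <- match.arg(format)
  x <- rec@samples
  if (format == "text") {
    lines <- apply(x, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, path)
  } else {
    writeBin(as.vector(t(x)), path, size = 8L, endian = "little")
  }
  bad <- which(!rec@leadQuality)
  jsonlite::write_json(
    list(fs_hz = rec@fs, n_leads = ncol(x), format = format,
         lead_labels = seq_len(ncol(x)),
         bad_leads = if (length(bad)) bad else integer()),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Stable column order of the per-segment index table.
.indexColumns <- c("patient_id", "segment_id", "subset_kind", "k",
                   "er_nrmse", "er_abse", "ndi", "outcome")

#' Write / read a per-segment index table
#'
#' Serializes the results of [computeAllIndices()] (one row per segment and
#' subset kind) as a tab-delimited table with a stable column order and
#' 17-significant-digit numeric formatting, so a round-trip is lossless.
#'
#' @param results data.frame of segment indices (columns `patient_id`,
#'   `segment_id`, `subset_kind`, `k`, `er_nrmse`, `er_abse`, `ndi`,
#'   `outcome`).
#' @param path destination path.
#' @return `writeSegmentIndices` returns `path` invisibly;
#'   `readSegmentIndices` returns the data.frame.
#' @export
writeSegmentIndices <- function(results, path) {
  if (is.null(results) || !nrow(as.data.frame(results)))
    stop("results must contain at least one segment-index row")
  df <- as.data.frame(results)
  missing <- setdiff(.indexColumns, names(df))
  if (length(missing))
    stop("results table is missing columns: ", paste(missing, collapse = ", "))
  df <- df[, .indexColumns]
  for (col in c("er_nrmse", "er_abse", "ndi"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSegmentIndices
#' @export
readSegmentIndices <- function(path) {
  if (!file.exists(path)) stop("index table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("er_nrmse", "er_abse", "ndi")) df[[col]] <- as.numeric(df[[col]])
  df$k <- as.integer(df$k)
  df
}
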