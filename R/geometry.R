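#' @include AllClasses.R
NULL

## Lead index on a 9-row column-major grid panel.
.gridIndex <- function(col, row, nrows = 9L) (col - 1L) * nrows + row

#' Default synthetic vest geometry
#'
#' Builds the package's default electrode geometry: two 9 x 14 panels
#' (anterior leads 1-126, posterior leads 127-252) on an unrolled torso grid,
#' with ECG-analogue subsets placed at plausible precordial, limb-equivalent
#' and posterior positions. The true manufacturer coordinates of clinical
#' mapping vests are not public, so this geometry is synthetic: subset
#' membership is a consistent, documented mapping, not a claim about any
#' physical vest. For lead counts other than 252 a single near-square panel is
#' generated and the ECG-analogue subsets are spread deterministically across
#' it.
#'
#' @param nLeads number of leads (default 252).
#' @return A \linkS4class{VestGeometry}.
#' @examples
#' geom <- defaultVestGeometry()
#' numLeads(geom)
#' @export
defaultVestGeometry <- function(nLeads = 252L) {
  nLeads <- as.integer(nLeads)
  if (nLeads == 252L) {
    nrows <- 9L; ncols <- 14L
    ant <- expand.grid(row = seq_len(nrows), col = seq_len(ncols))
    pos <- cbind(x = c(ant$col, ant$col + 16L), y = c(ant$row, ant$row))
    ## Precordial analogues V1..V6 run across the mid anterior chest,
    ## limb-equivalent leads sit at the upper panel corners.
    v1to6 <- c(.gridIndex(7L, 5L), .gridIndex(8L, 5L), .gridIndex(9L, 5L),
               .gridIndex(10L, 4L), .gridIndex(11L, 4L), .gridIndex(12L, 4L))
    limb <- c(.gridIndex(1L, 9L), .gridIndex(14L, 9L))
    ecg8 <- c(v1to6, limb)
    ## V8/V9/V10 analogues: posterior panel, same horizontal row as V6.
    post <- 126L + c(.gridIndex(4L, 4L), .gridIndex(6L, 4L), .gridIndex(8L, 4L))
    ecg11 <- c(ecg8, post)
  } else {
    nrows <- max(1L, floor(sqrt(nLeads)))
    ncols <- ceiling(nLeads / nrows)
    g <- expand.grid(row = seq_len(nrows), col = seq_len(ncols))
    pos <- cbind(x = g$col[seq_len(nLeads)], y = g$row[seq_len(nLeads)])
    if (nLeads >= 11L) {
      ecg11 <- unique(round(seq(1L, nLeads, length.out = 11L)))
      while (length(ecg11) < 11L)
        ecg11 <- sort(c(ecg11, setdiff(seq_len(nLeads), ecg11)[1L]))
      ecg8 <- ecg11[seq_len(8L)]
    } else {
      ## too few leads for ECG analogues: leave the subsets undefined
      ecg8 <- integer(0)
      ecg11 <- integer(0)
    }
  }
  new("VestGeometry", nLeads = nLeads,
      positions = matrix(as.numeric(pos), ncol = 2L,
                         dimnames = list(NULL, c("x", "y"))),
      ecg8 = as.integer(ecg8), ecg11 = as.integer(ecg11))
}

#' Read / write a vest geometry as JSON
#'
#' The JSON schema is `{n_leads, positions: [[x, y], ...], ecg8, ecg11}` with
#' 1-based lead indices.
#'
#' @param path file path.
#' @return `readGeometry` returns a \linkS4class{VestGeometry};
#'   `writeGeometry` returns `path` invisibly.
#' @export
readGeometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("n_leads", "positions", "ecg8", "ecg11"))
    if (is.null(j[[f]])) stop("malformed geometry file: missing field '", f, "'")
  new("VestGeometry", nLeads = as.integer(j$n_leads),
      positions = matrix(as.numeric(j$positions), ncol = 2L,
                         dimnames = list(NULL, c("x", "y"))),
      ecg8 = as.integer(j$ecg8), ecg11 = as.integer(j$ecg11))
}

#' @rdname readGeometry
#' @param geometry a \linkS4class{VestGeometry} to serialize.
#' @export
writeGeometry <- function(geometry, path) {
  stopifnot(is(geometry, "VestGeometry"))
  jsonlite::write_json(
    list(n_leads = geometry@nLeads,
         positions = unname(geometry@positions),
         ecg8 = geometry@ecg8, ecg11 = geometry@ecg11),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
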