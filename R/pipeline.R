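#' @include AllClasses.R synthetic.R preprocess.R indices.R evaluate.R io.R
NULL

#' Default pipeline configuration
#'
#' Nested configuration for [runPipeline()]: a synthetic cohort (patients
#' with a per-patient AF-organization regime and matching outcome label,
#' organized -> SR, disorganized -> AR), the synthesis settings, the index
#' settings, and the evaluation settings. Any element can be overridden by
#' the `config` argument of [runPipeline()] or a JSON file with the same
#' structure.
#'
#' @param nPatients number of synthetic patients (default 11).
#' @param segmentsPerPatient 1-min segments per patient (default 7).
#' @param arFraction fraction of patients with the disorganized regime /
#'   AR outcome (default 6/11).
#' @param seed base RNG seed (default 1).
#' @param synth named list of [synthConfig()] overrides.
#' @param indices named list of [indexConfig()] overrides.
#' @param evaluate named list: `nFolds`, `testFrac`, `indexColumn`,
#'   `subsetKind`.
#' @return A list of class `RunConfig`.
#' @export
pipelineConfig <- function(nPatients = 11L, segmentsPerPatient = 7L,
                           arFraction = 6 / 11, seed = 1L,
                           synth = list(), indices = list(),
                           evaluate = list()) {
  ev <- utils::modifyList(list(nFolds = 3L, testFrac = 0.2,
                               indexColumn = "er_nrmse",
                               subsetKind = "SEQ8"), evaluate)
  structure(list(nPatients = as.integer(nPatients),
                 segmentsPerPatient = as.integer(segmentsPerPatient),
                 arFraction = arFraction, seed = as.integer(seed),
                 synth = synth, indices = indices, evaluate = ev),
            class = "RunConfig")
}

## Derive a per-(patient, segment) child seed from the base seed (kept well
## below 2^31).
.childSeed <- function(base, patient, segment) {
  as.integer((as.numeric(base) * 7919 + patient * 104729 +
                segment * 1299709) %% 2000000011)
}

#' Simulate a labeled cohort index table in memory
#'
#' Generates a synthetic cohort (per-patient AF-organization regime linked to
#' outcome: organized -> SR, disorganized -> AR), computes the requested
#' segment indices for every 1-min segment, and returns the labeled table
#' ready for [groupwiseFolds()] / [univariateRoc()] — the desk-scale replica
#' of a clinical index-vs-outcome analysis.
#'
#' @inheritParams pipelineConfig
#' @param subsetKinds subset kinds to compute (default `"SEQ8"` only, the
#'   fastest; pass more kinds as in [indexConfig()]).
#' @param computeAbse also compute ER_ABSE (slower; default FALSE).
#' @param synth named list of [synthConfig()] overrides.
#' @return data.frame in the [computeAllIndices()] schema with one row per
#'   (segment, subset kind).
#' @export
simulateCohortIndices <- function(nPatients = 11L, segmentsPerPatient = 7L,
                                  arFraction = 6 / 11, seed = 1L,
                                  subsetKinds = "SEQ8", computeAbse = FALSE,
                                  synth = list()) {
  nAR <- round(arFraction * nPatients)
  regimes <- c(rep("disorganized", nAR), rep("organized", nPatients - nAR))
  outcomes <- ifelse(regimes == "disorganized", "AR", "SR")
  icfg <- indexConfig(subsetKinds = subsetKinds)
  rows <- list()
  for (p in seq_len(nPatients)) {
    for (s in seq_len(segmentsPerPatient)) {
      sc <- do.call(synthConfig, utils::modifyList(
        list(regime = regimes[p], seed = .childSeed(seed, p, s)), synth))
      seg <- generateAASegment(sc)
      rows[[length(rows) + 1L]] <- computeAllIndices(
        seg, icfg, patientId = sprintf("p%02d", p),
        segmentId = sprintf("s%02d", s), outcome = outcomes[p],
        computeAbse = computeAbse)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the synthetic end-to-end pipeline
#'
#' Chains synthesis -> preprocessing -> index computation -> group-wise CV
#' evaluation for a synthetic cohort, writing every artifact to `outDir` and
#' a `manifest.json` listing each output file with its MD5 content hash.
#' Identical configuration and seed produce identical artifact hashes.
#'
#' @param config a [pipelineConfig()] (or a path to a JSON file of
#'   overrides).
#' @param outDir output directory (created if missing).
#' @param stages character subset of `c("synth", "indices", "evaluate")` to
#'   run; `"indices"` consumes the segments written by `"synth"` (which
#'   internally includes preprocessing/normalization), `"evaluate"` consumes
#'   the index table. Stages with missing inputs raise an error naming the
#'   stage.
#' @param fullPreprocess if TRUE, segments are generated as full recordings
#'   (with QRST complexes, wander and noise) and passed through the complete
#'   preprocessing chain; if FALSE (default) clean atrial segments with
#'   measurement noise are generated directly, which is much faster and
#'   isolates the index behavior.
#' @return Invisibly, the manifest as a named list of MD5 hashes.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        stages = c("synth", "indices", "evaluate"),
                        fullPreprocess = FALSE) {
  if (is.character(config)) {
    ov <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipelineConfig, ov)
  }
  stopifnot(inherits(config, "RunConfig"))
  stages <- match.arg(stages, c("synth", "indices", "evaluate"),
                      several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  addArtifact <- function(path) {
    h <- unname(tools::md5sum(path))
    manifest[basename(path)] <<- h
  }
  nAR <- round(config$arFraction * config$nPatients)
  regimes <- c(rep("disorganized", nAR),
               rep("organized", config$nPatients - nAR))
  outcomes <- ifelse(regimes == "disorganized", "AR", "SR")
  segDir <- file.path(outDir, "segments")

  if ("synth" %in% stages) {
    dir.create(segDir, showWarnings = FALSE)
    for (p in seq_len(config$nPatients)) {
      for (s in seq_len(config$segmentsPerPatient)) {
        sc <- do.call(synthConfig, utils::modifyList(
          list(regime = regimes[p],
               seed = .childSeed(config$seed, p, s)),
          config$synth))
        seg <- if (fullPreprocess) {
          preprocessRecording(generateRecording(sc)$recording)
        } else generateAASegment(sc)
        path <- file.path(segDir, sprintf("p%02d_s%02d.bin", p, s))
        writeRecording(BspmRecording(signalMatrix(seg), fs = samplingRate(seg)),
                       path, format = "binary")
        addArtifact(path); addArtifact(.sidecarPath(path))
      }
    }
  }

  if ("indices" %in% stages) {
    if (!dir.exists(segDir) || !length(list.files(segDir, pattern = "\\.bin$")))
      stop("stage 'indices': no segments found in ", segDir,
           " (run the 'synth' stage first)")
    rows <- list()
    for (p in seq_len(config$nPatients)) {
      for (s in seq_len(config$segmentsPerPatient)) {
        path <- file.path(segDir, sprintf("p%02d_s%02d.bin", p, s))
        if (!file.exists(path))
          stop("stage 'indices': missing segment ", path)
        rec <- readRecording(path, format = "binary")
        seg <- AASegment(signalMatrix(rec), fs = samplingRate(rec),
                         normalized = FALSE)
        icfg <- do.call(indexConfig, config$indices)
        rows[[length(rows) + 1L]] <- computeAllIndices(
          seg, icfg, patientId = sprintf("p%02d", p),
          segmentId = sprintf("s%02d", s), outcome = outcomes[p],
          computeAbse = FALSE)
      }
    }
    idxPath <- file.path(outDir, "indices.tsv")
    writeSegmentIndices(do.call(rbind, rows), idxPath)
    addArtifact(idxPath)
  }

  if ("evaluate" %in% stages) {
    idxPath <- file.path(outDir, "indices.tsv")
    if (!file.exists(idxPath))
      stop("stage 'evaluate': index table not found at ", idxPath,
           " (run the 'indices' stage first)")
    tab <- readSegmentIndices(idxPath)
    tab <- tab[tab$subset_kind == config$evaluate$subsetKind, ]
    folds <- groupwiseFolds(tab, nFolds = config$evaluate$nFolds,
                            testFrac = config$evaluate$testFrac,
                            seed = config$seed)
    sig <- foldSignificance(tab, folds,
                            valueCol = config$evaluate$indexColumn)
    rep <- univariateRoc(tab, folds,
                         valueCol = config$evaluate$indexColumn)
    repPath <- file.path(outDir, "report.json")
    jsonlite::write_json(
      list(index = config$evaluate$indexColumn,
           subset = config$evaluate$subsetKind,
           fold_aucs = rep@foldAucs, auc_mean = rep@aucMean,
           auc_std = rep@aucStd, sensitivity = rep@sensitivity,
           specificity = rep@specificity, mean_p = sig$meanP,
           test_used = sig$testUsed,
           roc_points = rep@rocPoints),
      repPath, auto_unbox = TRUE, digits = NA)
    addArtifact(repPath)
  }

  manPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(as.list(manifest[order(names(manifest))]), manPath,
                       auto_unbox = TRUE)
  invisible(as.list(manifest))
}
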