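#' @include AllClasses.R
NULL

#' Group-wise stratified cross-validation folds
#'
#' Builds `nFolds` independent random patient-level 80/20 splits, stratified
#' by outcome, so that all segments of a patient fall entirely on one side of
#' every fold (no within-patient information leak). Each fold draws
#' approximately `testFrac` of the patients of each outcome class into the
#' test side, with at least one patient of each class on both sides; a draw
#' violating that is re-sampled (up to 100 attempts).
#'
#' @param table data.frame with at least `patient_id` and `outcome` columns;
#'   every patient must carry a single outcome.
#' @param nFolds number of folds (default 3).
#' @param testFrac fraction of patients per class in the test side (default
#'   0.2).
#' @param seed optional RNG seed for reproducible folds.
#' @return A list of `nFolds` lists with `train` and `test` patient-id
#'   vectors.
#' @export
groupwiseFolds <- function(table, nFolds = 3L, testFrac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pat <- unique(table[, c("patient_id", "outcome")])
  if (anyDuplicated(pat$patient_id))
    stop("a patient carries more than one outcome label")
  if (nrow(pat) < 5L) stop("group-wise CV requires at least 5 patients")
  classes <- split(pat$patient_id, pat$outcome)
  if (length(classes) < 2L) stop("both outcome classes must be present")
  if (any(lengths(classes) < 2L))
    stop("each outcome class needs at least 2 patients")
  lapply(seq_len(nFolds), function(f) {
    for (attempt in seq_len(100L)) {
      test <- unlist(lapply(classes, function(ids) {
        nt <- max(1L, round(testFrac * length(ids)))
        nt <- min(nt, length(ids) - 1L)  # keep the class present in train
        sample(ids, nt)
      }), use.names = FALSE)
      train <- setdiff(pat$patient_id, test)
      trainOut <- pat$outcome[pat$patient_id %in% train]
      testOut <- pat$outcome[pat$patient_id %in% test]
      if (length(unique(trainOut)) >= 2L && length(unique(testOut)) >= 2L)
        return(list(train = train, test = test))
    }
    stop("could not build a fold with both classes on both sides")
  })
}

#' Fold-wise significance of an index between outcome groups
#'
#' Within each fold, using the training (held-in, ~80%) rows only, each
#' outcome class is checked for normality with the Lilliefors test at
#' alpha = 0.05; if both classes look normal, a one-way ANOVA compares the
#' groups, otherwise the Wilcoxon rank-sum test is used. The mean p-value
#' across folds is reported, together with which test dominated. Classes too
#' small for the Lilliefors test (< 5 values) take the rank-sum path.
#'
#' @param table data.frame with `patient_id`, `outcome` and the value column.
#' @param folds fold list from [groupwiseFolds()].
#' @param valueCol name of the numeric index column (default `"value"`).
#' @return A list with `meanP`, `foldP`, `tests` (per-fold test name) and
#'   `testUsed` (the majority test).
#' @export
foldSignificance <- function(table, folds, valueCol = "value") {
  foldP <- numeric(length(folds))
  tests <- character(length(folds))
  for (f in seq_along(folds)) {
    tr <- table[table$patient_id %in% folds[[f]]$train, ]
    groups <- split(tr[[valueCol]], tr$outcome)
    if (length(groups) < 2L || any(lengths(groups) < 3L))
      stop("need at least 3 values per class per fold")
    normal <- vapply(groups, function(v) {
      if (length(v) < 5L || stats::sd(v) < 1e-15) return(FALSE)
      nortest::lillie.test(v)$p.value > 0.05
    }, logical(1L))
    if (all(normal)) {
      tests[f] <- "anova"
      fit <- stats::aov(v ~ g, data = data.frame(
        v = tr[[valueCol]], g = factor(tr$outcome)))
      foldP[f] <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    } else {
      tests[f] <- "wilcoxon"
      foldP[f] <- suppressWarnings(
        stats::wilcox.test(groups[[1L]], groups[[2L]])$p.value)
    }
  }
  majority <- names(sort(base::table(tests), decreasing = TRUE))[1L]
  list(meanP = mean(foldP), foldP = foldP, tests = tests,
       testUsed = majority)
}

#' Univariate logistic-regression ROC analysis under group-wise CV
#'
#' Per fold: fits an unpenalized intercept+slope logistic model of the
#' outcome on the (train-standardized) index over the training segments,
#' scores the test segments, and computes the fold ROC/AUC. Arrhythmia
#' recurrence (`positive`, default "AR") is the positive class. The AUC is
#' reported as mean +/- sd over folds; sensitivity and specificity are
#' evaluated at the Youden-optimal threshold of the ROC pooled over all
#' folds' test scores (per-fold values at the same threshold are also
#' reported). Folds whose test side degenerates to a single class are
#' skipped and flagged.
#'
#' @inheritParams foldSignificance
#' @param positive the positive outcome label (default `"AR"`).
#' @return A \linkS4class{CvReport}.
#' @export
univariateRoc <- function(table, folds, valueCol = "value", positive = "AR") {
  negClass <- setdiff(unique(table$outcome), positive)
  if (length(negClass) != 1L)
    stop("outcome must contain the positive class and exactly one other class")
  foldAucs <- numeric(0)
  skipped <- integer(0)
  pooledScore <- numeric(0)
  pooledLabel <- character(0)
  foldScores <- list()
  for (f in seq_along(folds)) {
    tr <- table[table$patient_id %in% folds[[f]]$train, ]
    te <- table[table$patient_id %in% folds[[f]]$test, ]
    if (length(unique(te$outcome)) < 2L || length(unique(tr$outcome)) < 2L) {
      skipped <- c(skipped, f)
      next
    }
    mu <- mean(tr[[valueCol]]); sdv <- stats::sd(tr[[valueCol]])
    if (sdv < 1e-15) sdv <- 1
    z <- (tr[[valueCol]] - mu) / sdv
    y <- as.integer(tr$outcome == positive)
    fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
    zTest <- (te[[valueCol]] - mu) / sdv
    score <- as.numeric(stats::plogis(stats::coef(fit)[1L] +
                                        stats::coef(fit)[2L] * zTest))
    r <- pROC::roc(response = te$outcome, predictor = score,
                   levels = c(negClass, positive), direction = "<",
                   quiet = TRUE)
    foldAucs <- c(foldAucs, as.numeric(pROC::auc(r)))
    pooledScore <- c(pooledScore, score)
    pooledLabel <- c(pooledLabel, te$outcome)
    foldScores[[length(foldScores) + 1L]] <-
      data.frame(score = score, outcome = te$outcome)
  }
  if (!length(foldAucs)) stop("all folds were degenerate; cannot compute ROC")
  pooled <- pROC::roc(response = pooledLabel, predictor = pooledScore,
                      levels = c(negClass, positive), direction = "<",
                      quiet = TRUE)
  best <- pROC::coords(pooled, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1L, ]  # first optimum if ties
  thr <- best$threshold
  perFold <- vapply(foldScores, function(d) {
    pos <- d$outcome == positive
    c(sens = 100 * mean(d$score[pos] > thr),
      spec = 100 * mean(d$score[!pos] <= thr))
  }, numeric(2L))
  rp <- data.frame(fpr = rev(1 - pooled$specificities),
                   tpr = rev(pooled$sensitivities))
  rp <- rp[order(rp$fpr, rp$tpr), ]
  rownames(rp) <- NULL
  new("CvReport", foldAucs = foldAucs, aucMean = mean(foldAucs),
      aucStd = if (length(foldAucs) > 1L) stats::sd(foldAucs) else 0,
      sensitivity = 100 * as.numeric(best$sensitivity),
      specificity = 100 * as.numeric(best$specificity),
      foldSensitivities = as.numeric(perFold["sens", ]),
      foldSpecificities = as.numeric(perFold["spec", ]),
      foldPvalues = numeric(0), rocPoints = rp,
      skippedFolds = skipped)
}

#' Electrode occurrence across subsets
#'
#' For each vest lead, the fraction of the supplied subsets that contain it —
#' the quantity behind occurrence maps of greedy-selected electrodes (a value
#' of 1 means the lead was in every subset, 0.1 in 10% of them).
#'
#' @param subsets nonempty list of \linkS4class{ElectrodeSubset} objects.
#' @param nLeads total lead count (or a \linkS4class{VestGeometry}).
#' @return Numeric vector of per-lead occurrence fractions in [0, 1].
#' @export
subsetOccurrence <- function(subsets, nLeads) {
  if (!length(subsets)) stop("subsets must be a nonempty list")
  if (is(nLeads, "VestGeometry")) nLeads <- numLeads(nLeads)
  counts <- numeric(nLeads)
  for (s in subsets) {
    stopifnot(is(s, "ElectrodeSubset"))
    counts[leadIndices(s)] <- counts[leadIndices(s)] + 1
  }
  counts / length(subsets)
}
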