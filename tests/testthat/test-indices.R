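test_that("ER_NRMSE is bounded below by one and detects instability", {
  org <- generateAASegment(smallSynthConfig(seed = 21L))
  dis <- generateAASegment(smallSynthConfig(regime = "disorganized",
                                            seed = 21L))
  for (seg in list(org, dis)) {
    r <- erNrmseSegment(seg, "SEQ", 8L)
    expect_true(all(r$perWindow >= 1 - 1e-9, na.rm = TRUE))
    expect_gte(r$value, 1 - 1e-9)
  }
  expect_lt(erNrmseSegment(org, "SEQ", 8L)$value,
            erNrmseSegment(dis, "SEQ", 8L)$value)
})

test_that("duplicating the post-anchor windows leaves ER_NRMSE unchanged", {
  seg <- generateAASegment(smallSynthConfig(seed = 22L))
  x <- signalMatrix(seg)
  wlen <- round(seg@windowLenS * samplingRate(seg))
  tail <- x[(wlen + 1L):nrow(x), ]
  tiled <- AASegment(rbind(x, tail), fs = samplingRate(seg),
                     windowLenS = seg@windowLenS)
  r1 <- erNrmseSegment(seg, "SEQ", 8L)
  r2 <- erNrmseSegment(tiled, "SEQ", 8L)
  # the multiset of non-anchor windows is repeated, so the mean is unchanged
  expect_equal(r2$value, r1$value, tolerance = 1e-9)
})

test_that("ER_ABSE follows its ratio definition and policies", {
  seg <- generateAASegment(smallSynthConfig(seed = 23L))
  r <- erAbseSegment(seg, "SEQ", 8L)
  expect_true(is.na(r$value) || r$value >= 0)
  # amplitude scaling leaves the index unchanged (DF invariance)
  seg10 <- AASegment(10 * signalMatrix(seg), fs = samplingRate(seg),
                     windowLenS = seg@windowLenS)
  r10 <- erAbseSegment(seg10, "SEQ", 8L)
  expect_equal(r10$value, r$value, tolerance = 1e-9)
})

test_that("the window-ratio arithmetic of ER_ABSE is correct", {
  # hand-set DF errors: subset errors (1.0, 0.5) Hz, PCA errors (0.5, 0.5)
  # Hz; the ratio of sums is 1.5 / 1.0 = 1.5
  expect_equal((1.0 + 0.5) / (0.5 + 0.5), 1.5)
  # the implemented ratio-of-sums agrees on a constructed two-lead window:
  # verified indirectly through dfMap on tone matrices
  X <- toneMatrix(c(5, 7))
  sub <- toneMatrix(c(6, 6.5))   # DF errors 1.0 and 0.5 Hz
  pca <- toneMatrix(c(5.5, 7.5)) # DF errors 0.5 and 0.5 Hz
  dfX <- dfMap(X, 1000); dfS <- dfMap(sub, 1000); dfP <- dfMap(pca, 1000)
  ratio <- sum(abs(dfX - dfS)) / sum(abs(dfX - dfP))
  expect_equal(ratio, 1.5, tolerance = 0.1)
})

test_that("NDI matches closed forms on constructed spectra", {
  # exact rank-3 window: 3 sources mixed to 10 leads
  set.seed(31)
  src <- matrix(rnorm(60 * 3), 60, 3)
  src <- scale(src, center = TRUE, scale = FALSE)
  X3 <- src %*% matrix(rnorm(30), 3, 10)
  seg3 <- AASegment(X3, fs = 10, windowLenS = 6)  # one 60-sample window
  expect_lt(ndiSegment(seg3)$value, 1e-9)
  # prescribed singular values (2, 1, 1, 1): NDI = 1 - 6/7 = 1/7
  X <- matrixWithSingularValues(c(2, 1, 1, 1))
  seg <- AASegment(X, fs = 4, windowLenS = 6)  # one 24-sample window
  expect_equal(ndiSegment(seg)$value, 1 / 7, tolerance = 1e-9)
})

test_that("NDI of isotropic noise approaches (n - 3) / n", {
  n <- 252L; m <- 2000L
  vals <- vapply(1:10, function(s) {
    set.seed(400 + s)
    seg <- AASegment(matrix(rnorm(m * n), m, n), fs = m / 5)
    ndiSegment(seg)$value
  }, numeric(1L))
  expect_lt(abs(mean(vals) - (n - 3) / n), 0.02)
})

test_that("NDI is invariant to lead permutation and amplitude scaling", {
  seg <- generateAASegment(smallSynthConfig(seed = 24L))
  v <- ndiSegment(seg)$value
  expect_gte(v, 0); expect_lte(v, 1)
  set.seed(1)
  perm <- sample(numLeads(seg))
  segP <- AASegment(signalMatrix(seg)[, perm], fs = samplingRate(seg),
                    windowLenS = seg@windowLenS)
  expect_equal(ndiSegment(segP)$value, v, tolerance = 1e-9)
  segS <- AASegment(7 * signalMatrix(seg), fs = samplingRate(seg),
                    windowLenS = seg@windowLenS)
  expect_equal(ndiSegment(segS)$value, v, tolerance = 1e-9)
})

test_that("computeAllIndices returns one labeled row per subset kind", {
  seg <- generateAASegment(smallSynthConfig(seed = 25L))
  cfg <- indexConfig(subsetKinds = c("SEQ8", "SEQ11", "ECG8", "ECG11"))
  tab <- computeAllIndices(seg, cfg, patientId = "pX", outcome = "SR",
                           computeAbse = FALSE)
  expect_identical(tab$subset_kind, c("SEQ8", "SEQ11", "ECG8", "ECG11"))
  expect_identical(tab$k, c(8L, 11L, 8L, 11L))
  expect_equal(length(unique(tab$ndi)), 1L)  # NDI is subset-independent
  expect_true(all(tab$er_nrmse >= 1 - 1e-9))
  # reordering the requested kinds permutes rows, not values
  cfg2 <- indexConfig(subsetKinds = c("ECG8", "SEQ8"))
  tab2 <- computeAllIndices(seg, cfg2, patientId = "pX", outcome = "SR",
                            computeAbse = FALSE)
  expect_equal(tab2$er_nrmse[tab2$subset_kind == "SEQ8"],
               tab$er_nrmse[tab$subset_kind == "SEQ8"])
  # determinism: regenerating the same seeded segment gives identical rows
  segB <- generateAASegment(smallSynthConfig(seed = 25L))
  tabB <- computeAllIndices(segB, cfg, patientId = "pX", outcome = "SR",
                            computeAbse = FALSE)
  expect_identical(tab$er_nrmse, tabB$er_nrmse)
})

test_that("anchoring tracks stationarity: refit and anchored agree only on stable data", {
  refitEr <- function(seg, k = 8L) {
    wins <- segmentWindows(seg)
    mean(vapply(2:length(wins), function(i) {
      sel <- sequentialSelect(wins[[i]], k)
      num <- attr(sel, "stepErrors")[k]
      ev <- sort(eigen(crossprod(wins[[i]]), symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
      num / sqrt(sum(ev[(k + 1):length(ev)]))
    }, numeric(1L)))
  }
  org <- generateAASegment(smallSynthConfig(seed = 26L))
  dis <- generateAASegment(smallSynthConfig(regime = "disorganized",
                                            seed = 26L))
  aOrg <- erNrmseSegment(org, "SEQ", 8L)$value
  aDis <- erNrmseSegment(dis, "SEQ", 8L)$value
  rOrg <- refitEr(org)
  rDis <- refitEr(dis)
  # anchoring can only lose to per-window refitting (in-sample optimism)...
  expect_gte(aOrg, rOrg - 1e-9)
  expect_gte(aDis, rDis - 1e-9)
  # ...the loss is modest on stationary data and dominates on drifted data
  expect_lt(abs(aOrg - rOrg) / rOrg, 0.15)
  expect_gt(aDis - rDis, 5 * (aOrg - rOrg))
})
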