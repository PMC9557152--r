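test_that("pseudoinverse fitting matches closed forms and is orthogonal", {
  # identity matrix, first column only: A = [1, 0], residual on lead 2 only
  A <- pinvFit(diag(2), 1L)
  expect_equal(A, matrix(c(1, 0), 1, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nrmse(diag(2), diag(2)[, 1, drop = FALSE] %*% A),
               1 / sqrt(2), tolerance = 1e-12)
  # exact representability: X = S B
  set.seed(1)
  S <- matrix(rnorm(40), 20, 2)
  X <- S %*% matrix(rnorm(2 * 6), 2, 6)
  Af <- pinvFit(X, c(1L, 2L))
  expect_lt(sqrt(sum((X - X[, 1:2] %*% Af)^2)), 1e-9)
  # orthonormal subset: A = S' X
  Q <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
  Xq <- cbind(Q, matrix(rnorm(20 * 2), 20, 2))
  Aq <- pinvFit(Xq, 1:3)
  expect_equal(Aq, t(Q) %*% Xq, tolerance = 1e-9, ignore_attr = TRUE)
  # residual orthogonality for a generic matrix
  Xg <- randMat(30, 8, seed = 2)
  Ag <- pinvFit(Xg, c(2L, 5L, 7L))
  Sg <- Xg[, c(2, 5, 7)]
  resid <- Xg - Sg %*% Ag
  expect_lt(max(abs(crossprod(Sg, resid))) / sum(Sg^2), 1e-8)
  # rank deficiency is flagged and the minimum-norm solution returned
  Xd <- cbind(Xg[, 1], Xg[, 1], Xg[, -1])
  Ad <- pinvFit(Xd, 1:2)
  expect_true(attr(Ad, "rankDeficient"))
  expect_false(attr(Ag, "rankDeficient"))
})

test_that("PCA reconstruction achieves the Eckart-Young optimum", {
  p <- pcaReconstruct(diag(c(3, 2, 1)), 2L)
  expect_equal(p$frobError, 1, tolerance = 1e-12)
  expect_equal(p$nrmse, 1 / sqrt(14), tolerance = 1e-12)
  # full-rank reconstruction is exact
  X <- randMat(10, 4, seed = 3)
  expect_lt(pcaReconstruct(X, 4L)$nrmse, 1e-9)
  # rank-1 matrix is exactly captured at k = 1
  u <- rnorm(12); v <- rnorm(5)
  expect_lt(pcaReconstruct(u %o% v, 1L)$nrmse, 1e-9)
  expect_error(pcaReconstruct(X, 0L), "rank")
  expect_error(pcaReconstruct(X, 9L), "rank")
})

test_that("PCA error equals the discarded-singular-value formula", {
  for (s in 1:5) {
    X <- randMat(25, 8, seed = 10 + s)
    # independent route: eigenvalues of the cross-product matrix
    ev <- sort(eigen(crossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    for (k in c(1L, 3L, 6L)) {
      expected <- sqrt(sum(ev[(k + 1):8]))
      expect_equal(pcaReconstruct(X, k)$frobError, expected,
                   tolerance = 1e-9 * expected)
    }
  }
})

test_that("greedy selection matches the exhaustive oracle at step one", {
  hits <- 0L
  for (s in 1:100) {
    X <- randMat(20, 6, seed = 1000 + s)
    hits <- hits + (leadIndices(sequentialSelect(X, 1L))[1L] ==
                      bruteBestColumn(X))
  }
  expect_identical(hits, 100L)
})

test_that("greedy pair error is bounded below by the exhaustive optimum", {
  for (s in 1:25) {
    X <- randMat(20, 6, seed = 2000 + s)
    sel <- sequentialSelect(X, 2L)
    greedyErr <- attr(sel, "stepErrors")[2L]
    expect_gte(greedyErr, bruteBestPairError(X) - 1e-9)
  }
})

test_that("greedy incremental update equals pseudoinverse refitting", {
  X <- randMat(40, 10, seed = 5)
  sel <- sequentialSelect(X, 6L)
  refit <- vapply(1:6, function(k) {
    idx <- leadIndices(sel)[seq_len(k)]
    A <- pinvFit(X, idx)
    sqrt(sum((X - X[, idx, drop = FALSE] %*% A)^2))
  }, numeric(1L))
  expect_equal(attr(sel, "stepErrors"), refit, tolerance = 1e-9)
  # fit errors are nonincreasing in subset size
  expect_true(all(diff(attr(sel, "stepErrors")) <= 1e-12))
})

test_that("a duplicated column is never selected after its twin", {
  X <- randMat(20, 5, seed = 6)
  Xd <- cbind(X, X[, 2])  # column 6 duplicates column 2
  sel <- leadIndices(sequentialSelect(Xd, 5L))
  if (6L %in% sel) expect_false(2L %in% sel[seq_len(which(sel == 6L))])
  if (2L %in% sel) expect_false(6L %in% sel)
})

test_that("NRMSE follows its definition", {
  X <- randMat(8, 3, seed = 7)
  expect_equal(nrmse(X, X), 0)
  expect_equal(nrmse(X, 0 * X), 1)
  expect_error(nrmse(X, X[, 1:2]), "shape")
  expect_error(nrmse(0 * X, X), "zero")
})

test_that("ABSE averages per-lead DF differences and ignores amplitude", {
  X <- toneMatrix(c(5, 7))
  Xh <- toneMatrix(c(5, 8))
  expect_equal(as.numeric(abse(X, Xh, fs = 1000)), 0.5, tolerance = 0.03)
  expect_equal(as.numeric(abse(X, X, fs = 1000)), 0)
  expect_equal(as.numeric(abse(X, 3 * X, fs = 1000)), 0)
})

test_that("anchored subset reconstruction reuses the anchor mixing", {
  seg <- generateAASegment(smallSynthConfig(seed = 8L))
  wins <- segmentWindows(seg)
  sub <- sequentialSelect(wins[[1L]], 8L)
  # on the anchor window itself this is the least-squares fit
  r1 <- subsetReconstruct(wins[[1L]], sub)
  A <- pinvFit(wins[[1L]], leadIndices(sub))
  direct <- nrmse(wins[[1L]],
                  wins[[1L]][, leadIndices(sub), drop = FALSE] %*% A)
  expect_equal(r1$nrmse, direct, tolerance = 1e-12)
  # stationary data: out-of-sample windows agree within 10% (the anchor
  # window itself sits below them by in-sample fitting optimism)
  r2 <- subsetReconstruct(wins[[2L]], sub)
  r3 <- subsetReconstruct(wins[[3L]], sub)
  expect_lt(abs(r3$nrmse - r2$nrmse) / r2$nrmse, 0.10)
  expect_lte(r1$nrmse, r2$nrmse + 1e-12)
  # consistent lead permutation leaves the NRMSE unchanged
  perm <- sample(ncol(wins[[1L]]))
  Xp <- wins[[2L]][, perm]
  subP <- ElectrodeSubset(match(leadIndices(sub), perm), kind = "SEQ",
                          mixing = mixingMatrix(sub)[, perm, drop = FALSE])
  expect_equal(subsetReconstruct(Xp, subP)$nrmse, r2$nrmse,
               tolerance = 1e-12)
})

test_that("error profiles respect the PCA lower bound and k-monotonicity", {
  seg <- generateAASegment(smallSynthConfig(seed = 9L, nLeads = 24L))
  prof <- subsetErrorProfile(seg, kinds = c("SEQ", "PCA"), kRange = 8:12)
  pca <- prof[prof$kind == "PCA", ]
  seq_ <- prof[prof$kind == "SEQ", ]
  expect_true(all(diff(pca$nrmse) <= 1e-12))
  expect_true(all(diff(seq_$nrmse) <= 1e-12))
  expect_true(all(seq_$nrmse >= pca$nrmse - 1e-9))
})

test_that("anchored error profiles are never below per-window refits", {
  seg <- generateAASegment(smallSynthConfig(seed = 10L, nLeads = 24L))
  pw <- subsetErrorProfile(seg, kinds = "SEQ", kRange = c(8L, 10L))
  an <- subsetErrorProfile(seg, kinds = "SEQ", kRange = c(8L, 10L),
                           mode = "anchored")
  expect_true(all(an$nrmse >= pw$nrmse - 1e-9))
})
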