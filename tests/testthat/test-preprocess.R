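test_that("bad-lead interpolation is a weighted neighbor average", {
  # all leads good: exact no-op
  rec <- BspmRecording(randMat(50, 12, seed = 41), fs = 1000)
  expect_identical(signalMatrix(interpolateBadLeads(rec)), signalMatrix(rec))
  # a bad lead surrounded by equidistant good leads carrying s(t) gets s(t)
  pos <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(5, 5))
  geom <- new("VestGeometry", nLeads = 6L,
              positions = matrix(as.numeric(pos), ncol = 2),
              ecg8 = integer(0), ecg11 = integer(0))
  s <- sin(2 * pi * 6 * seq(0, 1, by = 1e-3))
  x <- cbind(0 * s, s, s, s, s, rnorm(length(s)))
  recB <- BspmRecording(x, fs = 1000, geometry = geom,
                        leadQuality = c(FALSE, rep(TRUE, 5)))
  out <- interpolateBadLeads(recB, K = 4L)
  expect_equal(signalMatrix(out)[, 1L], s, tolerance = 1e-12)
  expect_identical(out@leadQuality, recB@leadQuality)
  # K = 3: hand-computed inverse-distance weights
  pos3 <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 0), c(9, 9))
  geom3 <- new("VestGeometry", nLeads = 5L,
               positions = matrix(as.numeric(pos3), ncol = 2),
               ecg8 = integer(0), ecg11 = integer(0))
  x3 <- cbind(rep(0, 10), rep(1, 10), rep(2, 10), rep(3, 10), rep(4, 10))
  rec3 <- BspmRecording(x3, fs = 100, geometry = geom3,
                        leadQuality = c(FALSE, rep(TRUE, 4)))
  w <- (1 / c(1, 2, 3)) / sum(1 / c(1, 2, 3))
  expected <- sum(w * c(1, 2, 3))
  out3 <- interpolateBadLeads(rec3, K = 3L)
  expect_equal(signalMatrix(out3)[1L, 1L], expected, tolerance = 1e-12)
  # more than half bad: quality error
  recQ <- BspmRecording(x3, fs = 100, geometry = geom3,
                        leadQuality = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(interpolateBadLeads(recQ), "50%")
})

test_that("the band-pass keeps the passband and rejects drift and mains", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mk <- function(sig) BspmRecording(cbind(sig), fs = fs)
  mid <- function(v) v[(length(v) %/% 4):(3 * length(v) %/% 4)]
  # 10 Hz unit tone: amplitude preserved within 5%
  out10 <- signalMatrix(bandpassRecording(mk(sin(2 * pi * 10 * t))))[, 1L]
  expect_lt(abs(max(mid(out10)) - 1), 0.05)
  # 0.05 Hz drift of amplitude 5: residual amplitude < 0.5
  drift <- signalMatrix(bandpassRecording(mk(5 * sin(2 * pi * 0.05 * t))))[, 1L]
  expect_lt(max(abs(mid(drift))), 0.5)
  # 60 Hz tone attenuated by > 20 dB
  out60 <- signalMatrix(bandpassRecording(mk(sin(2 * pi * 60 * t))))[, 1L]
  expect_lt(sqrt(mean(mid(out60)^2)) / sqrt(0.5), 10^(-20 / 20))
  # zero-phase: a symmetric pulse stays symmetric
  pulse <- exp(-(t - 10)^2 / (2 * 0.05^2))
  outP <- signalMatrix(bandpassRecording(mk(pulse)))[, 1L]
  expect_equal(which.max(outP), which.max(pulse), tolerance = 2)
  left <- outP[(which.max(outP) - 200):(which.max(outP) - 1)]
  right <- rev(outP[(which.max(outP) + 1):(which.max(outP) + 200)])
  expect_lt(max(abs(left - right)), 1e-3 * max(abs(outP)))
  expect_error(bandpassRecording(BspmRecording(cbind(rnorm(100)), fs = 50)),
               "sampling rate")
})

test_that("R-peak detection recovers the true beats of a synthetic recording", {
  cfg <- smallSynthConfig(seed = 42L, durationS = 20)
  g <- generateRecording(cfg)
  rec <- bandpassRecording(g$recording)
  peaks <- detectRPeaks(rec)
  truth <- g$groundTruth$rPeaks
  tol <- round(0.030 * cfg$fs)
  matched <- vapply(truth, function(p) any(abs(peaks - p) <= tol), logical(1L))
  falseDet <- vapply(peaks, function(p) all(abs(truth - p) > tol), logical(1L))
  expect_gte(mean(matched), 0.95)
  expect_lte(mean(falseDet), 0.05)
  expect_true(all(diff(peaks) >= round(0.2 * cfg$fs)))
  # determinism and the zero-signal edge case
  expect_identical(detectRPeaks(rec), peaks)
  zero <- BspmRecording(matrix(0, 2000, 3), fs = 1000)
  expect_length(detectRPeaks(zero), 0L)
})

test_that("delineation clusters beat shapes correctly", {
  fs <- 500
  tmpl <- exp(-(seq(0, 0.4, by = 1 / fs) - 0.06)^2 / (2 * 0.01^2))
  m <- 10 * fs
  onsets <- seq(0.3, 9.2, by = 0.7)
  mkRec <- function(polarity) {
    x <- matrix(0, m, 4)
    for (b in seq_along(onsets)) {
      i0 <- round(onsets[b] * fs)
      idx <- i0:(i0 + length(tmpl) - 1L)
      x[idx, ] <- x[idx, ] + polarity[b] * tmpl %o% c(1, 0.8, -0.5, 0.3)
    }
    BspmRecording(x + 1e-6 * matrix(rnorm(length(x)), m, 4), fs = fs)
  }
  peaks <- as.integer(round(onsets * fs) + round(0.06 * fs))
  # one morphology: a single effective cluster, template matches the truth
  recU <- mkRec(rep(1, length(onsets)))
  bsU <- delineateAndCluster(recU, peaks)
  expect_equal(max(bsU$clusterLabels), 1L)
  lead1 <- bsU$templates[[1L]][, 1L]
  ref <- recU@samples[(peaks[3] - bsU$preSamples):(peaks[3] + 200), 1L]
  expect_gt(cor(lead1[seq_along(ref)], ref), 0.99)
  # alternating polarity: two clusters with alternating labels
  recA <- mkRec(rep(c(1, -1), length.out = length(onsets)))
  bsA <- delineateAndCluster(recA, peaks)
  expect_equal(max(bsA$clusterLabels), 2L)
  expect_true(all(bsA$clusterLabels[c(TRUE, FALSE)] ==
                    bsA$clusterLabels[1L]))
  expect_true(all(bsA$clusterLabels[c(FALSE, TRUE)] ==
                    bsA$clusterLabels[2L]))
  # nClusters = 1 forces a single label
  bs1 <- delineateAndCluster(recA, peaks, nClusters = 1L)
  expect_true(all(bs1$clusterLabels == 1L))
  expect_error(delineateAndCluster(recU, peaks[1L]), "2 beats")
})

test_that("QRST cancellation subtracts fitted templates and nothing else", {
  cfg <- smallSynthConfig(seed = 43L, durationS = 20)
  g <- generateRecording(cfg)
  rec <- bandpassRecording(g$recording)
  peaks <- detectRPeaks(rec)
  beats <- delineateAndCluster(rec, peaks)
  # doubling the ventricular amplitude doubles the fitted per-beat scale
  recD <- BspmRecording(2 * signalMatrix(rec) - signalMatrix(
    bandpassRecording(BspmRecording(g$groundTruth$aa, fs = cfg$fs))),
    fs = cfg$fs)
  resD <- cancelQRST(recD, beats, details = TRUE)
  expect_equal(median(resD$fits$medianScale), 2, tolerance = 0.15)
  # with (near-)zero templates there is nothing to subtract
  noise <- BspmRecording(matrix(rnorm(5000 * 4, sd = 0.01), 5000, 4),
                         fs = 500)
  pk <- as.integer(seq(300, 4500, by = 350))
  bsN <- delineateAndCluster(noise, pk)
  outN <- cancelQRST(noise, bsN)
  expect_equal(signalMatrix(outN), signalMatrix(noise),
               tolerance = 0.05)
})

test_that("finalization normalizes, smooths and is idempotent", {
  cfg <- smallSynthConfig(seed = 44L)
  # finalization operates on band-passed, cancellation-stage output
  rec <- bandpassRecording(generateRecording(cfg)$recording)
  seg <- AASegment(signalMatrix(rec), fs = cfg$fs)
  fin <- finalizeSegment(seg)
  x <- signalMatrix(fin)
  expect_lt(max(abs(colMeans(x))), 1e-9)
  expect_lt(max(abs(apply(x, 2, sd) - 1)), 1e-6)
  # a 50 Hz contaminant is attenuated by > 20 dB
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  cont <- AASegment(cbind(sin(2 * pi * 6 * t) + sin(2 * pi * 50 * t),
                          rnorm(length(t))), fs = 1000)
  out <- signalMatrix(finalizeSegment(cont))[, 1L]
  spec <- welchPsd(out, fs = 1000)
  p50 <- spec$psd[which.min(abs(spec$freq - 50))]
  p6 <- spec$psd[which.min(abs(spec$freq - 6))]
  expect_lt(p50 / p6, 10^(-20 / 10))
  # near-idempotence: a second pass changes < 3% RMS (bounded by the
  # Butterworth passband rolloff acting on the f-wave third harmonic,
  # ~21 Hz, which sits close to the 30 Hz cutoff)
  fin2 <- finalizeSegment(fin)
  rel <- sqrt(sum((signalMatrix(fin2) - signalMatrix(fin))^2) /
                sum(signalMatrix(fin)^2))
  expect_lt(rel, 0.03)
  # constant leads are tolerated up to 10%
  xc <- randMat(1000, 12, seed = 45); xc[, 1] <- 5
  expect_error(finalizeSegment(AASegment(cbind(xc[, 1:3] * 0, xc[, 4:12]),
                                         fs = 100)), "constant")
})

test_that("the full preprocessing chain recovers the atrial activity", {
  cfg <- smallSynthConfig(seed = 46L, durationS = 20)
  g <- generateRecording(cfg)
  fin <- preprocessRecording(g$recording)
  cors <- vapply(seq_len(numLeads(fin)), function(l)
    cor(signalMatrix(fin)[, l], g$groundTruth$aa[, l]), numeric(1L))
  expect_gte(median(cors), 0.9)
})
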