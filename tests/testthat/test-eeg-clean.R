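test_that("AAS cancels a TR-identical gradient artifact to machine precision", {
  # artifact-only recording: oscillators and background silenced
  cfg <- smallConfig(seed = 2, nVolumes = 40L,
                     bands = oneAlphaBand(meanAmp = 0), backgroundSd = 0,
                     artifact = list(gradientAmp = 160, gradientJitterSd = 0,
                                     bcgAmp = 0, rrMean = 0.9, rrSd = 0.04,
                                     bcgDelay = 0.21))
  rec <- simulateEEG(cfg, 1)
  pre <- max(abs(eegData(rec)))
  out <- removeGradientArtifact(rec)
  expect_gt(pre, 100)
  expect_lt(max(abs(eegData(out))) / pre, 1e-10)
})

test_that("AAS distortion of artifact-free data is bounded by window leakage", {
  cfg <- smallConfig(seed = 3, nVolumes = 40L, backgroundSd = 2,
                     artifact = list(gradientAmp = 0, gradientJitterSd = 0,
                                     bcgAmp = 0, rrMean = 0.9, rrSd = 0.04,
                                     bcgDelay = 0.21))
  rec <- simulateEEG(cfg, 1)
  out <- removeGradientArtifact(rec)
  relChange <- sum((eegData(out) - eegData(rec))^2) / sum(eegData(rec)^2)
  expect_lt(relChange, 3 / 21)   # sliding template leaks ~1/window of signal
})

test_that("AAS attenuates TR-locked power by > 100x on default simulated data", {
  cfg <- smallConfig(seed = 5, nVolumes = 60L)
  rec <- simulateEEG(cfg, 1)
  len <- floor(cfg@tr * cfg@eegRate)
  pre <- lockedAveragePower(eegData(rec), triggerIndices(rec), len)
  out <- removeGradientArtifact(rec)
  post <- lockedAveragePower(eegData(out), triggerIndices(out), len)
  expect_lt(post / pre, 1e-2)
})

test_that("AAS is idempotent on its artifact target", {
  cfg <- smallConfig(seed = 6, nVolumes = 60L)
  rec <- simulateEEG(cfg, 1)
  once <- removeGradientArtifact(rec)
  twice <- removeGradientArtifact(once)
  firstCorrection <- sqrt(mean((eegData(once) - eegData(rec))^2))
  secondChange <- sqrt(mean((eegData(twice) - eegData(once))^2))
  expect_lt(secondChange / firstCorrection, 0.01)
})

test_that("irregular trigger spacing is rejected with a diagnostic", {
  cfg <- smallConfig(seed = 2, nVolumes = 40L)
  rec <- simulateEEG(cfg, 1)
  rec@triggers[10] <- rec@triggers[10] + as.integer(0.2 * cfg@eegRate)
  expect_error(removeGradientArtifact(rec), "spacing")
})

test_that("QRS detection recovers simulated R peaks exactly on clean ECG", {
  cfg <- smallConfig(seed = 7, nVolumes = 60L)
  rec <- simulateEEG(cfg, 1)
  peaks <- detectQRS(ecgTrace(rec), samplingRate(rec))
  truth <- rec@meta$rPeaks
  expect_equal(length(peaks), length(truth))
  offsets <- vapply(truth, function(p) min(abs(peaks - p)), numeric(1))
  expect_lte(max(offsets), 1)
})

test_that("QRS detection tolerates 10% additive noise", {
  cfg <- smallConfig(seed = 8, nVolumes = 60L)
  rec <- simulateEEG(cfg, 1)
  set.seed(99)
  noisy <- ecgTrace(rec) + rnorm(length(ecgTrace(rec)), 0, 80)  # R amp 800
  peaks <- detectQRS(noisy, samplingRate(rec))
  truth <- rec@meta$rPeaks
  offsets <- vapply(truth, function(p) min(abs(peaks - p)), numeric(1))
  expect_gte(mean(offsets <= 2), 0.99)
})

test_that("flat-line ECG is rejected", {
  expect_error(detectQRS(rep(0, 10000), 500), "flat")
})

test_that("BCG subtraction cancels an identical cardiac template exactly", {
  cfg <- smallConfig(seed = 9, nVolumes = 40L,
                     bands = oneAlphaBand(meanAmp = 0), backgroundSd = 0,
                     artifact = list(gradientAmp = 0, gradientJitterSd = 0,
                                     bcgAmp = 40, rrMean = 0.9, rrSd = 0,
                                     bcgDelay = 0.21))
  rec <- simulateEEG(cfg, 1)
  pre <- max(abs(eegData(rec)))
  out <- removeBCG(rec, rec@meta$rPeaks)
  expect_gt(pre, 10)
  # interior beats cancel exactly; run edges keep at most a few beats' worth
  interior <- eegData(out)[, seq(10 * 500, 70 * 500)]
  expect_lt(max(abs(interior)) / pre, 1e-10)
})

test_that("BCG subtraction attenuates R-locked power >= 10x with RR jitter", {
  cfg <- smallConfig(seed = 10, nVolumes = 60L,
                     artifact = list(gradientAmp = 0, gradientJitterSd = 0,
                                     bcgAmp = 40, rrMean = 0.9, rrSd = 0.04,
                                     bcgDelay = 0.21))
  rec <- simulateEEG(cfg, 1)
  peaks <- detectQRS(ecgTrace(rec), samplingRate(rec))
  delay <- as.integer(round(0.21 * samplingRate(rec)))
  len <- as.integer(0.5 * samplingRate(rec))
  pre <- lockedAveragePower(eegData(rec), peaks + delay, len)
  out <- removeBCG(rec, peaks)
  post <- lockedAveragePower(eegData(out), peaks + delay, len)
  expect_lt(post / pre, 0.1)
})

test_that("the filter chain passes 10 Hz, blocks 50 Hz and 18 Hz, lands at 256 Hz", {
  rate <- 500
  t <- (0:(60 * rate - 1)) / rate
  mk <- function(f) {
    data <- rbind(sin(2 * pi * f * t), sin(2 * pi * f * t + 1))
    new("EEGRecording", data = data, rate = rate, labels = c("Cz", "Pz"),
        triggers = as.integer(round((0:24) * 2.1 * rate)) + 1L)
  }
  ampOut <- function(f) {
    out <- filterChain(mk(f))
    mid <- eegData(out)[1, seq(0.25 * ncol(eegData(out)),
                               0.75 * ncol(eegData(out)))]
    sd(mid) * sqrt(2)
  }
  out <- filterChain(mk(10))
  expect_equal(samplingRate(out), 256)
  expect_equal(length(triggerIndices(out)), 25)
  # triggers re-indexed to the new rate
  expect_lt(max(abs(triggerIndices(out) -
                      (round((0:24) * 2.1 * 256) + 1))), 3)
  a10 <- ampOut(10)
  expect_gt(a10, 0.7)
  expect_lte(a10, 1.005)
  expect_gt(ampOut(30), 0.7)                 # 20-45 Hz stays in the passband
  expect_lt(ampOut(50), 0.1)                 # mains notch
  expect_lt(ampOut(18), 0.1)                 # residual slice-artifact reject
  expect_gt(ampOut(15), 0.6)                 # reject band is narrow
  expect_gt(ampOut(21), 0.6)
})

test_that("bad epochs are replaced by their nearest (earlier on tie) good epoch", {
  cfg <- smallConfig(seed = 12, eegRate = 256, nVolumes = 12L)
  rec <- simulateEEG(cfg, 1, artifacts = FALSE)
  len <- floor(median(diff(triggerIndices(rec))))
  seg <- function(r, i) eegData(r)[, triggerIndices(r)[i] + 0:(len - 1L)]
  out0 <- replaceBadEpochs(rec, integer(0))
  expect_identical(eegData(out0), eegData(rec))
  out <- replaceBadEpochs(rec, 5L)
  expect_identical(seg(out, 5), seg(rec, 4))  # earlier neighbor wins the tie
  expect_identical(seg(out, 6), seg(rec, 6))
  outB <- replaceBadEpochs(rec, 1L)
  expect_identical(seg(outB, 1), seg(rec, 2)) # boundary: only later neighbor
  expect_error(replaceBadEpochs(rec, 1:12), "all epochs")
})

test_that("average reference zeroes the scalp mean and skips ECG channels", {
  data <- rbind(c(2, 2, 2), c(4, 4, 4), c(100, 100, 100))
  rec <- new("EEGRecording", data = data, rate = 10,
             labels = c("Cz", "Pz", "ECG"), triggers = 1L)
  out <- rereferenceAverage(rec)
  expect_equal(eegData(out)[1, ], rep(-1, 3))
  expect_equal(eegData(out)[2, ], rep(1, 3))
  expect_equal(eegData(out)[3, ], rep(100, 3))  # ECG untouched
  set.seed(1)
  rec2 <- new("EEGRecording", data = matrix(rnorm(40), 4), rate = 10,
              labels = c("Fz", "Cz", "Pz", "Oz"), triggers = 1L)
  out2 <- rereferenceAverage(rec2)
  expect_lt(max(abs(colMeans(eegData(out2)))), 1e-12)
})

test_that("every cleaning stage preserves channel count, labels, and history", {
  cfg <- smallConfig(seed = 14, nVolumes = 40L)
  rec <- simulateEEG(cfg, 1)
  clean <- cleanEEG(rec)
  expect_equal(channelLabels(clean), channelLabels(rec))
  expect_equal(nrow(eegData(clean)), nrow(eegData(rec)))
  ops <- vapply(historyLog(clean), `[[`, character(1), "op")
  expect_equal(ops, c("simulateEEG", "removeGradientArtifact", "removeBCG",
                      "filterChain", "rereferenceAverage"))
})
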