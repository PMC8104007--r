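test_that("identical seed reproduces EEG and BOLD byte-identically", {
  cfg <- smallConfig(seed = 3, nVolumes = 20L)
  r1 <- simulateEEG(cfg, 1)
  r2 <- simulateEEG(cfg, 1)
  expect_identical(eegData(r1), eegData(r2))
  expect_identical(ecgTrace(r1), ecgTrace(r2))
  b1 <- simulateBold(cfg, NULL, 1, "A")
  b2 <- simulateBold(cfg, NULL, 1, "A")
  expect_identical(boldData(b1), boldData(b2))
  r3 <- simulateEEG(smallConfig(seed = 4, nVolumes = 20L), 1)
  expect_false(identical(eegData(r1), eegData(r3)))
})

test_that("a too-short recording is rejected", {
  cfg <- smallConfig(nVolumes = 20L)
  expect_error(simulateEEG(cfg, 1, durationS = 30), "shorter")
})

test_that("constant envelope yields constant per-epoch alpha power", {
  cfg <- smallConfig(seed = 5, eegRate = 256, bands = oneAlphaBand(),
                     backgroundSd = 0)
  rec <- simulateEEG(cfg, 1, artifacts = FALSE)
  spectra <- volumeSpectra(rec, cfg@tr)
  bp <- bandPower(spectra, bandDefinitions("alpha1"))
  series <- powerValues(gsp(bp, bandDefinitions("alpha1")))
  expect_lt(sd(series) / mean(series), 0.02)
})

test_that("realized per-epoch alpha power has the envelope's autocorrelation", {
  # closed form for the lag-1 autocorrelation of the squared log-normal AR(1)
  # envelope: (exp(4 rho s2) - 1) / (exp(4 s2) - 1), s2 = innovSd^2/(1-rho^2)
  a <- 0.9; s <- 0.3
  s2 <- s^2 / (1 - a^2)
  theory <- (exp(4 * a * s2) - 1) / (exp(4 * s2) - 1)
  cfg <- smallConfig(seed = 11, eegRate = 256, nVolumes = 185L,
                     bands = oneAlphaBand(arCoef = a, innovSd = s),
                     backgroundSd = 0)
  rec <- simulateEEG(cfg, 1, artifacts = FALSE)
  spectra <- volumeSpectra(rec, cfg@tr)
  bp <- bandPower(spectra, bandDefinitions("alpha1"), units = "power")
  measured <- rowMeans(bp)
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  truth <- oscoupler:::.truthPower(cfg, 1)[, "alpha1"]
  # same realization: measured per-epoch power tracks the generating envelope
  expect_gt(cor(measured, truth), 0.99)
  expect_lt(abs(lag1(measured) - lag1(truth)), 0.05)
  # and the realization agrees with the closed-form process autocorrelation
  # up to sampling error over 185 epochs
  expect_lt(abs(lag1(measured) - theory), 0.15)
})

test_that("single oscillator concentrates >= 90% of power in its band", {
  cfg <- smallConfig(seed = 7, eegRate = 256, bands = oneAlphaBand(freq = 9),
                     backgroundSd = 0)
  rec <- simulateEEG(cfg, 1, artifacts = FALSE)
  spectra <- volumeSpectra(rec, cfg@tr)
  bands <- bandDefinitions()
  pw <- sapply(seq_len(nrow(bands)), function(i) {
    sel <- spectra@freqs >= bands$lo[i] & spectra@freqs <= bands$hi[i]
    sum(spectra@amplitude[, , sel]^2)
  })
  total <- sum(spectra@amplitude[, , spectra@freqs > 0]^2)
  expect_gt(pw[bands$name == "alpha1"] / total, 0.9)
})

test_that("noise-free BOLD is its constant baseline when nothing is planted", {
  cfg <- smallConfig(seed = 9, coupling = noCoupling, alffRois = noAlffRois,
                     boldNoise = quietNoise(sd = 0))
  run <- simulateBold(cfg, NULL, 1, "A")
  inside <- boldData(run)[array(analysisMask(run) > 0,
                                dim(boldData(run)))]
  expect_equal(range(inside), c(100, 100))
})

test_that("with beta = 1 and no noise the ROI carries exactly the regressor", {
  cfg <- smallConfig(seed = 9, boldNoise = quietNoise(sd = 0),
                     alffRois = noAlffRois,
                     coupling = data.frame(roi = "thalamus", band = "alpha1",
                                           group = "A", beta = 1,
                                           stringsAsFactors = FALSE))
  run <- simulateBold(cfg, NULL, 1, "A")
  truth <- oscoupler:::.truthPower(cfg, 1)
  reg <- convolveHRF(zscore(truth[, "alpha1"]), cfg@tr)
  rv <- roiVoxels(cfg, "thalamus")
  flat <- array(boldData(run), c(prod(dim(boldData(run))[1:3]),
                                 cfg@nVolumes))
  for (v in rv[c(1, length(rv) %/% 2, length(rv))])
    expect_equal(flat[v, ] - 100, reg, tolerance = 1e-12)
  # coupling realism: correlation of regressor with the noiseless ROI signal
  expect_equal(cor(flat[rv[1], ], reg), 1, tolerance = 1e-12)
})

test_that("BOLD noise is AR(1) with the configured coefficient", {
  # oracle: stats::filter-based AR(1) has lag-1 autocorrelation rho
  cfg <- smallConfig(seed = 13, nVolumes = 185L, coupling = noCoupling,
                     alffRois = noAlffRois, boldNoise = quietNoise(rho = 0.3))
  run <- simulateBold(cfg, NULL, 1, "A")
  flat <- array(boldData(run), c(prod(dim(boldData(run))[1:3]), 185L))
  midx <- which(analysisMask(run) > 0)[1:200]
  lag1 <- vapply(midx, function(v) {
    y <- flat[v, ] - mean(flat[v, ])
    sum(y[-1] * y[-185]) / sum(y^2)
  }, numeric(1))
  expect_lt(abs(mean(lag1) - 0.3), 0.05)
})

test_that("cohorts have the requested layout and are seed-reproducible", {
  cfg <- smallConfig(seed = 17, nPerGroup = 3L, eegMode = "power",
                     nVolumes = 30L)
  coh <- simulateCohort(cfg)
  expect_length(coh$subjects, 6)
  expect_equal(sort(unique(coh$design$group)), c("A", "B"))
  expect_equal(as.vector(table(coh$design$group)), c(3, 3))
  expect_length(coh$truth@power, 6)
  # planted group difference is recorded in the ground truth
  expect_equal(coh$truth@coupling$beta[coh$truth@coupling$group == "A"], 0.8)
  expect_equal(coh$truth@coupling$beta[coh$truth@coupling$group == "B"], 0)
  coh2 <- simulateCohort(cfg)
  expect_identical(coh$design, coh2$design)
  expect_identical(coh$truth@power, coh2$truth@power)
  expect_error(simulateCohort(smallConfig(nPerGroup = 1L)), "nPerGroup")
})

test_that("cohort files round-trip through the interchange formats", {
  cfg <- smallConfig(seed = 19, nPerGroup = 2L, nVolumes = 10L,
                     eegRate = 256)
  dir <- withr::local_tempdir()
  coh <- simulateCohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_length(list.files(dir, pattern = "_eeg\\.tsv$"), 4)
  expect_length(list.files(dir, pattern = "_bold\\.nii$"), 4)
  rec <- readEEG(file.path(dir, "A01_eeg"))
  expect_equal(eegData(rec), eegData(coh$subjects[[1]]$eeg),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(triggerIndices(rec),
                   triggerIndices(coh$subjects[[1]]$eeg))
  run <- readBoldRun(file.path(dir, "A01_bold.nii"),
                     maskPath = file.path(dir, "mask.nii"))
  expect_equal(boldData(run), boldData(coh$subjects[[1]]$bold),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(analysisMask(run)),
               sum(analysisMask(coh$subjects[[1]]$bold)))
})

test_that("YAML configuration round-trips scalar and table fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 42", "nPerGroup: 3", "nVolumes: 25", "eegRate: 250",
    "eegMode: power",
    "coupling:",
    "  - {roi: thalamus, band: alpha1, group: A, beta: 0.5}",
    "  - {roi: thalamus, band: alpha1, group: B, beta: 0.0}",
    "boldNoise: {rho: 0.2, sd: 0.5}"), path)
  cfg <- readSimConfig(path)
  expect_s4_class(cfg, "SimConfig")
  expect_equal(cfg@seed, 42L)
  expect_equal(cfg@nVolumes, 25L)
  expect_equal(cfg@coupling$beta, c(0.5, 0))
  expect_equal(cfg@boldNoise$rho, 0.2)
  expect_equal(cfg@boldNoise$driftAmp, 1)   # default preserved by merge
})
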