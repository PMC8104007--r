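test_that("the DCT drift basis holds exactly the periods above the cutoff", {
  cfg <- smallConfig(seed = 1, nVolumes = 185L, eegMode = "power")
  run <- simulateBold(cfg, NULL, 1, "A")
  design <- buildDesign(rnorm(185), run)
  # oracle: enumerate k with period 2*T*tr/k above the 128 s cutoff
  K <- sum(2 * 185 * 2.1 / seq_len(185) > 128)
  expect_equal(K, 6)
  expect_equal(sum(grepl("^dct", design@names)), K)
  # DCT columns are mutually orthogonal
  D <- design@X[, grepl("^dct", design@names)]
  off <- crossprod(D) - diag(diag(crossprod(D)))
  expect_lt(max(abs(off)), 1e-8)
})

test_that("a unit impulse modulator reproduces the HRF samples", {
  cfg <- smallConfig(seed = 2, nVolumes = 40L, eegMode = "power")
  run <- simulateBold(cfg, NULL, 1, "A")
  impulse <- c(1, rep(0, 39))
  design <- buildDesign(impulse, run, center = FALSE)
  h <- canonicalHRF(seq(0, 32, by = 2.1))
  expect_equal(unname(design@X[, "interest"]),
               c(h, rep(0, 40 - length(h))), tolerance = 1e-12)
})

test_that("a constant modulator is flagged as degenerate", {
  cfg <- smallConfig(seed = 3, nVolumes = 30L, eegMode = "power")
  run <- simulateBold(cfg, NULL, 1, "A")
  expect_warning(
    expect_warning(d <- buildDesign(rep(5, 30), run), "constant series"),
    "degenerate")
  expect_true(all(d@X[, "interest"] == 0))
})

test_that("GLS at rho = 0 equals brute-force normal equations to 1e-8", {
  set.seed(11)
  for (i in 1:100) {
    T <- 20
    X <- cbind(rnorm(T), rnorm(T), 1)
    colnames(X) <- c("interest", "x2", "intercept")
    design <- new("DesignMatrix", X = X,
                  names = colnames(X), interest = 1L, hpCutoff = 128,
                  tr = 2.1)
    Y <- matrix(rnorm(5 * T), 5, T)
    run <- new("BoldRun", data = array(t(t(Y)), c(5, 1, 1, T)), voxelMm = 3,
               tr = 2.1, affine = diag(4), mask = array(1, c(5, 1, 1)),
               motion = matrix(0, 0, 6), wm = numeric(0), csf = numeric(0))
    fit <- fitFirstLevel(run, design, rho = 0)
    oracle <- solve(crossprod(X), crossprod(X, t(Y)))
    expect_lt(max(abs(fit$beta - oracle)), 1e-8)
  }
})

test_that("noiseless voxels give exact betas and saturated t maps", {
  set.seed(13)
  T <- 60
  x <- convolveHRF(zscore(rnorm(T)), 2.1)
  X <- cbind(interest = x, intercept = 1)
  design <- new("DesignMatrix", X = X, names = colnames(X), interest = 1L,
                hpCutoff = 128, tr = 2.1)
  Y <- matrix(rep(2 * x + 5, 3), 3, T, byrow = TRUE)
  run <- new("BoldRun", data = array(Y, c(3, 1, 1, T)), voxelMm = 3,
             tr = 2.1, affine = diag(4), mask = array(1, c(3, 1, 1)),
             motion = matrix(0, 0, 6), wm = numeric(0), csf = numeric(0))
  fit <- fitFirstLevel(run, design, rho = 0)
  expect_equal(unname(fit$beta["interest", ]), rep(2, 3), tolerance = 1e-10)
  expect_equal(unname(fit$beta["intercept", ]), rep(5, 3), tolerance = 1e-10)
  tm <- contrastT(fit)
  expect_true(tm@provenance$saturated)
  expect_true(all(statValues(tm) == oscoupler:::.T_CAP))
  # sign flip of the contrast flips t
  tm2 <- contrastT(fit, c(-1, 0))
  expect_equal(statValues(tm2)[, 1, 1], -statValues(tm)[, 1, 1])
})

test_that("t and F statistics are invariant to rescaling the modulator", {
  cfg <- smallConfig(seed = 17, nVolumes = 60L, eegMode = "power")
  run <- simulateBold(cfg, NULL, 1, "A")
  pw <- oscoupler:::.truthPower(cfg, 1)[, "alpha1"]
  t1 <- contrastT(fitFirstLevel(run, buildDesign(pw, run)))
  t2 <- contrastT(fitFirstLevel(run, buildDesign(pw * 100, run)))
  expect_equal(statValues(t1), statValues(t2), tolerance = 1e-8)
})

test_that("one-sample group t agrees with the textbook statistic", {
  set.seed(19)
  mkMap <- function(v) new("StatMap", values = array(v, c(5, 1, 1)),
                           stat = "beta", df = 0,
                           mask = array(1, c(5, 1, 1)), affine = diag(4),
                           voxelMm = 3)
  vals <- matrix(rnorm(5 * 6, mean = 0.4), 5, 6)
  maps <- lapply(1:6, function(i) mkMap(vals[, i]))
  out <- groupOneSample(maps)
  expect_equal(out@df, 5)
  for (v in 1:5) {
    oracle <- t.test(vals[v, ])$statistic
    expect_equal(unname(statValues(out)[v, 1, 1]), unname(oracle),
                 tolerance = 1e-10)
  }
  # symmetric +/- pairs give t = 0
  sym <- lapply(c(1, -1, 2, -2), function(s) mkMap(rep(s, 5)))
  expect_equal(unname(statValues(groupOneSample(sym))[, 1, 1]), rep(0, 5))
  # identical constant maps saturate
  same <- lapply(1:3, function(i) mkMap(rep(3, 5)))
  outS <- groupOneSample(same)
  expect_true(outS@provenance$saturated)
})

test_that("the group F contrast is the squared two-sample t", {
  set.seed(23)
  mkMap <- function(v) new("StatMap", values = array(v, c(7, 1, 1)),
                           stat = "beta", df = 0,
                           mask = array(1, c(7, 1, 1)), affine = diag(4),
                           voxelMm = 3)
  vals <- matrix(rnorm(7 * 8), 7, 8)
  groups <- rep(c("A", "B"), each = 4)
  maps <- lapply(1:8, function(i) mkMap(vals[, i]))
  fmap <- groupFContrast(maps, groups)
  expect_equal(fmap@df, c(1, 6))
  for (v in 1:7) {
    tt <- t.test(vals[v, 1:4], vals[v, 5:8], var.equal = TRUE)$statistic
    expect_equal(unname(statValues(fmap)[v, 1, 1]), unname(tt^2),
                 tolerance = 1e-10)
  }
  # identical groups: F ~ 0
  mapsEq <- lapply(1:8, function(i) mkMap(vals[, (i - 1) %% 4 + 1]))
  expect_lt(max(statValues(groupFContrast(mapsEq, groups))), 1e-20)
  expect_error(groupFContrast(maps[1:3], c("A", "A", "B")), ">= 2")
})

test_that("voxelwise null p < 0.005 exceedance is nominal under the noise model", {
  # null cohorts: no planted effects, AR(1) + drift noise
  total <- 0; exceed <- 0
  for (r in 1:37) {
    cfg <- smallConfig(seed = 5000 + r, nVolumes = 185L, eegMode = "power",
                       coupling = noCoupling, alffRois = noAlffRois,
                       boldNoise = list(rho = 0.3, sd = 1, driftAmp = 1,
                                        alffBase = 0))
    run <- simulateBold(cfg, NULL, 1, "A")
    pw <- oscoupler:::.truthPower(cfg, 1)[, "alpha1"]
    fit <- fitFirstLevel(run, buildDesign(pw, run))
    tm <- contrastT(fit)
    tv <- statValues(tm)[analysisMask(tm) > 0]
    p <- 2 * pt(-abs(tv), fit$df)
    total <- total + length(tv)
    exceed <- exceed + sum(p < 0.005)
  }
  expect_gte(total, 1e5)
  halfWidth <- 3 * sqrt(0.005 * 0.995 / total)
  expect_lt(abs(exceed / total - 0.005), halfWidth)
})

test_that("Gaussian smoothing has the requested FWHM and preserves constants", {
  img <- array(0, c(21, 21, 21))
  expect_identical(smoothVolume(img + 2, 0, voxelMm = 3), img + 2)
  const <- smoothVolume(img + 2, 8, voxelMm = 3,
                        mask = array(1, dim(img)))
  expect_equal(const, img + 2, tolerance = 1e-8)
  delta <- img; delta[11, 11, 11] <- 1
  sm <- smoothVolume(delta, 8, voxelMm = 3)
  prof <- sm[, 11, 11] / max(sm)
  # half-maximum crossings by linear interpolation
  lo <- approx(prof[1:11], 1:11, xout = 0.5)$y
  hi <- approx(prof[21:11], 21:11, xout = 0.5)$y
  expect_lt(abs((hi - lo) - 8 / 3), 0.5)
})
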