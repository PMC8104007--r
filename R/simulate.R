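# Synthetic two-group EEG-fMRI cohort generator with known ground truth.

.montage60 <- c(
  "Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")

.defaultBands <- function() {
  data.frame(
    name    = c("delta", "theta", "alpha1", "alpha2", "beta"),
    lo      = c(1, 4, 8, 10.5, 14),
    hi      = c(3, 7.5, 10, 13, 30),
    freq    = c(2, 6, 9, 11.5, 20),
    meanAmp = c(4, 3, 8, 5, 2),
    arCoef  = c(0.7, 0.7, 0.8, 0.8, 0.6),
    innovSd = c(0.25, 0.25, 0.30, 0.30, 0.20),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Constructs a \linkS4class{SimConfig} with study-condition defaults: TR 2.1 s,
#' 185 volumes, 60-channel 10-10 montage at 5 kHz, log-normal AR(1) band
#' envelopes, TR-periodic gradient and cardiac-locked BCG artifacts, AR(1)
#' BOLD noise with drift on a 20 x 20 x 18 grid of 3 mm voxels, a planted
#' group-specific alpha coupling in a central "thalamus" ROI and a planted
#' low-frequency-amplitude difference in a posterior "pcc" ROI.
#'
#' @param seed integer master seed; every output is a pure function of the
#'   configuration including this seed.
#' @param nPerGroup subjects per group.
#' @param tr repetition time, s.
#' @param nVolumes number of volumes (volume-locked EEG epochs).
#' @param eegRate raw EEG sampling rate, Hz.
#' @param channels channel label vector.
#' @param bands band/oscillator table, see \linkS4class{SimConfig}.
#' @param coupling coupling table (roi, band, group, beta in BOLD percent
#'   signal per unit z-scored band power).
#' @param artifact gradient/BCG artifact parameters.
#' @param boldNoise AR(1) rho, SD (percent of baseline), drift amplitude, and
#'   the baseline low-frequency (0.01-0.08 Hz) amplitude \code{alffBase}.
#' @param alffRois planted low-frequency amplitude multipliers.
#' @param grid volume grid specification (dim, voxelMm, maskType).
#' @param backgroundSd EEG 1/f background RMS, microvolt.
#' @param eegMode "full" raw-EEG synthesis or "power" band-power-only.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed = 1L, nPerGroup = 10L, tr = 2.1, nVolumes = 185L,
                      eegRate = 5000, channels = .montage60,
                      bands = .defaultBands(),
                      coupling = data.frame(roi = "thalamus", band = "alpha1",
                                            group = c("A", "B"),
                                            beta = c(0.8, 0),
                                            stringsAsFactors = FALSE),
                      artifact = list(gradientAmp = 160, gradientJitterSd = 0,
                                      bcgAmp = 40, rrMean = 0.9, rrSd = 0.04,
                                      bcgDelay = 0.21),
                      boldNoise = list(rho = 0.3, sd = 1.0, driftAmp = 1.0,
                                       alffBase = 0.5),
                      alffRois = data.frame(roi = "pcc", group = "A",
                                            multiplier = 1.5,
                                            stringsAsFactors = FALSE),
                      grid = list(dim = c(20L, 20L, 18L), voxelMm = 3,
                                  maskType = "ellipsoid"),
                      backgroundSd = 2, eegMode = "full") {
  new("SimConfig", seed = as.integer(seed), nPerGroup = as.integer(nPerGroup),
      tr = tr, nVolumes = as.integer(nVolumes), eegRate = eegRate,
      channels = channels, bands = bands, coupling = coupling,
      artifact = artifact, boldNoise = boldNoise, alffRois = alffRois,
      grid = grid, backgroundSd = backgroundSd, eegMode = eegMode)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override the defaults of \code{\link{simConfig}}; table
#' fields (\code{bands}, \code{coupling}, \code{alffRois}) are given as lists
#' of records.
#'
#' @param path YAML file path.
#' @return A \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("seed", "nPerGroup", "tr", "nVolumes", "eegRate", "channels",
              "backgroundSd", "eegMode"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  for (f in c("bands", "coupling", "alffRois"))
    if (!is.null(y[[f]]))
      args[[f]] <- do.call(rbind, lapply(y[[f]], as.data.frame))
  for (f in c("artifact", "boldNoise", "grid")) {
    if (!is.null(y[[f]])) {
      defaults <- formals(simConfig)[[f]]
      merged <- eval(defaults)
      merged[names(y[[f]])] <- y[[f]]
      args[[f]] <- merged
    }
  }
  do.call(simConfig, args)
}

# Run expr under a derived seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.subjectSeed <- function(config, subject, stage) {
  (abs(config@seed) %% 100000L) * 20011L + as.integer(subject) * 1009L +
    as.integer(stage)
}

# Log-normal AR(1) envelope amplitudes, one column per band, one row per epoch.
.simEnvelopes <- function(config, subject) {
  nb <- nrow(config@bands)
  withSeed(.subjectSeed(config, subject, 1L), {
    A <- matrix(0, config@nVolumes, nb)
    for (b in seq_len(nb)) {
      a <- config@bands$arCoef[b]
      s <- config@bands$innovSd[b]
      x <- numeric(config@nVolumes)
      x[1] <- stats::rnorm(1, 0, if (abs(a) < 1) s / sqrt(1 - a^2) else s)
      if (config@nVolumes > 1)
        for (t in 2:config@nVolumes)
          x[t] <- a * x[t - 1] + stats::rnorm(1, 0, s)
      A[, b] <- config@bands$meanAmp[b] * exp(x - stats::var(x) / 2)
    }
    colnames(A) <- config@bands$name
    A
  })
}

# Realized per-epoch band power (squared envelope amplitude); this is the
# series the BOLD generator couples to.
.truthPower <- function(config, subject) .simEnvelopes(config, subject)^2

.gradientWaveform <- function(config) {
  rate <- config@eegRate
  n <- floor(config@tr * rate)
  tau <- (seq_len(n) - 1) / rate
  fslice <- 30 / config@tr                 # 30 axial slices per TR
  w <- numeric(n)
  coefs <- c(0.6, 0.3, 0.1)
  for (h in 1:3) {
    f <- h * fslice
    if (f < 0.45 * rate) w <- w + coefs[h] * sin(2 * pi * f * tau)
  }
  config@artifact$gradientAmp * w / max(stats::sd(w), 1e-12)
}

.bcgTemplate <- function(rate, amp) {
  tau <- seq(0, 0.5, by = 1 / rate)
  amp * exp(-((tau - 0.25) / 0.1)^2) * sin(2 * pi * 6 * tau)
}

.ecgTemplate <- function(rate) {
  # stylized PQRST: sharp R spike plus low, broad T wave
  tau <- seq(0, 0.5, by = 1 / rate)
  800 * exp(-((tau - 0.05) / 0.008)^2) + 120 * exp(-((tau - 0.3) / 0.06)^2) -
    120 * exp(-((tau - 0.035) / 0.012)^2) - 100 * exp(-((tau - 0.065) / 0.012)^2)
}

# Deterministic scalp topography: band weight per channel.
.channelWeights <- function(channels, bands) {
  w <- matrix(1, length(channels), nrow(bands),
              dimnames = list(channels, bands$name))
  posterior <- grepl("^(O|PO|P)[0-9z]", channels)
  frontal <- grepl("^(F|AF|Fp)", channels)
  alpha <- grepl("^alpha", bands$name)
  w[posterior, alpha] <- 1.4
  w[frontal, alpha] <- 0.6
  w[frontal, bands$name == "delta"] <- 1.3
  w
}

#' Simulate one subject's in-scanner EEG recording
#'
#' Sums band-limited oscillators (one carrier per band, log-normal AR(1)
#' envelope held constant within each TR epoch, deterministic scalp
#' topography) with 1/f background noise, then adds, when enabled, a fixed
#' gradient waveform at every volume trigger and a BCG template convolved on
#' simulated R-peak times.  A stylized ECG trace and the volume triggers are
#' included; true R-peak indices are stored in \code{meta$rPeaks}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param subject integer subject index (1 .. 2 * nPerGroup); determines the
#'   subject-level seed.
#' @param durationS recording length in seconds; defaults to
#'   nVolumes * tr + 1 and must cover all volumes.
#' @param artifacts logical, add gradient + BCG artifacts (default TRUE).
#' @return An \linkS4class{EEGRecording}.
#' @export
simulateEEG <- function(config, subject = 1L, durationS = NULL,
                        artifacts = TRUE) {
  validObject(config)
  rate <- config@eegRate
  need <- config@nVolumes * config@tr
  if (is.null(durationS)) durationS <- need + 1
  if (durationS < need)
    stop("recording duration (", durationS, " s) shorter than nVolumes * tr (",
         need, " s)")
  n <- round(durationS * rate)
  nch <- length(config@channels)
  triggers <- as.integer(round((seq_len(config@nVolumes) - 1) * config@tr *
                                 rate)) + 1L
  A <- .simEnvelopes(config, subject)
  w <- .channelWeights(config@channels, config@bands)
  epochLen <- floor(config@tr * rate)
  # epoch index of every sample (0 = before first/after last epoch tail)
  epoch <- pmin(floor((seq_len(n) - 1) / (config@tr * rate)) + 1,
                config@nVolumes)

  withSeed(.subjectSeed(config, subject, 2L), {
    tvec <- (seq_len(n) - 1) / rate
    phases <- stats::runif(nrow(config@bands), 0, 2 * pi)
    carriers <- sapply(seq_len(nrow(config@bands)), function(b)
      sin(2 * pi * config@bands$freq[b] * tvec + phases[b]))
    modulated <- carriers * A[epoch, , drop = FALSE]   # n x bands
    data <- tcrossprod(w, modulated)                   # channels x samples
    if (config@backgroundSd > 0)
      for (c in seq_len(nch))
        data[c, ] <- data[c, ] + .pinkNoise(n, config@backgroundSd)

    rPeaks <- integer(0)
    ecg <- numeric(n)
    if (artifacts) {
      grad <- .gradientWaveform(config)
      jit <- config@artifact$gradientJitterSd * rate
      gains <- 1 + 0.005 * (seq_len(nch) - 1)
      for (i in seq_along(triggers)) {
        start <- triggers[i] +
          if (jit > 0) as.integer(round(stats::rnorm(1, 0, jit))) else 0L
        idx <- start:min(start + length(grad) - 1L, n)
        idx <- idx[idx >= 1]
        data[, idx] <- data[, idx] +
          outer(gains, grad[seq_along(idx) + (idx[1] - start)])
      }
      # cardiac cycle: R-peak times with jittered RR intervals
      rr <- numeric(0); t0 <- 0.3
      while (t0 < durationS) {
        rr <- c(rr, t0)
        t0 <- t0 + pmin(pmax(stats::rnorm(1, config@artifact$rrMean,
                                          config@artifact$rrSd), 0.4), 2.5)
      }
      rPeaks <- as.integer(round(rr * rate)) + 1L
      rPeaks <- rPeaks[rPeaks <= n]
      ecgT <- .ecgTemplate(rate)
      bcgT <- .bcgTemplate(rate, config@artifact$bcgAmp)
      delay <- as.integer(round(config@artifact$bcgDelay * rate))
      bgains <- 1 + 0.01 * (seq_len(nch) - 1)
      for (p in rPeaks) {
        # ECG template centered so its R spike lands exactly on the peak index
        es <- p - as.integer(round(0.05 * rate))
        eidx <- es:min(es + length(ecgT) - 1L, n)
        keep <- eidx >= 1
        ecg[eidx[keep]] <- ecg[eidx[keep]] + ecgT[which(keep)]
        bs <- p + delay
        bidx <- bs:min(bs + length(bcgT) - 1L, n)
        keep <- bidx >= 1 & bidx <= n
        if (any(keep))
          data[, bidx[keep]] <- data[, bidx[keep]] +
            outer(bgains, bcgT[which(keep)])
      }
      ecg <- ecg + stats::rnorm(n, 0, 2)
    }
    new("EEGRecording", data = data, rate = rate, labels = config@channels,
        triggers = triggers, ecg = ecg,
        history = list(list(op = "simulateEEG", subject = subject,
                            seed = .subjectSeed(config, subject, 2L),
                            artifacts = artifacts)),
        meta = list(rPeaks = rPeaks, subject = subject, tr = config@tr))
  })
}

# 1/f-amplitude background noise normalized to the requested RMS.
.pinkNoise <- function(n, sd) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                  # symmetric bin distance from DC
  X <- X / sqrt(pmax(f, 2))
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  sd * y / stats::sd(y)
}

# Named spherical ROIs on the simulation grid (fractional grid offsets).
.roiCenters <- list(thalamus = c(0, 0, 0), pcc = c(0, -0.30, 0.10),
                    occipital = c(0, -0.38, -0.05), frontal = c(0, 0.32, 0.05))

.simGrid <- function(config) {
  d <- as.integer(config@grid$dim)
  vox <- config@grid$voxelMm
  affine <- diag(c(vox, vox, vox, 1))
  affine[1:3, 4] <- -vox * (d + 1) / 2     # grid centered on world origin
  centers <- lapply(1:3, function(i) (seq_len(d[i]) - (d[i] + 1) / 2) * vox)
  g <- expand.grid(x = centers[[1]], y = centers[[2]], z = centers[[3]])
  radii <- 0.45 * d * vox
  mask <- array((g$x / radii[1])^2 + (g$y / radii[2])^2 +
                  (g$z / radii[3])^2 <= 1, dim = d)
  list(dim = d, vox = vox, affine = affine, mask = mask, world = g)
}

#' Voxel indices of a named simulation ROI
#'
#' @param config a \linkS4class{SimConfig}.
#' @param roi ROI name ("thalamus", "pcc", "occipital", "frontal").
#' @param radiusMm sphere radius in mm.
#' @return Integer vector of linear voxel indices into the simulation grid.
#' @export
roiVoxels <- function(config, roi, radiusMm = 6) {
  grid <- .simGrid(config)
  if (!roi %in% names(.roiCenters)) stop("unknown ROI: ", roi)
  ctr <- .roiCenters[[roi]] * grid$dim * grid$vox
  d2 <- (grid$world$x - ctr[1])^2 + (grid$world$y - ctr[2])^2 +
    (grid$world$z - ctr[3])^2
  idx <- which(d2 <= radiusMm^2)
  if (!all(grid$mask[idx]))
    stop("ROI '", roi, "' extends outside the simulation mask")
  idx
}

#' Simulate one subject's BOLD run
#'
#' ROI voxels named in the coupling table (for the subject's group) carry
#' baseline + beta x (canonical HRF convolved with the z-scored ground-truth
#' band power); every mask voxel additionally carries linear + slow-cosine
#' drift, AR(1) noise, and a low-frequency (0.01-0.08 Hz) sinusoidal
#' component whose amplitude is multiplied inside planted ALFF ROIs.
#' Motion parameters (smooth random walks) and white-matter/CSF signals
#' (low-pass noise) are generated alongside.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth a \linkS4class{GroundTruth} from \code{\link{simulateCohort}},
#'   or NULL to derive the subject's ground truth from the configuration.
#' @param subject integer subject index.
#' @param group group label of the subject ("A" or "B"); defaults to the
#'   cohort layout (first nPerGroup subjects are "A").
#' @return A \linkS4class{BoldRun}.
#' @export
simulateBold <- function(config, truth = NULL, subject = 1L, group = NULL) {
  validObject(config)
  if (is.null(group)) group <- if (subject <= config@nPerGroup) "A" else "B"
  pw <- if (!is.null(truth)) truth@power[[subject]] else .truthPower(config, subject)
  T <- config@nVolumes
  stopifnot(nrow(pw) == T)
  grid <- .simGrid(config)
  nvox <- prod(grid$dim)
  midx <- which(grid$mask)
  baseline <- 100
  rho <- config@boldNoise$rho
  nsd <- config@boldNoise$sd
  tt <- (seq_len(T) - 1) * config@tr

  withSeed(.subjectSeed(config, subject, 3L), {
    Y <- matrix(0, length(midx), T)
    Y[] <- baseline
    # AR(1) noise with stationary marginal SD = nsd
    if (nsd > 0) {
      innov <- matrix(stats::rnorm(length(midx) * T, 0,
                                   nsd * sqrt(1 - rho^2)), T, length(midx))
      noise <- if (rho != 0)
        stats::filter(innov, rho, method = "recursive") else innov
      Y <- Y + t(noise)
    }
    if (config@boldNoise$driftAmp > 0) {
      lin <- seq(-1, 1, length.out = T)
      slow <- cos(pi * (seq_len(T) - 0.5) / T)
      Y <- Y + outer(stats::runif(length(midx), -1, 1) *
                       config@boldNoise$driftAmp, lin) +
        outer(stats::runif(length(midx), -1, 1) *
                config@boldNoise$driftAmp, slow)
    }
    # low-frequency component: baseline amplitude everywhere, multiplied in
    # planted ALFF ROIs for the subject's group
    alffBase <- config@boldNoise$alffBase %||% 0.5
    mult <- rep(1, length(midx))
    roiOf <- rep(NA_character_, length(midx))
    ar <- config@alffRois
    if (nrow(ar) && alffBase > 0) {
      for (roi in unique(ar$roi))
        roiOf[match(roiVoxels(config, roi), midx)] <- roi
      for (r in seq_len(nrow(ar)))
        if (ar$group[r] == group) {
          rv <- roiVoxels(config, ar$roi[r])
          mult[match(rv, midx)] <- ar$multiplier[r]
        }
    }
    if (alffBase > 0)
      for (f in c(0.02, 0.045, 0.07)) {
        # background voxels fluctuate with independent phases; voxels of a
        # named ROI share one phase (regional fluctuations are coherent, so
        # the planted amplitude survives spatial smoothing)
        ph <- stats::runif(length(midx), 0, 2 * pi)
        for (roi in unique(roiOf[!is.na(roiOf)]))
          ph[which(roiOf == roi)] <- stats::runif(1, 0, 2 * pi)
        Y <- Y + (mult * alffBase / sqrt(3)) *
          cos(outer(ph, 2 * pi * f * tt, "+"))
      }
    # planted coupling
    cp <- config@coupling
    if (nrow(cp))
      for (r in seq_len(nrow(cp))) {
        if (cp$group[r] != group || cp$beta[r] == 0) next
        if (!cp$band[r] %in% colnames(pw))
          stop("coupling band '", cp$band[r], "' not simulated")
        rv <- roiVoxels(config, cp$roi[r])
        if (!all(rv %in% midx)) stop("coupling ROI outside mask")
        reg <- convolveHRF(zscore(pw[, cp$band[r]]), config@tr)
        Y[match(rv, midx), ] <- sweep(Y[match(rv, midx), , drop = FALSE], 2,
                                      cp$beta[r] * reg, "+")
      }
    vol <- array(0, c(grid$dim, T))
    flat <- matrix(0, nvox, T)
    flat[midx, ] <- Y
    vol[] <- flat
    motion <- sapply(1:6, function(i)
      stats::filter(c(0, stats::rnorm(T - 1, 0, 0.02)), 1,
                    method = "recursive"))
    wm <- as.numeric(stats::filter(stats::rnorm(T, 0, 0.3), 0.9,
                                   method = "recursive"))
    csf <- as.numeric(stats::filter(stats::rnorm(T, 0, 0.3), 0.9,
                                    method = "recursive"))
    new("BoldRun", data = vol, voxelMm = grid$vox, tr = config@tr,
        affine = grid$affine, mask = grid$mask * 1, motion = as.matrix(motion),
        wm = wm, csf = csf)
  })
}

#' Simulate a labeled two-group cohort
#'
#' Generates 2 x nPerGroup subjects (group "A" then group "B"), each with the
#' realized band-power ground truth, an optional raw EEG recording (skipped in
#' eegMode "power"), and a BOLD run with the configured planted effects.
#'
#' @param config a \linkS4class{SimConfig}; \code{nPerGroup >= 2}.
#' @param dir optional directory; when given, EEG (TSV + JSON sidecar), BOLD
#'   (NIfTI), mask (NIfTI), confounds (TSV) and the group table (TSV) are
#'   written there.
#' @return A list with \code{subjects} (each: id, group, eeg, bold),
#'   \code{design} (data.frame subject_id, group), and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateCohort <- function(config, dir = NULL) {
  validObject(config)
  if (config@nPerGroup < 2)
    stop("nPerGroup must be >= 2: group statistics are undefined otherwise")
  nsub <- 2L * config@nPerGroup
  groups <- rep(c("A", "B"), each = config@nPerGroup)
  ids <- sprintf("%s%02d", groups, c(seq_len(config@nPerGroup),
                                     seq_len(config@nPerGroup)))
  power <- lapply(seq_len(nsub), function(s) .truthPower(config, s))
  names(power) <- ids
  rois <- unique(c(config@coupling$roi, config@alffRois$roi))
  roiIdx <- lapply(rois, function(r) roiVoxels(config, r))
  names(roiIdx) <- rois
  truth <- new("GroundTruth", power = power, coupling = config@coupling,
               rois = roiIdx, alffRois = config@alffRois)
  subjects <- lapply(seq_len(nsub), function(s) {
    eeg <- if (config@eegMode == "full") simulateEEG(config, s) else NULL
    bold <- simulateBold(config, truth, s, groups[s])
    list(id = ids[s], group = groups[s], eeg = eeg, bold = bold)
  })
  design <- data.frame(subject_id = ids, group = groups,
                       stringsAsFactors = FALSE)
  out <- list(subjects = subjects, design = design, truth = truth)
  if (!is.null(dir)) writeCohort(out, dir)
  out
}

#' Write a simulated cohort to disk
#'
#' EEG as TSV (samples x channels) with a JSON sidecar (rate, labels, trigger
#' indices, ECG), BOLD as 4D NIfTI-1 with confounds TSV, mask as 3D NIfTI-1,
#' group table as TSV.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$design, file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  first <- TRUE
  for (s in cohort$subjects) {
    if (!is.null(s$eeg))
      writeEEG(s$eeg, file.path(dir, paste0(s$id, "_eeg")))
    if (!is.null(s$bold)) {
      writeBoldRun(s$bold, file.path(dir, paste0(s$id, "_bold.nii")))
      if (first) {
        maskNii <- RNifti::asNifti(s$bold@mask * 1)
        RNifti::writeNifti(maskNii, file.path(dir, "mask.nii"))
        first <- FALSE
      }
    }
  }
  invisible(dir)
}

#' Write / read the EEG two-file interchange format
#'
#' A tab-separated samples x channels matrix (\code{<stem>.tsv}) plus a JSON
#' sidecar (\code{<stem>.json}) holding rate, labels, trigger sample indices,
#' and the ECG trace.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param stem output path without extension.
#' @return \code{writeEEG}: the stem, invisibly; \code{readEEG}: an
#'   \linkS4class{EEGRecording}.
#' @export
writeEEG <- function(rec, stem) {
  m <- t(rec@data)
  colnames(m) <- rec@labels
  utils::write.table(m, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- list(rate = rec@rate, labels = rec@labels,
               triggers = rec@triggers, ecg = rec@ecg,
               history = rec@history)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeEEG
#' @param stemOrTsv stem (or .tsv path) written by \code{writeEEG}.
#' @export
readEEG <- function(stemOrTsv) {
  stem <- sub("\\.tsv$", "", stemOrTsv)
  m <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t",
                                   header = TRUE, check.names = FALSE))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  new("EEGRecording", data = t(m), rate = side$rate, labels = side$labels,
      triggers = as.integer(side$triggers),
      ecg = as.numeric(side$ecg %||% numeric(0)),
      history = as.list(side$history %||% list()))
}

#' Write / read a BOLD run as NIfTI plus confounds TSV
#'
#' @param run a \linkS4class{BoldRun}.
#' @param path output NIfTI path (".nii"); confounds are written beside it as
#'   \code{<path minus extension>_confounds.tsv} with columns mot1..mot6, wm,
#'   csf.
#' @return \code{writeBoldRun}: the path, invisibly; \code{readBoldRun}: a
#'   \linkS4class{BoldRun}.
#' @export
writeBoldRun <- function(run, path) {
  nii <- RNifti::asNifti(run@data)
  nii <- RNifti::`pixdim<-`(nii, c(rep(run@voxelMm, 3), run@tr))
  RNifti::writeNifti(nii, path)
  conf <- cbind(run@motion, wm = run@wm, csf = run@csf)
  colnames(conf) <- c(paste0("mot", 1:6), "wm", "csf")
  utils::write.table(conf, paste0(sub("\\.nii(\\.gz)?$", "", path),
                                  "_confounds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBoldRun
#' @param maskPath NIfTI mask path; when NULL, all voxels are in-mask.
#' @param tr repetition time, s (read from the NIfTI pixdim when present).
#' @export
readBoldRun <- function(path, maskPath = NULL, tr = NULL) {
  nii <- RNifti::readNifti(path)
  dat <- array(as.numeric(nii), dim = dim(nii))
  pd <- attr(nii, "pixdim") %||% RNifti::pixdim(nii)
  vox <- pd[1]
  if (is.null(tr)) tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2.1
  mask <- if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    array(as.numeric(m) > 0, dim = dim(m)) * 1
  } else array(1, dim = dim(dat)[1:3])
  confPath <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_confounds.tsv")
  if (file.exists(confPath)) {
    conf <- utils::read.table(confPath, sep = "\t", header = TRUE)
    motion <- as.matrix(conf[, paste0("mot", 1:6)])
    wm <- conf$wm; csf <- conf$csf
  } else {
    motion <- matrix(0, dim(dat)[4], 6); wm <- csf <- numeric(dim(dat)[4])
  }
  affine <- structure(RNifti::xform(nii), class = "matrix")
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine)) < 1e-12) affine <- diag(c(rep(vox, 3), 1))
  new("BoldRun", data = dat, voxelMm = vox, tr = tr, affine = affine,
      mask = mask, motion = motion, wm = wm, csf = csf)
}
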