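# Shared small-scale simulation fixtures, built in code.

smallChannels <- c("Fz", "Cz", "Pz", "POz", "Oz", "O1")

# Compact config: 6 channels at 500 Hz, 60 volumes -- fast but structurally
# identical to the full study conditions.
smallConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, nPerGroup = 2, eegRate = 500,
               channels = smallChannels, nVolumes = 60L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}

noCoupling <- data.frame(roi = character(0), band = character(0),
                         group = character(0), beta = numeric(0),
                         stringsAsFactors = FALSE)

noAlffRois <- data.frame(roi = character(0), group = character(0),
                         multiplier = numeric(0), stringsAsFactors = FALSE)

# Band table with a single constant-envelope alpha oscillator.
oneAlphaBand <- function(freq = 9, meanAmp = 8, arCoef = 0, innovSd = 0) {
  data.frame(name = "alpha1", lo = 8, hi = 10, freq = freq,
             meanAmp = meanAmp, arCoef = arCoef, innovSd = innovSd,
             stringsAsFactors = FALSE)
}

# Pure-noise BOLD: no drift, no low-frequency component, no planted effects.
quietNoise <- function(rho = 0.3, sd = 1)
  list(rho = rho, sd = sd, driftAmp = 0, alffBase = 0)

# Minimal BoldRun wrapping a voxels x T matrix on a Vx1x1 grid.
matrixBoldRun <- function(Y, tr = 2.1, motion = NULL) {
  V <- nrow(Y); T <- ncol(Y)
  if (is.null(motion)) {
    set.seed(42)
    motion <- matrix(rnorm(T * 6, 0, 0.05), T, 6)
  }
  new("BoldRun", data = array(Y, c(V, 1, 1, T)), voxelMm = 3, tr = tr,
      affine = diag(c(3, 3, 3, 1)), mask = array(1, c(V, 1, 1)),
      motion = motion, wm = rnorm(T, 0, 0.1), csf = rnorm(T, 0, 0.1))
}

# TR-locked (event-locked) average power of a recording: power of the mean
# epoch waveform, averaged over channels.
lockedAveragePower <- function(data, onsets, len) {
  mean(vapply(seq_len(nrow(data)), function(ch) {
    idx <- outer(0:(len - 1L), onsets, "+")
    keep <- colSums(idx > ncol(data)) == 0
    E <- matrix(data[ch, idx[, keep]], len)
    mean(rowMeans(E)^2)
  }, numeric(1)))
}
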