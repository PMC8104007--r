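#' @import methods
NULL

#' Multichannel in-scanner EEG recording
#'
#' Container for a channels-by-samples EEG matrix together with the metadata
#' every cleaning and spectral operation needs: sampling rate, channel labels
#' (10-10 convention), fMRI volume-onset trigger sample indices, and the ECG
#' trace recorded alongside the scalp channels.  All artifact-correction
#' operations act on and return objects of this class, appending a record of
#' themselves to \code{history}.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot rate sampling rate in Hz.
#' @slot labels character vector of unique channel names, one per row.
#' @slot triggers integer vector of volume-onset sample indices (1-based,
#'   strictly increasing).
#' @slot ecg numeric vector, the ECG trace at the same rate (may be length 0
#'   when no ECG was recorded).
#' @slot history list of applied processing stages, each a list with at least
#'   \code{op} and its parameters; a reproducibility audit trail.
#' @slot meta free-form list (e.g. simulation ground truth such as true
#'   R-peak indices, written by the cohort generator).
#' @export
setClass("EEGRecording",
  representation(data = "matrix", rate = "numeric", labels = "character",
                 triggers = "integer", ecg = "numeric", history = "list",
                 meta = "list"),
  prototype(ecg = numeric(0), history = list(), meta = list()))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (nrow(object@data) != length(object@labels))
    msg <- c(msg, "number of labels must equal number of data rows")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@triggers) > 1 && any(diff(object@triggers) <= 0))
    msg <- c(msg, "triggers must be strictly increasing")
  if (length(object@triggers) &&
      (min(object@triggers) < 1 || max(object@triggers) > ncol(object@data)))
    msg <- c(msg, "triggers must lie within the recording")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@rate) != 1 || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic EEG-fMRI cohorts
#'
#' Defines the study conditions of a synthetic two-group cohort: acquisition
#' geometry (TR, number of volumes, EEG rate, channel montage), the per-band
#' oscillator/envelope processes, the coupling table mapping (ROI, band,
#' group) to a BOLD effect size, artifact parameters, BOLD noise, and the
#' planted low-frequency-amplitude ROIs.  The seed fully determines every
#' output derived from the configuration.
#'
#' @slot seed integer master seed.
#' @slot nPerGroup subjects per group (>= 2 for any group statistic).
#' @slot tr repetition time in seconds.
#' @slot nVolumes number of fMRI volumes (epochs).
#' @slot eegRate raw EEG sampling rate, Hz.
#' @slot channels character vector of channel labels (10-10 set).
#' @slot bands data.frame: name, lo, hi (Hz band edges), freq (oscillator
#'   carrier, Hz), meanAmp (mean envelope amplitude, microvolt),
#'   arCoef (AR(1) coefficient of the log-envelope), innovSd (innovation SD
#'   of the log-envelope).
#' @slot coupling data.frame: roi, band, group, beta — BOLD percent signal
#'   change per unit z-scored band power.
#' @slot artifact list: gradientAmp (microvolt), gradientJitterSd (s),
#'   bcgAmp (microvolt), rrMean (s), rrSd (s), bcgDelay (s).
#' @slot boldNoise list: rho (AR(1)), sd (percent of baseline), driftAmp.
#' @slot alffRois data.frame: roi, group, multiplier — low-frequency
#'   amplitude multipliers relative to the mask-wide baseline.
#' @slot grid list: dim (length-3 integer), voxelMm, maskType.
#' @slot backgroundSd 1/f background noise RMS, microvolt.
#' @slot eegMode "full" (synthesize raw EEG) or "power" (band-power series
#'   only, for pipeline stages downstream of the spectral module).
#' @export
setClass("SimConfig",
  representation(seed = "integer", nPerGroup = "integer", tr = "numeric",
                 nVolumes = "integer", eegRate = "numeric",
                 channels = "character", bands = "data.frame",
                 coupling = "data.frame", artifact = "list",
                 boldNoise = "list", alffRois = "data.frame", grid = "list",
                 backgroundSd = "numeric", eegMode = "character"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nVolumes < 1) msg <- c(msg, "nVolumes must be positive")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (!all(is.finite(object@coupling$beta %||% numeric(0))))
    msg <- c(msg, "all coupling betas must be finite")
  if (!object@eegMode %in% c("full", "power"))
    msg <- c(msg, "eegMode must be 'full' or 'power'")
  if (!all(c("name", "lo", "hi", "freq", "meanAmp", "arCoef", "innovSd")
           %in% names(object@bands)))
    msg <- c(msg, "bands must have columns name, lo, hi, freq, meanAmp, arCoef, innovSd")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot power list, one epochs-by-bands matrix of realized band power per
#'   subject (named by subject id).
#' @slot coupling data.frame mirroring the configuration coupling table.
#' @slot rois named list of voxel index vectors (linear indices into the
#'   simulation grid) for every ROI referenced by coupling or alffRois.
#' @slot alffRois data.frame of planted low-frequency amplitude multipliers.
#' @export
setClass("GroundTruth",
  representation(power = "list", coupling = "data.frame", rois = "list",
                 alffRois = "data.frame"))

#' A 4D BOLD run with mask and confounds
#'
#' @slot data 4D numeric array X x Y x Z x T.
#' @slot voxelMm voxel size in mm (isotropic).
#' @slot tr repetition time, seconds.
#' @slot affine 4x4 voxel-index (1-based) to world (MNI mm) matrix.
#' @slot mask logical/0-1 array X x Y x Z, the analysis (gray-matter) mask.
#' @slot motion T x 6 matrix of head-motion parameters.
#' @slot wm,csf length-T white-matter and CSF mean signals.
#' @export
setClass("BoldRun",
  representation(data = "array", voxelMm = "numeric", tr = "numeric",
                 affine = "matrix", mask = "array", motion = "matrix",
                 wm = "numeric", csf = "numeric"))

setValidity("BoldRun", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 4) msg <- c(msg, "data must be 4D")
  if (!identical(dim(object@mask), d[1:3]))
    msg <- c(msg, "mask dimensions must match the volume grid")
  if (sum(object@mask) == 0) msg <- c(msg, "mask must be nonempty")
  if (nrow(object@motion) && nrow(object@motion) != d[4])
    msg <- c(msg, "motion must have one row per volume")
  if (abs(det(object@affine)) < 1e-12) msg <- c(msg, "affine must be invertible")
  if (length(msg)) msg else TRUE
})

#' Per-volume, per-channel amplitude spectra
#'
#' @slot amplitude epochs x channels x bins array of absolute spectral
#'   amplitude (microvolt); the single-sided discrete-Fourier amplitude so a
#'   unit sinusoid maps to (approximately, up to taper loss) amplitude 1.
#' @slot freqs bin center frequencies, Hz (spacing 0.5 Hz at defaults).
#' @slot labels channel labels.
#' @slot epochLength seconds of data entering each transform.
#' @export
setClass("VolumeEpochSpectra",
  representation(amplitude = "array", freqs = "numeric", labels = "character",
                 epochLength = "numeric"))

setValidity("VolumeEpochSpectra", function(object) {
  msg <- character(0)
  if (length(dim(object@amplitude)) != 3)
    msg <- c(msg, "amplitude must be epochs x channels x bins")
  if (dim(object@amplitude)[3] != length(object@freqs))
    msg <- c(msg, "freqs must match bin count")
  if (any(object@amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One scalar EEG band-power value per fMRI volume
#'
#' The EEG-side regressor: either the global spectral power (root mean square
#' of band power across all scalp channels) or a regional mean over named
#' electrodes (default the midline parieto-occipital Oz, POz, Pz for alpha).
#'
#' @slot values numeric, one value per volume epoch.
#' @slot band list(name, lo, hi).
#' @slot kind "GSP" or "regional".
#' @slot electrodes channels entering a regional series (empty for GSP).
#' @export
setClass("BandPowerSeries",
  representation(values = "numeric", band = "list", kind = "character",
                 electrodes = "character"),
  prototype(electrodes = character(0)))

setValidity("BandPowerSeries", function(object) {
  msg <- character(0)
  if (any(object@values < 0)) msg <- c(msg, "band power must be >= 0")
  if (!object@kind %in% c("GSP", "regional")) msg <- c(msg, "kind must be GSP or regional")
  if (length(msg)) msg else TRUE
})

#' First-level design matrix for the parametric-modulation GLM
#'
#' Columns: the HRF-convolved z-scored band-power modulator (the regressor of
#' interest), six head-motion parameters, white-matter and CSF signals, a
#' discrete-cosine high-pass drift basis (periods above the cutoff), and an
#' intercept.
#'
#' @slot X T x P numeric design matrix.
#' @slot names column names.
#' @slot interest column index of the modulated regressor.
#' @slot hpCutoff high-pass cutoff, seconds.
#' @slot tr repetition time, seconds.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", names = "character", interest = "integer",
                 hpCutoff = "numeric", tr = "numeric"))

setValidity("DesignMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@X) != length(object@names)) msg <- c(msg, "names must match columns")
  nonzero <- colSums(abs(object@X)) > 1e-12   # zero interest column = flagged degenerate case
  if (qr(object@X[, nonzero, drop = FALSE])$rank < sum(nonzero))
    msg <- c(msg, "design matrix is rank deficient")
  if (length(msg)) msg else TRUE
})

#' A voxelwise statistic map
#'
#' @slot values 3D array; finite inside the mask, NA outside.
#' @slot stat one of "t", "F", "beta", "z".
#' @slot df degrees of freedom (length 1 for t/z, length 2 for F, 0 for beta).
#' @slot mask logical/0-1 3D array.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot voxelMm voxel size, mm.
#' @slot provenance list (band, regressor kind, contrast, flags such as
#'   \code{saturated} when a statistic was capped).
#' @export
setClass("StatMap",
  representation(values = "array", stat = "character", df = "numeric",
                 mask = "array", affine = "matrix", voxelMm = "numeric",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("StatMap", function(object) {
  msg <- character(0)
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask dimensions differ")
  inside <- object@values[object@mask > 0]
  if (any(!is.finite(inside))) msg <- c(msg, "values inside mask must be finite")
  if (!object@stat %in% c("t", "F", "beta", "z")) msg <- c(msg, "unknown stat type")
  if (length(msg)) msg else TRUE
})

#' Per-subject ALFF and mALFF maps
#'
#' ALFF is the mean single-sided spectral amplitude of the (motion-residualized,
#' linearly detrended) BOLD time series over 0.01-0.08 Hz; mALFF normalizes it
#' by the mask-wide mean (subtractive by default, divisive optional).
#'
#' @slot alff 3D array, >= 0 inside the mask.
#' @slot malff 3D array (may be empty before normalization).
#' @slot mask 3D mask.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot voxelMm voxel size, mm.
#' @slot config list(band, normalization, detrend).
#' @export
setClass("AlffMaps",
  representation(alff = "array", malff = "array", mask = "array",
                 affine = "matrix", voxelMm = "numeric", config = "list"))

setValidity("AlffMaps", function(object) {
  msg <- character(0)
  inside <- object@alff[object@mask > 0]
  if (any(inside < -1e-12)) msg <- c(msg, "alff must be >= 0 inside mask")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
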