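# Per-volume EEG spectra and band-power regressors (global spectral power and
# regional alpha).

#' Standard frequency-band definitions
#'
#' delta 1-3, theta 4-7.5, alpha1 8-10, alpha2 10.5-13, beta 14-30 Hz, plus
#' the combined "alpha" (8-13 Hz) used by the regional regressor.
#'
#' @param name optional single band name; when given, returns one band as a
#'   list(name, lo, hi) instead of the full table.
#' @return A data.frame (name, lo, hi) or a single-band list.
#' @export
bandDefinitions <- function(name = NULL) {
  tab <- data.frame(
    name = c("delta", "theta", "alpha1", "alpha2", "beta", "alpha"),
    lo = c(1, 4, 8, 10.5, 14, 8),
    hi = c(3, 7.5, 10, 13, 30, 13),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(tab[tab$name != "alpha", ])
  row <- tab[tab$name == name, ]
  if (!nrow(row)) stop("unknown band: ", name)
  list(name = row$name, lo = row$lo, hi = row$hi)
}

#' Cut a recording into volume-locked epochs
#'
#' One epoch per volume trigger, starting at the trigger and spanning
#' \code{tr} seconds.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param tr repetition time, s.
#' @return A list of channels x samples matrices, one per volume.
#' @export
epochByVolume <- function(rec, tr) {
  if (!length(rec@triggers)) stop("no volume triggers present")
  len <- as.integer(floor(tr * rec@rate))
  lastEnd <- rec@triggers[length(rec@triggers)] + len - 1L
  if (lastEnd > ncol(rec@data))
    stop("recording truncated: last epoch needs samples up to ", lastEnd,
         " but only ", ncol(rec@data), " are available")
  lapply(rec@triggers, function(t0)
    rec@data[, t0 + 0:(len - 1L), drop = FALSE])
}

# Tukey taper: flat with a cosine ramp over `frac` of the samples
# (frac/2 per end).
.tukeyWindow <- function(n, frac = 0.1) {
  w <- rep(1, n)
  m <- floor(frac * n / 2)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
  }
  w
}

#' Absolute amplitude spectrum of one volume epoch
#'
#' Applies a Hann-type taper to the outer 10 percent of the analysis segment
#' (5 percent per end), chooses the segment length so the bin spacing equals
#' \code{resolution} (at 256 Hz and 0.5 Hz this is the first 512 samples, 2 s,
#' of the epoch; shorter epochs are zero padded), and returns single-sided
#' absolute amplitudes: a unit-amplitude in-band sinusoid maps to
#' approximately 1 (exactly 1 with no taper).
#'
#' @param epoch channels x samples matrix (or a numeric vector, one channel).
#' @param rate sampling rate, Hz.
#' @param resolution bin spacing, Hz.
#' @param taperFrac tapered fraction of the segment.
#' @return List: \code{amplitude} channels x bins matrix, \code{freqs} bin
#'   frequencies (0 .. Nyquist).
#' @export
epochSpectrum <- function(epoch, rate, resolution = 0.5, taperFrac = 0.1) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  nUse <- as.integer(round(rate / resolution))
  n <- ncol(epoch)
  seg <- if (n >= nUse) epoch[, seq_len(nUse), drop = FALSE] else
    cbind(epoch, matrix(0, nrow(epoch), nUse - n))
  w <- .tukeyWindow(min(n, nUse), taperFrac)
  if (length(w) < nUse) w <- c(w, rep(0, nUse - length(w)))
  seg <- sweep(seg, 2, w, "*")
  X <- t(apply(seg, 1, stats::fft))
  if (nrow(seg) == 1) X <- matrix(X, nrow = 1)
  half <- nUse %/% 2
  amp <- Mod(X[, seq_len(half + 1), drop = FALSE]) / nUse
  if (half >= 2) amp[, 2:half] <- 2 * amp[, 2:half]
  list(amplitude = amp, freqs = (0:half) * resolution)
}

#' Per-volume, per-channel amplitude spectra for a whole recording
#'
#' @param rec a clean \linkS4class{EEGRecording}.
#' @param tr repetition time, s.
#' @param resolution bin spacing, Hz (default 0.5).
#' @param taperFrac tapered fraction of each analysis segment.
#' @return A \linkS4class{VolumeEpochSpectra}.
#' @export
volumeSpectra <- function(rec, tr, resolution = 0.5, taperFrac = 0.1) {
  eps <- epochByVolume(rec, tr)
  first <- epochSpectrum(eps[[1]], rec@rate, resolution, taperFrac)
  amp <- array(0, c(length(eps), nrow(rec@data), length(first$freqs)))
  amp[1, , ] <- first$amplitude
  if (length(eps) > 1)
    for (i in 2:length(eps))
      amp[i, , ] <- epochSpectrum(eps[[i]], rec@rate, resolution,
                                  taperFrac)$amplitude
  nUse <- round(rec@rate / resolution)
  new("VolumeEpochSpectra", amplitude = amp, freqs = first$freqs,
      labels = rec@labels,
      epochLength = min(ncol(eps[[1]]), nUse) / rec@rate)
}

#' Mean absolute spectral band value per epoch and channel
#'
#' @param spectra a \linkS4class{VolumeEpochSpectra}.
#' @param band a band from \code{\link{bandDefinitions}} (or list(name, lo,
#'   hi)).
#' @param units "amplitude" (default) averages absolute amplitudes; "power"
#'   averages squared amplitudes.
#' @return epochs x channels matrix with channel labels as column names.
#' @export
bandPower <- function(spectra, band, units = c("amplitude", "power")) {
  units <- match.arg(units)
  sel <- which(spectra@freqs >= band$lo & spectra@freqs <= band$hi)
  if (!length(sel))
    stop("band ", band$name, " (", band$lo, "-", band$hi,
         " Hz) contains no spectral bins")
  a <- spectra@amplitude[, , sel, drop = FALSE]
  if (units == "power") a <- a^2
  out <- apply(a, c(1, 2), mean)
  colnames(out) <- spectra@labels
  out
}

#' Global spectral power series
#'
#' Per epoch, the root mean square of band power across all scalp channels — a
#' whole-scalp measure of oscillatory activity.
#'
#' @param bp epochs x channels band-power matrix from \code{\link{bandPower}}.
#' @param band the band the matrix was computed for.
#' @return A \linkS4class{BandPowerSeries} of kind "GSP".
#' @export
gsp <- function(bp, band) {
  if (ncol(bp) < 1) stop("need at least one channel")
  new("BandPowerSeries", values = sqrt(rowMeans(bp^2)),
      band = band, kind = "GSP")
}

#' Regional alpha power series
#'
#' Arithmetic mean of band power over midline parieto-occipital electrodes
#' (default Oz, POz, Pz), per epoch.
#'
#' @param bp epochs x channels band-power matrix (columns named by channel).
#' @param band the band the matrix was computed for (conventionally alpha,
#'   8-13 Hz).
#' @param electrodes channel subset to average.
#' @return A \linkS4class{BandPowerSeries} of kind "regional".
#' @export
regionalAlpha <- function(bp, band = bandDefinitions("alpha"),
                          electrodes = c("Oz", "POz", "Pz")) {
  missing <- setdiff(electrodes, colnames(bp))
  if (length(missing))
    stop("electrode(s) not present: ", paste(missing, collapse = ", "))
  new("BandPowerSeries",
      values = rowMeans(bp[, electrodes, drop = FALSE]),
      band = band, kind = "regional", electrodes = electrodes)
}

#' Compute all band-power regressors for one clean recording
#'
#' GSP series for each of the five standard bands plus the regional alpha
#' series, as used by the first-level coupling GLMs.
#'
#' @param rec clean \linkS4class{EEGRecording} (256 Hz, average reference).
#' @param tr repetition time, s.
#' @param units "amplitude" or "power" band values.
#' @return Named list of \linkS4class{BandPowerSeries}: delta, theta, alpha1,
#'   alpha2, beta (GSP) and regional_alpha.
#' @export
bandRegressors <- function(rec, tr, units = "amplitude") {
  spectra <- volumeSpectra(rec, tr)
  bands <- bandDefinitions()
  out <- list()
  for (i in seq_len(nrow(bands))) {
    band <- list(name = bands$name[i], lo = bands$lo[i], hi = bands$hi[i])
    out[[band$name]] <- gsp(bandPower(spectra, band, units), band)
  }
  alpha <- bandDefinitions("alpha")
  out$regional_alpha <- regionalAlpha(bandPower(spectra, alpha, units), alpha)
  out
}

#' Export regressors as a TSV table (one column per series)
#'
#' @param regressors named list of \linkS4class{BandPowerSeries}.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeRegressors <- function(regressors, path) {
  tab <- as.data.frame(lapply(regressors, function(s) s@values))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
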