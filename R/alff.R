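# BOLD spectral power: ALFF / mALFF maps and their group contrasts.

#' ALFF configuration
#'
#' @param band low-frequency band, Hz.
#' @param normalization "subtractive" (mALFF = ALFF - mean(ALFF), default) or
#'   "divisive" (ALFF / mean).
#' @return A list of class \code{AlffConfig}.
#' @export
alffConfig <- function(band = c(0.01, 0.08),
                       normalization = c("subtractive", "divisive")) {
  normalization <- match.arg(normalization)
  stopifnot(band[1] > 0, band[2] > band[1])
  structure(list(band = band, normalization = normalization,
                 detrend = "linear", taper = 0), class = "AlffConfig")
}

#' Residualize head motion from every voxel time series
#'
#' Per voxel, the OLS residual of the series on an intercept plus the six
#' motion parameters, with the voxel mean added back.
#'
#' @param run a \linkS4class{BoldRun} with motion parameters.
#' @return The residualized \linkS4class{BoldRun}.
#' @export
residualizeMotion <- function(run) {
  if (!nrow(run@motion)) stop("no motion parameters present")
  T <- dim(run@data)[4]
  X <- cbind(1, run@motion)
  midx <- which(run@mask > 0)
  flat <- array(run@data, c(prod(dim(run@data)[1:3]), T))
  Y <- t(flat[midx, , drop = FALSE])
  qrX <- qr(X)
  cf <- qr.coef(qrX, Y)
  cf[is.na(cf)] <- 0                       # rank-deficient (e.g. zero motion)
  R <- Y - X %*% cf
  R <- sweep(R, 2, colMeans(Y), "+")
  flat[midx, ] <- t(R)
  run@data <- array(flat, dim(run@data))
  run
}

#' Amplitude of low-frequency fluctuation
#'
#' Per voxel: linear detrend, untapered full-length discrete Fourier
#' transform (no padding, transform length = T, so bins sit at k/(T*TR) Hz),
#' then the mean single-sided amplitude (square root of power) over the bins
#' inside the configured band.
#'
#' @param run a \linkS4class{BoldRun}, already motion-residualized.
#' @param cfg an \code{\link{alffConfig}}.
#' @return An \linkS4class{AlffMaps} with the alff slot filled (malff empty
#'   until \code{\link{normalizeMalff}}).
#' @export
computeAlff <- function(run, cfg = alffConfig()) {
  T <- dim(run@data)[4]
  nyq <- 1 / (2 * run@tr)
  if (cfg$band[2] > nyq)
    stop("band upper edge ", cfg$band[2], " Hz above Nyquist ", round(nyq, 4))
  freqs <- (0:(T %/% 2)) / (T * run@tr)
  sel <- which(freqs >= cfg$band[1] & freqs <= cfg$band[2])
  if (!length(sel)) stop("band contains no frequency bins")
  midx <- which(run@mask > 0)
  flat <- array(run@data, c(prod(dim(run@data)[1:3]), T))
  Y <- t(flat[midx, , drop = FALSE])
  tt <- seq_len(T)
  X <- cbind(1, tt - mean(tt))
  Y <- Y - X %*% qr.coef(qr(X), Y)            # linear detrend
  amp <- Mod(stats::mvfft(Y)) / T
  amp[2:(T %/% 2 + (T %% 2)), ] <- 2 * amp[2:(T %/% 2 + (T %% 2)), ]
  alffVals <- colMeans(amp[sel, , drop = FALSE])
  alff <- array(0, dim(run@data)[1:3])
  alff[midx] <- alffVals
  new("AlffMaps", alff = alff, malff = array(0, dim(alff)), mask = run@mask,
      affine = run@affine, voxelMm = run@voxelMm,
      config = list(band = cfg$band, normalization = cfg$normalization,
                    detrend = cfg$detrend, nBins = length(sel)))
}

#' Spatially normalize ALFF to mALFF
#'
#' Subtractive (default): mALFF = ALFF - mean over the mask, so the mask mean
#' of mALFF is zero.  Divisive: ALFF / mask mean.
#'
#' @param maps an \linkS4class{AlffMaps} from \code{\link{computeAlff}}.
#' @param normalization override of the stored normalization dialect.
#' @return The \linkS4class{AlffMaps} with the malff slot filled.
#' @export
normalizeMalff <- function(maps, normalization = NULL) {
  norm <- normalization %||% maps@config$normalization
  midx <- which(maps@mask > 0)
  if (!length(midx)) stop("mask is empty")
  mu <- mean(maps@alff[midx])
  malff <- array(0, dim(maps@alff))
  malff[midx] <- if (norm == "subtractive") maps@alff[midx] - mu
  else maps@alff[midx] / mu
  maps@malff <- malff
  maps@config$normalization <- norm
  maps
}

#' Two-sample group test on mALFF maps with cluster correction
#'
#' Voxelwise pooled-variance two-sample t inside the analysis mask (optionally
#' restricted to a provided mask, e.g. the union of coupling-difference
#' clusters), followed by Monte-Carlo cluster-extent correction computed on
#' the same (restricted) mask.
#'
#' @param maps list of subject \linkS4class{AlffMaps}.
#' @param groups two-level group label vector, one per subject.
#' @param restrictMask optional 3D mask; must intersect the analysis mask.
#' @param cfg a \code{\link{clusterConfig}} for the correction.
#' @param measure "malff" (default) or "alff".
#' @return List: \code{map} (\linkS4class{StatMap}, two-sample t),
#'   \code{clusters} (data.frame as \code{\link{thresholdClusters}}),
#'   \code{kMin}.
#' @export
groupMapTtest <- function(maps, groups, restrictMask = NULL,
                          cfg = clusterConfig(), measure = c("malff", "alff")) {
  measure <- match.arg(measure)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2 || min(table(groups)) < 2)
    stop("two groups with >= 2 subjects each required")
  base <- maps[[1]]@mask > 0
  mask <- if (!is.null(restrictMask)) base & (restrictMask > 0) else base
  if (!sum(mask)) stop("restricted mask is empty")
  midx <- which(mask)
  vals <- vapply(maps, function(m) slot(m, measure)[midx],
                 numeric(length(midx)))
  g1 <- vals[, groups == lev[1], drop = FALSE]
  g2 <- vals[, groups == lev[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  sp2 <- (rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se, 0)
  varr <- array(NA_real_, dim(mask))
  varr[midx] <- t
  map <- new("StatMap", values = varr, stat = "t", df = n1 + n2 - 2,
             mask = mask * 1, affine = maps[[1]]@affine,
             voxelMm = maps[[1]]@voxelMm,
             provenance = list(contrast = paste(lev, collapse = " >< "),
                               measure = measure,
                               restricted = !is.null(restrictMask)))
  kMin <- monteCarloClusterThreshold(mask * 1, maps[[1]]@voxelMm, cfg)
  clusters <- thresholdClusters(map, kMin, cfg)
  list(map = map, clusters = clusters, kMin = as.integer(kMin))
}

#' ALFF/mALFF maps for one run
#'
#' Motion residualization, ALFF, and mALFF normalization in one call.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param cfg an \code{\link{alffConfig}}.
#' @return An \linkS4class{AlffMaps} with both maps filled.
#' @export
alffPipeline <- function(run, cfg = alffConfig()) {
  normalizeMalff(computeAlff(residualizeMotion(run), cfg))
}
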