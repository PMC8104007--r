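# First-level parametric-modulation GLM (canonical HRF, DCT high pass, AR(1)
# prewhitening) and second-level one-sample / two-group inference.

#' Canonical double-gamma hemodynamic response function
#'
#' Positive gamma peaking at 6 s minus an undershoot gamma peaking at 16 s at
#' 1/6 amplitude, scaled to unit peak.
#'
#' @param t time points, s.
#' @param peak1,peak2 peak times of response and undershoot, s.
#' @param ratio response/undershoot amplitude ratio.
#' @return HRF values at \code{t}.
#' @export
canonicalHRF <- function(t, peak1 = 6, peak2 = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak1, rate = 1) -
    stats::dgamma(t, shape = peak2, rate = 1) / ratio
  h / max(stats::dgamma(seq(0, 32, by = 0.01), shape = peak1, rate = 1) -
            stats::dgamma(seq(0, 32, by = 0.01), shape = peak2, rate = 1) / ratio)
}

#' z-score a series
#'
#' @param x numeric vector.
#' @return (x - mean) / sd; all zeros (with a warning) for a constant input.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant series: z-score degenerates to zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Convolve a per-volume series with the canonical HRF
#'
#' The HRF is sampled at the TR over 0-32 s and convolved causally; the
#' result is truncated to the input length.
#'
#' @param x per-volume series.
#' @param tr repetition time, s.
#' @return Convolved series, same length as \code{x}.
#' @export
convolveHRF <- function(x, tr) {
  h <- canonicalHRF(seq(0, 32, by = tr))
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq_along(x)]
}

# Discrete cosine high-pass drift basis: columns k = 1..K with period
# 2*T*tr/k > cutoff, i.e. K = floor(2*T*tr/cutoff).
.dctBasis <- function(T, tr, cutoff) {
  K <- floor(2 * T * tr / cutoff)
  if (K < 1) return(matrix(nrow = T, ncol = 0))
  tt <- seq_len(T) - 1
  sapply(seq_len(K), function(k) cos(pi * (2 * tt + 1) * k / (2 * T)))
}

#' Build the first-level design matrix
#'
#' The regressor of interest is the canonical-HRF convolution of the z-scored
#' band-power series (the parametric modulation of an eyes-closed boxcar whose
#' unmodulated part is absorbed by the intercept).  Confounds: six motion
#' parameters, white-matter and CSF signals (all centered), a discrete-cosine
#' basis for drift periods above \code{hpCutoff}, and an intercept.
#'
#' @param series a \linkS4class{BandPowerSeries} (or numeric vector) of length
#'   T.
#' @param run a \linkS4class{BoldRun}.
#' @param hpCutoff high-pass cutoff, s.
#' @param center z-score the modulator before convolution (default TRUE).
#' @return A \linkS4class{DesignMatrix}.
#' @export
buildDesign <- function(series, run, hpCutoff = 128, center = TRUE) {
  v <- if (is(series, "BandPowerSeries")) series@values else as.numeric(series)
  T <- dim(run@data)[4]
  if (length(v) != T)
    stop("series length ", length(v), " does not match run length ", T)
  mod <- if (center) zscore(v) else v
  interest <- convolveHRF(mod, run@tr)
  dct <- .dctBasis(T, run@tr, hpCutoff)
  conf <- cbind(run@motion, run@wm, run@csf)
  conf <- sweep(conf, 2, colMeans(conf))
  X <- cbind(interest, conf, dct, 1)
  nm <- c("interest", paste0("mot", 1:6), "wm", "csf",
          if (ncol(dct)) paste0("dct", seq_len(ncol(dct))), "intercept")
  colnames(X) <- nm
  degenerate <- all(abs(interest) < 1e-12)
  qrX <- qr(if (degenerate) X[, -1, drop = FALSE] else X)
  if (qrX$rank < ncol(X) - degenerate) {
    keep <- if (degenerate) nm[-1] else nm
    drop <- keep[qrX$pivot[(qrX$rank + 1):(ncol(X) - degenerate)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  out <- new("DesignMatrix", X = X, names = nm, interest = 1L,
             hpCutoff = hpCutoff, tr = run@tr)
  if (degenerate)
    warning("modulator is constant: interest column is all zeros (degenerate)")
  out
}

# Pooled AR(1) coefficient by restricted (REML) profile likelihood: for
# candidate rho, whiten design and data and maximize, summed over voxels,
#   (1/2) log(1-rho^2) - (1/2) log|Xw'Xw| - ((T-P)/2) log(RSS_v).
# Naive estimates (lag-1 autocorrelation of OLS residuals, or plain ML) are
# biased low here because the drift/confound columns absorb exactly the
# low-frequency fluctuations that identify rho; the restricted likelihood
# removes that bias.
.estimateAR1 <- function(X, Y, maxVoxels = 500L) {
  T <- nrow(X)
  P <- ncol(X)
  V <- ncol(Y)
  sel <- if (V > maxVoxels)
    unique(round(seq(1, V, length.out = maxVoxels))) else seq_len(V)
  Ys <- Y[, sel, drop = FALSE]
  negll <- function(rho) {
    Xw <- .whiten(X, rho)
    Yw <- .whiten(Ys, rho)
    qrw <- qr(Xw)
    rss <- colSums((Yw - Xw %*% qr.coef(qrw, Yw))^2)
    logDetXtX <- 2 * sum(log(abs(diag(qr.R(qrw)))))
    length(sel) * (-0.5 * log(1 - rho^2) + 0.5 * logDetXtX) +
      ((T - P) / 2) * sum(log(pmax(rss, 1e-300)))
  }
  opt <- stats::optimize(negll, interval = c(-0.5, 0.95), tol = 0.005)
  opt$minimum
}

# AR(1) prewhitening transform of a T x n matrix (columns are series).
.whiten <- function(M, rho) {
  if (rho == 0) return(M)
  W <- M
  W[1, ] <- sqrt(1 - rho^2) * M[1, ]
  W[-1, ] <- M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]
  W
}

#' Fit the first-level GLM in every mask voxel
#'
#' A single AR(1) coefficient per run is estimated by profile maximum
#' likelihood pooled over mask voxels; both data and design are prewhitened
#' with it and the GLS coefficients, residual variances and the whitened
#' crossproduct inverse are returned.  With \code{rho = 0} (forced) the fit
#' equals ordinary least squares exactly.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param design a \linkS4class{DesignMatrix}.
#' @param rho NULL to estimate the pooled AR(1) coefficient, or a fixed value
#'   in (-1, 1).
#' @return List of class \code{FirstLevelFit}: \code{beta} (P x V), \code{sigma2}
#'   (length V), \code{XtXinv}, \code{df}, \code{rho}, \code{maskIdx},
#'   \code{design}, \code{run} geometry (dim, affine, mask, voxelMm).
#' @export
fitFirstLevel <- function(run, design, rho = NULL) {
  X <- design@X
  T <- nrow(X)
  midx <- which(run@mask > 0)
  flat <- array(run@data, c(prod(dim(run@data)[1:3]), T))
  Y <- t(flat[midx, , drop = FALSE])          # T x V
  if (is.null(rho)) rho <- .estimateAR1(X, Y)
  Xw <- .whiten(X, rho)
  Yw <- .whiten(Y, rho)
  qrw <- qr(Xw)
  if (qrw$rank < ncol(Xw)) stop("whitened design is near-singular")
  beta <- qr.coef(qrw, Yw)
  resid <- Yw - Xw %*% beta
  df <- T - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrw))
  structure(list(beta = beta, sigma2 = sigma2, XtXinv = XtXinv, df = df,
                 rho = rho, maskIdx = midx, design = design,
                 dim = dim(run@data)[1:3], affine = run@affine,
                 mask = run@mask, voxelMm = run@voxelMm),
            class = "FirstLevelFit")
}

.emptyMap <- function(fit) {
  vals <- array(NA_real_, fit$dim)
  vals
}

#' Extract a coefficient map from a first-level fit
#'
#' @param fit a \code{FirstLevelFit}.
#' @param column design column name or index (default the interest column).
#' @return A \linkS4class{StatMap} with stat "beta".
#' @export
betaMap <- function(fit, column = "interest") {
  j <- if (is.character(column)) match(column, fit$design@names) else column
  vals <- .emptyMap(fit)
  vals[fit$maskIdx] <- fit$beta[j, ]
  new("StatMap", values = vals, stat = "beta", df = 0,
      mask = fit$mask, affine = fit$affine, voxelMm = fit$voxelMm,
      provenance = list(column = fit$design@names[j], rho = fit$rho))
}

.T_CAP <- 1e6

#' Voxelwise t map for a contrast of first-level coefficients
#'
#' t = c'beta / sqrt(sigma2 * c'(Xw'Xw)^-1 c) with the whitened design;
#' df = T - P.  Zero-residual voxels are capped at a finite sentinel and
#' flagged \code{saturated} in the provenance.
#'
#' @param fit a \code{FirstLevelFit}.
#' @param contrast numeric contrast vector of length P (default: 1 on the
#'   interest column).
#' @return A \linkS4class{StatMap} with stat "t".
#' @export
contrastT <- function(fit, contrast = NULL) {
  P <- nrow(fit$beta)
  if (is.null(contrast)) {
    contrast <- numeric(P); contrast[fit$design@interest] <- 1
  }
  if (length(contrast) != P) stop("contrast must have length ", P)
  eff <- as.numeric(crossprod(contrast, fit$beta))
  se2 <- fit$sigma2 * as.numeric(t(contrast) %*% fit$XtXinv %*% contrast)
  t <- ifelse(se2 > 0, eff / sqrt(se2), sign(eff) * .T_CAP)
  saturated <- any(se2 <= 0) || any(abs(t) > .T_CAP)
  t <- pmax(pmin(t, .T_CAP), -.T_CAP)
  vals <- .emptyMap(fit)
  vals[fit$maskIdx] <- t
  new("StatMap", values = vals, stat = "t", df = fit$df, mask = fit$mask,
      affine = fit$affine, voxelMm = fit$voxelMm,
      provenance = list(contrast = contrast, saturated = saturated,
                        rho = fit$rho))
}

.stackMaps <- function(maps) {
  mask <- maps[[1]]@mask
  for (m in maps[-1])
    if (!identical(dim(m@values), dim(mask)))
      stop("maps have differing grids")
  midx <- which(mask > 0)
  vals <- vapply(maps, function(m) m@values[midx], numeric(length(midx)))
  list(vals = vals, midx = midx, mask = mask, affine = maps[[1]]@affine,
       voxelMm = maps[[1]]@voxelMm)
}

#' Second-level one-sample t map
#'
#' Voxelwise one-sample t of subject-level coefficients against zero,
#' df = n - 1 (the within-group coupling map).
#'
#' @param maps list of subject \linkS4class{StatMap}s (stat "beta") on a
#'   common grid.
#' @return A \linkS4class{StatMap} with stat "t".
#' @export
groupOneSample <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 subject maps")
  st <- .stackMaps(maps)
  n <- length(maps)
  m <- rowMeans(st$vals)
  se <- apply(st$vals, 1, stats::sd) / sqrt(n)
  t <- ifelse(se > 0, m / se, sign(m) * .T_CAP)
  t[m == 0 & se == 0] <- 0
  saturated <- any(abs(t) >= .T_CAP)
  t <- pmax(pmin(t, .T_CAP), -.T_CAP)
  vals <- array(NA_real_, dim(st$mask))
  vals[st$midx] <- t
  new("StatMap", values = vals, stat = "t", df = n - 1, mask = st$mask,
      affine = st$affine, voxelMm = st$voxelMm,
      provenance = list(contrast = "one-sample", n = n,
                        saturated = saturated))
}

#' Second-level two-group F map
#'
#' Voxelwise F(1, n-2) for the group-difference contrast on subject-level
#' coefficients; equals the square of the pooled-variance two-sample t, the
#' undirected group-difference test.
#'
#' @param maps list of subject \linkS4class{StatMap}s on a common grid.
#' @param groups vector of two group labels, one per map.
#' @return A \linkS4class{StatMap} with stat "F", df = c(1, n - 2).
#' @export
groupFContrast <- function(maps, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  if (n1 < 2 || n2 < 2) stop("both groups must have >= 2 subjects")
  st <- .stackMaps(maps)
  g1 <- st$vals[, groups == lev[1], drop = FALSE]
  g2 <- st$vals[, groups == lev[2], drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  sp2 <- (rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)) / (n1 + n2 - 2)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  F <- ifelse(se2 > 0, (m1 - m2)^2 / se2, .T_CAP)
  F[(m1 - m2) == 0 & se2 == 0] <- 0
  saturated <- any(F >= .T_CAP)
  F <- pmin(F, .T_CAP)
  vals <- array(NA_real_, dim(st$mask))
  vals[st$midx] <- F
  new("StatMap", values = vals, stat = "F", df = c(1, n1 + n2 - 2),
      mask = st$mask, affine = st$affine, voxelMm = st$voxelMm,
      provenance = list(contrast = paste(lev, collapse = " >< "),
                        n = c(n1, n2), saturated = saturated))
}

# Pad to a size with only small prime factors (fast stats::fft).
.goodSize <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# Fourier transform of a periodized Gaussian kernel on the padded grid.
.kernelFT <- function(d, sigmaVox) {
  padw <- ceiling(4 * sigmaVox)
  dp <- vapply(d + 2 * padw, .goodSize, numeric(1))
  k1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigmaVox^2))
    k / sum(k)
  }
  K <- outer(outer(k1(dp[1]), k1(dp[2])), k1(dp[3]))
  list(FT = stats::fft(K), dp = dp)
}

.smoothWithKernel <- function(arr, kern) {
  d <- dim(arr)
  pad <- array(0, kern$dp)
  pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  sm <- Re(stats::fft(stats::fft(pad) * kern$FT, inverse = TRUE)) /
    prod(kern$dp)
  sm[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

# FFT Gaussian smoothing of one 3D array; sigma in voxels.
.gaussSmooth3d <- function(arr, sigmaVox, kern = NULL) {
  if (is.null(kern)) kern <- .kernelFT(dim(arr), sigmaVox)
  .smoothWithKernel(arr, kern)
}

#' Gaussian spatial smoothing of a volume, map, or 4D run
#'
#' Kernel FWHM is given in mm and converted with the voxel size.  When a mask
#' is supplied the smoothed image is renormalized by the smoothed mask inside
#' it, so values near the mask edge are not diluted by outside zeros.
#' \code{fwhm = 0} is the identity.
#'
#' @param x a 3D array, \linkS4class{StatMap}, or \linkS4class{BoldRun}.
#' @param fwhm kernel full width at half maximum, mm.
#' @param voxelMm voxel size (taken from the object when it carries one).
#' @param mask optional 3D mask for edge renormalization.
#' @return The smoothed object, same type as \code{x}.
#' @export
smoothVolume <- function(x, fwhm, voxelMm = NULL, mask = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (is(x, "BoldRun")) {
    out <- x
    if (fwhm == 0) return(out)
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / x@voxelMm
    kern <- .kernelFT(dim(x@mask), sigma)
    inside <- x@mask > 0
    wm <- pmax(.smoothWithKernel(array(as.numeric(inside), dim(x@mask)),
                                 kern), 1e-12)
    for (t in seq_len(dim(x@data)[4])) {
      sm <- .smoothWithKernel(x@data[, , , t], kern)
      sm[inside] <- sm[inside] / wm[inside]
      sm[!inside] <- 0
      out@data[, , , t] <- sm
    }
    return(out)
  }
  if (is(x, "StatMap")) {
    out <- x
    if (fwhm == 0) return(out)
    v <- x@values
    v[is.na(v)] <- 0
    out@values <- smoothVolume(v, fwhm, x@voxelMm, x@mask)
    out@values[x@mask == 0] <- NA_real_
    return(out)
  }
  if (fwhm == 0) return(x)
  if (is.null(voxelMm)) stop("voxelMm required for a bare array")
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxelMm
  sm <- .gaussSmooth3d(x, sigma)
  if (!is.null(mask)) {
    wm <- .gaussSmooth3d(array(as.numeric(mask > 0), dim(x)), sigma)
    inside <- mask > 0
    sm[inside] <- sm[inside] / pmax(wm[inside], 1e-12)
    sm[!inside] <- 0
  }
  sm
}
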