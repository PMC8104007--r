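# Monte-Carlo cluster-extent multiple-comparison correction and cluster
# reporting in world (MNI) coordinates.

#' Cluster-correction configuration
#'
#' @param voxelP voxelwise height threshold (two-sided by default).
#' @param alphaCluster cluster-wise family-wise error level.
#' @param nIter Monte-Carlo iterations.
#' @param fwhmMm smoothness of the null fields, mm FWHM (the nominal applied
#'   smoothing).
#' @param connectivity 6, 18 or 26 neighborhood for component labeling.
#' @param seed RNG seed of the simulation.
#' @param twoSided threshold at |z| for voxelP/2 (default) or one-sided.
#' @return A list of class \code{ClusterConfig}.
#' @export
clusterConfig <- function(voxelP = 0.005, alphaCluster = 0.05, nIter = 1000L,
                          fwhmMm = 8, connectivity = 26L, seed = 1L,
                          twoSided = TRUE) {
  stopifnot(voxelP > 0, voxelP < 1, nIter >= 100,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(voxelP = voxelP, alphaCluster = alphaCluster,
                 nIter = as.integer(nIter), fwhmMm = fwhmMm,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed), twoSided = twoSided),
            class = "ClusterConfig")
}

.connOffsets <- function(connectivity) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected suprathreshold components in a 3D volume
#'
#' @param idx linear voxel indices of suprathreshold voxels.
#' @param dims 3D grid dimensions.
#' @param connectivity 6, 18 or 26.
#' @return Integer component label per element of \code{idx} (may be empty).
#' @export
labelComponents <- function(idx, dims, connectivity = 26L) {
  if (!length(idx)) return(integer(0))
  off <- .connOffsets(connectivity)
  ai <- arrayInd(idx, dims)
  lin <- function(a) (a[, 3] - 1) * dims[1] * dims[2] + (a[, 2] - 1) * dims[1] +
    a[, 1]
  el <- list()
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ai, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    j <- match(lin(nb[ok, , drop = FALSE]), idx)
    i <- which(ok)[!is.na(j)]
    j <- j[!is.na(j)]
    if (length(i)) el[[length(el) + 1]] <- cbind(i, j)
  }
  if (!length(el)) return(seq_along(idx))
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  igraph::components(g)$membership
}

#' Monte-Carlo cluster-extent threshold
#'
#' Per iteration: standard-normal noise on the grid, Gaussian smoothing at the
#' configured FWHM (smoothing runs over the whole grid, then the mask is
#' applied), rescaling to unit variance inside the mask, thresholding at the
#' z quantile for the voxelwise p (two-sided by default), 26-connectivity
#' component labeling, and recording of the maximum cluster size.  The
#' returned threshold is the smallest extent k whose exceedance fraction
#' P(max cluster >= k) is at or below \code{alphaCluster}.
#'
#' @param mask 3D binary array (the gray-matter analysis mask).
#' @param voxelMm voxel size, mm.
#' @param cfg a \code{\link{clusterConfig}}.
#' @return Integer minimum cluster size (voxels), with attributes
#'   \code{nullMaxSizes} (the simulated null distribution of maximum cluster
#'   size) and \code{cfg}.
#' @export
monteCarloClusterThreshold <- function(mask, voxelMm, cfg = clusterConfig()) {
  dims <- dim(mask)
  midx <- which(mask > 0)
  if (!length(midx)) stop("mask is empty")
  zthr <- if (cfg$twoSided) stats::qnorm(1 - cfg$voxelP / 2) else
    stats::qnorm(1 - cfg$voxelP)
  sigma <- if (cfg$fwhmMm > 0)
    cfg$fwhmMm / (2 * sqrt(2 * log(2))) / voxelMm else 0
  mx <- withSeed(cfg$seed, {
    vapply(seq_len(cfg$nIter), function(it) {
      noise <- array(stats::rnorm(prod(dims)), dims)
      sm <- if (sigma > 0) .gaussSmooth3d(noise, sigma) else noise
      z <- sm[midx] / stats::sd(sm[midx])
      sup <- midx[if (cfg$twoSided) abs(z) > zthr else z > zthr]
      if (!length(sup)) return(0L)
      max(tabulate(labelComponents(sup, dims, cfg$connectivity)))
    }, integer(1))
  })
  if (all(mx == 0)) {
    warning("no iteration produced suprathreshold voxels; k_min = 1")
    return(structure(1L, nullMaxSizes = mx, cfg = cfg))
  }
  ks <- seq_len(max(mx) + 1L)
  exceed <- vapply(ks, function(k) mean(mx >= k), numeric(1))
  kmin <- ks[which(exceed <= cfg$alphaCluster)[1]]
  structure(as.integer(kmin), nullMaxSizes = mx, cfg = cfg)
}

#' Threshold a statistic map and report surviving clusters
#'
#' Converts the voxelwise p to a statistic threshold from the map's df (|t|
#' two-sided, F one-sided), labels suprathreshold voxels at the configured
#' connectivity, discards clusters below \code{kMin}, and reports peaks in
#' world (MNI) mm via the map's affine.  When \code{kMin} carries the null
#' max-cluster-size distribution from
#' \code{\link{monteCarloClusterThreshold}}, each cluster's corrected p is the
#' fraction of null iterations whose maximum cluster reached its size.
#'
#' @param map a \linkS4class{StatMap} with known df.
#' @param kMin minimum cluster extent (voxels).
#' @param cfg a \code{\link{clusterConfig}} (voxelP, connectivity).
#' @return A data.frame: cluster_id, size_vox, peak_x, peak_y, peak_z (mm),
#'   peak_stat, p_corrected — sorted by peak statistic, largest first.
#' @export
thresholdClusters <- function(map, kMin, cfg = clusterConfig()) {
  if (map@stat %in% c("t", "z") && !length(map@df))
    stop("map df missing: cannot convert voxel p to a threshold")
  thr <- switch(map@stat,
                t = stats::qt(1 - cfg$voxelP / 2, map@df),
                z = stats::qnorm(1 - cfg$voxelP / 2),
                F = stats::qf(1 - cfg$voxelP, map@df[1], map@df[2]),
                stop("cannot threshold a '", map@stat, "' map"))
  if (map@stat == "F" && length(map@df) != 2) stop("F map needs df = c(df1, df2)")
  vals <- map@values
  stat <- if (map@stat == "F") vals else abs(vals)
  sup <- which(map@mask > 0 & !is.na(stat) & stat > thr)
  empty <- data.frame(cluster_id = integer(0), size_vox = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_stat = numeric(0),
                      p_corrected = numeric(0))
  if (!length(sup)) return(empty)
  memb <- labelComponents(sup, dim(vals), cfg$connectivity)
  sizes <- tabulate(memb)
  keep <- which(sizes >= kMin)
  if (!length(keep)) return(empty)
  nullMax <- attr(kMin, "nullMaxSizes")
  rows <- lapply(keep, function(cl) {
    vox <- sup[memb == cl]
    peak <- vox[which.max(stat[vox])]
    ijk <- arrayInd(peak, dim(vals))
    world <- map@affine %*% c(ijk, 1)
    data.frame(cluster_id = cl, size_vox = sizes[cl],
               peak_x = world[1], peak_y = world[2], peak_z = world[3],
               peak_stat = vals[peak],
               p_corrected = if (!is.null(nullMax))
                 mean(nullMax >= sizes[cl]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$peak_stat)), ]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Synthetic gray-matter mask on the 3 mm MNI grid
#'
#' A deterministic stand-in for a gray-matter mask when no subject anatomy is
#' available: on the MNI bounding box (-90..90, -126..90, -72..108 mm) it
#' takes a cortical shell (an outer brain ellipsoid minus a scaled inner
#' white-matter ellipsoid) plus a subcortical ellipsoid, about 690 cm^3 of
#' tissue — the size and shape class of a smoothed gray-matter mask resampled
#' to 3 mm.
#'
#' @param voxelMm voxel size, mm.
#' @return List: \code{mask} (3D 0/1 array), \code{affine} (voxel to MNI mm),
#'   \code{voxelMm}.
#' @export
grayMatterTemplateMask <- function(voxelMm = 3) {
  xs <- seq(-90, 90, by = voxelMm)
  ys <- seq(-126, 90, by = voxelMm)
  zs <- seq(-72, 108, by = voxelMm)
  g <- expand.grid(x = xs, y = ys, z = zs)
  ell <- function(c0, r)
    ((g$x - c0[1]) / r[1])^2 + ((g$y - c0[2]) / r[2])^2 +
    ((g$z - c0[3]) / r[3])^2 <= 1
  outer <- ell(c(0, -20, 10), c(67, 84, 66))
  inner <- ell(c(0, -20, 10), 0.84 * c(67, 84, 66))
  subc <- ell(c(0, -18, 8), c(28, 24, 20))
  mask <- array((outer & (!inner | subc)) * 1,
                dim = c(length(xs), length(ys), length(zs)))
  affine <- diag(c(voxelMm, voxelMm, voxelMm, 1))
  affine[1:3, 4] <- c(xs[1], ys[1], zs[1]) - voxelMm
  list(mask = mask, affine = affine, voxelMm = voxelMm)
}
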