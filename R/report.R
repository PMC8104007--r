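# Subject -> group orchestration and table rendering.

#' Run the full first-level pipeline for one subject
#'
#' Cleans the EEG when it is raw (artifact history absent), computes the
#' band-power regressors (five GSP bands plus regional alpha), optionally
#' smooths the BOLD run, and fits one parametric-modulation GLM per
#' regressor, returning the interest-coefficient map for each, plus the
#' subject's ALFF/mALFF maps.
#'
#' @param eeg an \linkS4class{EEGRecording} (raw or clean) or NULL when
#'   \code{power} is given.
#' @param bold a \linkS4class{BoldRun}.
#' @param power optional epochs x bands matrix of band power (bypasses the
#'   EEG path; the regressor set is then one GSP-style series per column).
#' @param tr repetition time, s.
#' @param clean logical: run the cleaning chain on \code{eeg} first.
#' @param cleanCfg a \code{\link{cleanConfig}}.
#' @param fwhm spatial smoothing FWHM applied to the run before the GLM, mm.
#' @param alffCfg an \code{\link{alffConfig}}, or NULL to skip the ALFF maps.
#' @param units band-value units ("amplitude" or "power").
#' @return List: \code{betaMaps} (named list of \linkS4class{StatMap}),
#'   \code{regressors} (named list of series), \code{alff}
#'   (\linkS4class{AlffMaps}), \code{rho} (named numeric, AR(1) per GLM).
#' @export
runSubject <- function(eeg = NULL, bold, power = NULL, tr = bold@tr,
                       clean = FALSE, cleanCfg = cleanConfig(), fwhm = 0,
                       alffCfg = alffConfig(), units = "amplitude") {
  if (is.null(eeg) && is.null(power))
    stop("either an EEG recording or a band-power matrix is required")
  if (!is.null(eeg)) {
    if (clean) eeg <- cleanEEG(eeg, cleanCfg)
    regs <- bandRegressors(eeg, tr, units)
  } else {
    regs <- lapply(colnames(power) %||% paste0("band", seq_len(ncol(power))),
                   function(b) {
                     def <- tryCatch(bandDefinitions(b),
                                     error = function(e) list(name = b, lo = NA,
                                                              hi = NA))
                     new("BandPowerSeries", values = power[, b], band = def,
                         kind = "GSP")
                   })
    names(regs) <- colnames(power) %||% paste0("band", seq_len(ncol(power)))
  }
  run <- if (fwhm > 0) smoothVolume(bold, fwhm) else bold
  betaMaps <- list()
  rho <- numeric(0)
  for (nm in names(regs)) {
    design <- buildDesign(regs[[nm]], run)
    fit <- fitFirstLevel(run, design)
    bm <- betaMap(fit)
    bm@provenance$band <- regs[[nm]]@band$name
    bm@provenance$kind <- regs[[nm]]@kind
    betaMaps[[nm]] <- bm
    rho[nm] <- fit$rho
  }
  list(betaMaps = betaMaps, regressors = regs,
       alff = if (!is.null(alffCfg)) alffPipeline(bold, alffCfg),
       rho = rho)
}

#' Group-level inference for a cohort of subject results
#'
#' For every regressor: the between-group F contrast of subject coefficients
#' with Monte-Carlo cluster correction, and within-group one-sample t maps.
#' mALFF group differences are tested whole-brain and, when any coupling
#' difference survived, restricted to the union of all surviving coupling
#' clusters across regressors.
#'
#' @param subjectResults list of \code{\link{runSubject}} outputs.
#' @param groups two-level label vector, one per subject.
#' @param cfg a \code{\link{clusterConfig}}.
#' @param kMin optional precomputed cluster threshold (with null distribution
#'   attribute) for the coupling maps; computed from the common mask when
#'   NULL.
#' @return List: \code{coupling} (per regressor: fMap, clusters, within),
#'   \code{kMin}, \code{malffWholeBrain}, \code{malffRestricted} (NULL when no
#'   coupling cluster survived), \code{restrictMask}.
#' @export
runGroup <- function(subjectResults, groups, cfg = clusterConfig(),
                     kMin = NULL) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2 || min(table(groups)) < 2)
    stop("two groups with >= 2 subjects each required")
  if (length(subjectResults) != length(groups))
    stop("one group label per subject required")
  regNames <- names(subjectResults[[1]]$betaMaps)
  mask <- subjectResults[[1]]$betaMaps[[1]]@mask
  vox <- subjectResults[[1]]$betaMaps[[1]]@voxelMm
  if (is.null(kMin)) kMin <- monteCarloClusterThreshold(mask, vox, cfg)
  coupling <- list()
  restrict <- array(0, dim(mask))
  for (nm in regNames) {
    maps <- lapply(subjectResults, function(s) s$betaMaps[[nm]])
    fMap <- groupFContrast(maps, groups)
    clusters <- thresholdClusters(fMap, kMin, cfg)
    if (nrow(clusters)) {
      thr <- stats::qf(1 - cfg$voxelP, fMap@df[1], fMap@df[2])
      sup <- which(fMap@mask > 0 & !is.na(fMap@values) & fMap@values > thr)
      memb <- labelComponents(sup, dim(mask), cfg$connectivity)
      sizes <- tabulate(memb)
      restrict[sup[sizes[memb] >= as.integer(kMin)]] <- 1
    }
    within <- lapply(split(seq_along(groups), groups), function(ii)
      if (length(ii) >= 2) groupOneSample(maps[ii]) else NULL)
    coupling[[nm]] <- list(fMap = fMap, clusters = clusters, within = within)
  }
  alffMaps <- lapply(subjectResults, function(s) s$alff)
  haveAlff <- !any(vapply(alffMaps, is.null, logical(1)))
  whole <- if (haveAlff) groupMapTtest(alffMaps, groups, cfg = cfg)
  restricted <- if (haveAlff && sum(restrict) > 0)
    groupMapTtest(alffMaps, groups, restrictMask = restrict, cfg = cfg)
  else NULL
  list(coupling = coupling, kMin = as.integer(kMin),
       malffWholeBrain = whole, malffRestricted = restricted,
       restrictMask = restrict)
}

#' Render group results as TSV tables plus a markdown summary
#'
#' One coupling-cluster table (band, kind, size, peak MNI, peak F, corrected
#' p), one mALFF table (whole-brain and restricted), and a short markdown
#' digest.  Tables are sorted by peak statistic, descending, within band.
#'
#' @param results a \code{\link{runGroup}} output.
#' @param dir output directory.
#' @return Invisible list of written paths.
#' @export
renderReport <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(results$coupling)) {
    cl <- results$coupling[[nm]]$clusters
    if (nrow(cl)) {
      cl$regressor <- nm
      rows[[nm]] <- cl
    }
  }
  couplingTab <- if (length(rows)) {
    tab <- do.call(rbind, rows)
    tab <- tab[, c("regressor", "size_vox", "peak_x", "peak_y", "peak_z",
                   "peak_stat", "p_corrected")]
    tab[order(tab$regressor, -tab$peak_stat), ]
  } else data.frame(regressor = character(0), size_vox = integer(0),
                    peak_x = numeric(0), peak_y = numeric(0),
                    peak_z = numeric(0), peak_stat = numeric(0),
                    p_corrected = numeric(0))
  couplingPath <- file.path(dir, "coupling_clusters.tsv")
  utils::write.table(couplingTab, couplingPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  alffRows <- list()
  addAlff <- function(res, scope) {
    if (is.null(res) || !nrow(res$clusters)) return(NULL)
    cl <- res$clusters
    cl$scope <- scope
    cl
  }
  alffRows$whole <- addAlff(results$malffWholeBrain, "whole-brain")
  alffRows$restr <- addAlff(results$malffRestricted, "coupling-mask")
  alffTab <- if (length(Filter(Negate(is.null), alffRows))) {
    tab <- do.call(rbind, Filter(Negate(is.null), alffRows))
    tab[, c("scope", "size_vox", "peak_x", "peak_y", "peak_z", "peak_stat",
            "p_corrected")]
  } else data.frame(scope = character(0), size_vox = integer(0),
                    peak_x = numeric(0), peak_y = numeric(0),
                    peak_z = numeric(0), peak_stat = numeric(0),
                    p_corrected = numeric(0))
  alffPath <- file.path(dir, "malff_clusters.tsv")
  utils::write.table(alffTab, alffPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  md <- c("# Group results", "",
          sprintf("Cluster extent threshold: k >= %d voxels", results$kMin),
          "", sprintf("Coupling clusters: %d", nrow(couplingTab)),
          sprintf("mALFF clusters: %d", nrow(alffTab)), "")
  mdPath <- file.path(dir, "summary.md")
  writeLines(md, mdPath)
  invisible(list(coupling = couplingPath, malff = alffPath, summary = mdPath))
}
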