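#' Accessors for pipeline objects
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{eegData} (channels x samples matrix), \code{samplingRate},
#' \code{channelLabels}, \code{triggerIndices}, \code{ecgTrace},
#' \code{historyLog}, \code{boldData} (4D array), \code{analysisMask},
#' \code{statValues}, \code{powerValues}.
#'
#' @param x an object of the corresponding class.
#' @return The slot content (a matrix, vector, array or list as documented).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("triggerIndices", function(x) standardGeneric("triggerIndices"))
#' @rdname accessors
#' @export
setGeneric("ecgTrace", function(x) standardGeneric("ecgTrace"))
#' @rdname accessors
#' @export
setGeneric("historyLog", function(x) standardGeneric("historyLog"))
#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))
#' @rdname accessors
#' @export
setGeneric("statValues", function(x) standardGeneric("statValues"))
#' @rdname accessors
#' @export
setGeneric("powerValues", function(x) standardGeneric("powerValues"))

#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("triggerIndices", "EEGRecording", function(x) x@triggers)
#' @rdname accessors
#' @export
setMethod("ecgTrace", "EEGRecording", function(x) x@ecg)
#' @rdname accessors
#' @export
setMethod("historyLog", "EEGRecording", function(x) x@history)
#' @rdname accessors
#' @export
setMethod("boldData", "BoldRun", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("analysisMask", "BoldRun", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("analysisMask", "StatMap", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("statValues", "StatMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("powerValues", "BandPowerSeries", function(x) x@values)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@rate,
              ncol(object@data) / object@rate))
  cat(sprintf("  triggers: %d; ECG: %s; stages applied: %d\n",
              length(object@triggers),
              if (length(object@ecg)) "yes" else "no",
              length(object@history)))
  invisible(object)
})

setMethod("show", "BoldRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldRun: %d x %d x %d x %d, %g mm voxels, TR %g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], object@voxelMm, object@tr,
              sum(object@mask)))
  invisible(object)
})

setMethod("show", "StatMap", function(object) {
  v <- object@values[object@mask > 0]
  cat(sprintf("StatMap (%s, df %s): %d voxels, range [%.3g, %.3g]\n",
              object@stat, paste(round(object@df, 1), collapse = ","),
              length(v), min(v), max(v)))
  invisible(object)
})

setMethod("show", "BandPowerSeries", function(object) {
  cat(sprintf("BandPowerSeries (%s, %s %g-%g Hz): %d epochs, mean %.3g\n",
              object@kind, object@band$name, object@band$lo, object@band$hi,
              length(object@values), mean(object@values)))
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d, %d+%d subjects, %d volumes @ TR %g s, EEG %g Hz x %d ch (%s)\n",
              object@seed, object@nPerGroup, object@nPerGroup, object@nVolumes,
              object@tr, object@eegRate, length(object@channels), object@eegMode))
  if (nrow(object@coupling)) {
    cat("  coupling:\n")
    print(object@coupling, row.names = FALSE)
  }
  invisible(object)
})

setMethod("show", "AlffMaps", function(object) {
  v <- object@alff[object@mask > 0]
  cat(sprintf("AlffMaps: %d voxels, ALFF mean %.4g (%s normalization, %g-%g Hz)\n",
              length(v), mean(v), object@config$normalization,
              object@config$band[1], object@config$band[2]))
  invisible(object)
})
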