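#' Accessors for flyVAM classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{flyId}, \code{chamberId}, \code{fps}, \code{nFrames},
#' \code{coords} (data.frame of frame, x, y, likelihood),
#' \code{interpolatedMask}, \code{geometryUsed}, \code{binStarts},
#' \code{binValues}, \code{binSeconds}, \code{eventFrames},
#' \code{eventTimes}, \code{chamberBounds}, \code{foodRegions}.
#'
#' @param x a flyVAM object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("flyId", function(x) standardGeneric("flyId"))
#' @rdname accessors
#' @export
setGeneric("chamberId", function(x) standardGeneric("chamberId"))
#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("interpolatedMask", function(x) standardGeneric("interpolatedMask"))
#' @rdname accessors
#' @export
setGeneric("geometryUsed", function(x) standardGeneric("geometryUsed"))
#' @rdname accessors
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))
#' @rdname accessors
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))
#' @rdname accessors
#' @export
setGeneric("binSeconds", function(x) standardGeneric("binSeconds"))
#' @rdname accessors
#' @export
setGeneric("eventFrames", function(x) standardGeneric("eventFrames"))
#' @rdname accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("chamberBounds", function(x) standardGeneric("chamberBounds"))
#' @rdname accessors
#' @export
setGeneric("foodRegions", function(x) standardGeneric("foodRegions"))

#' @rdname accessors
#' @export
setMethod("flyId", "TrackingSeries", function(x) x@flyId)
#' @rdname accessors
#' @export
setMethod("chamberId", "TrackingSeries", function(x) x@chamberId)
#' @rdname accessors
#' @export
setMethod("fps", "TrackingSeries", function(x) x@fps)
#' @rdname accessors
#' @export
setMethod("nFrames", "TrackingSeries", function(x) length(x@frame))
#' @rdname accessors
#' @export
setMethod("coords", "TrackingSeries", function(x) {
  data.frame(frame = x@frame, x = x@x, y = x@y, likelihood = x@likelihood)
})

#' @rdname accessors
#' @export
setMethod("flyId", "CleanedSeries", function(x) x@series@flyId)
#' @rdname accessors
#' @export
setMethod("chamberId", "CleanedSeries", function(x) x@series@chamberId)
#' @rdname accessors
#' @export
setMethod("fps", "CleanedSeries", function(x) x@series@fps)
#' @rdname accessors
#' @export
setMethod("nFrames", "CleanedSeries", function(x) length(x@series@frame))
#' @rdname accessors
#' @export
setMethod("coords", "CleanedSeries", function(x) coords(x@series))
#' @rdname accessors
#' @export
setMethod("interpolatedMask", "CleanedSeries", function(x) x@interpolated)
#' @rdname accessors
#' @export
setMethod("geometryUsed", "CleanedSeries", function(x) x@geometryUsed)

#' @rdname accessors
#' @export
setMethod("flyId", "BinnedSeries", function(x) x@flyId)
#' @rdname accessors
#' @export
setMethod("binStarts", "BinnedSeries", function(x) x@binStarts)
#' @rdname accessors
#' @export
setMethod("binValues", "BinnedSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("binSeconds", "BinnedSeries", function(x) x@binSeconds)

#' @rdname accessors
#' @export
setMethod("eventFrames", "CrossingEvents", function(x) x@frame)
#' @rdname accessors
#' @export
setMethod("eventTimes", "CrossingEvents", function(x) x@frame / x@fps)
#' @rdname accessors
#' @export
setMethod("fps", "CrossingEvents", function(x) x@fps)

#' @rdname accessors
#' @export
setMethod("chamberBounds", "ChamberGeometry", function(x) {
  c(xMin = x@xMin, yMin = x@yMin, xMax = x@xMax, yMax = x@yMax)
})
#' @rdname accessors
#' @export
setMethod("foodRegions", "ChamberGeometry", function(x) x@foodRegions)

#' @rdname accessors
#' @export
setMethod("flyId", "PositionSeries", function(x) x@flyId)

setMethod("show", "TrackingSeries", function(object) {
  n <- length(object@frame)
  cat(sprintf("TrackingSeries '%s' (chamber '%s'): %d records at %g fps",
              object@flyId, object@chamberId, n, object@fps))
  if (n) {
    cat(sprintf(", frames %d..%d (%.1f min)",
                object@frame[1L], object@frame[n],
                (object@frame[n] - object@frame[1L] + 1L) / object@fps / 60))
    nlow <- sum(object@likelihood < 0.9, na.rm = TRUE)
    cat(sprintf("\n  likelihood < 0.9: %d (%.2f%%)", nlow, 100 * nlow / n))
  }
  cat("\n")
})

setMethod("show", "CleanedSeries", function(object) {
  n <- length(object@series@frame)
  cat(sprintf("CleanedSeries '%s': %d records, %d interpolated (%.2f%%)\n",
              object@series@flyId, n, sum(object@interpolated),
              if (n) 100 * mean(object@interpolated) else 0))
  cat("  geometry: "); show(object@geometryUsed)
})

setMethod("show", "ChamberGeometry", function(object) {
  cat(sprintf(
    "ChamberGeometry [%g, %g) x [%g, %g) px, long axis %s, midline %g",
    object@xMin, object@xMax, object@yMin, object@yMax,
    object@longAxis, object@midline))
  if (!is.na(object@mmPerPx)) cat(sprintf(", %g mm/px", object@mmPerPx))
  if (nrow(object@foodRegions))
    cat(sprintf("; food: %s",
                paste(object@foodRegions$label, collapse = ", ")))
  cat("\n")
})

setMethod("show", "LightSchedule", function(object) {
  p <- object@phases
  cat(sprintf("LightSchedule: %d phases over %.1f h (zt0 = %g s)\n",
              nrow(p), (p$end[nrow(p)] - p$start[1L]) / 3600, object@zt0))
  cat(" ", paste(sprintf("%s[%gh]", p$kind, (p$end - p$start) / 3600),
                 collapse = " "), "\n")
})

setMethod("show", "BinnedSeries", function(object) {
  cat(sprintf(
    "BinnedSeries '%s' (%s): %d bins of %g min, total %.4g\n",
    object@flyId, object@metric, length(object@values),
    object@binSeconds / 60, sum(object@values)))
})

setMethod("show", "CrossingEvents", function(object) {
  cat(sprintf(
    "CrossingEvents: %d crossings over [%g, %g] s at %g fps\n",
    length(object@frame), object@spanStart, object@spanEnd, object@fps))
})

setMethod("show", "PreferenceHistogram", function(object) {
  cat(sprintf("PreferenceHistogram '%s': %d bins", object@flyId,
              length(object@fractions)))
  if (length(object@foodBins))
    cat(sprintf("; food bins: %s",
                paste(sprintf("%s=%d", names(object@foodBins),
                              object@foodBins), collapse = ", ")))
  cat("\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: %g s at %g fps, entry rates day %g / night %g",
           " per frame,\n  startle x%g for %g s, siesta depth %g",
           " (ZT %g-%g), food bias %g, misdetect %g, seed %d\n"),
    object@durationS, object@fps, object@dayRate, object@nightRate,
    object@startleBoost, object@startleDurationS, object@siestaDepth,
    object@siestaStartZT, object@siestaEndZT, object@foodBias,
    object@misdetectRate, object@seed))
})
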