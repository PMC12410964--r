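#' Infer chamber limits from the detections themselves
#'
#' Estimates the chamber rectangle from the cloud of confident detections:
#' per axis, the \code{[loQ, hiQ]} quantile interval padded outward by
#' \code{pad} pixels. Extreme quantiles reject the rare misdetections that
#' land outside the chamber while a fly that patrols the walls still pins
#' the edges. The midline is placed at the centre of the long axis (the
#' longer inferred dimension). A user-supplied geometry always takes
#' precedence over inference in [cleanSeries()].
#'
#' @param series a [TrackingSeries-class].
#' @param likelihoodFloor detections below this confidence are ignored for
#'   inference (default 0.9).
#' @param loQ,hiQ quantiles per axis (defaults 0.001 and 0.999).
#' @param pad outward padding in px (default 2).
#' @param minDetections minimum number of confident detections required
#'   (default 100).
#' @return A [ChamberGeometry-class].
#' @export
inferChamberLimits <- function(series, likelihoodFloor = 0.9,
                               loQ = 0.001, hiQ = 0.999, pad = 2,
                               minDetections = 100L) {
  ok <- !is.na(series@x) & !is.na(series@y) &
    !is.na(series@likelihood) & series@likelihood >= likelihoodFloor
  if (sum(ok) < minDetections)
    stop("chamber-limit inference needs at least ", minDetections,
         " detections with likelihood >= ", likelihoodFloor,
         "; got ", sum(ok), " - supply the geometry explicitly")
  qx <- stats::quantile(series@x[ok], c(loQ, hiQ), names = FALSE)
  qy <- stats::quantile(series@y[ok], c(loQ, hiQ), names = FALSE)
  xMin <- qx[1L] - pad; xMax <- qx[2L] + pad
  yMin <- qy[1L] - pad; yMax <- qy[2L] + pad
  if ((xMax - xMin) < 5 || (yMax - yMin) < 5)
    stop("degenerate geometry: inferred chamber extent below 5 px (",
         sprintf("%.1f x %.1f", xMax - xMin, yMax - yMin),
         ") - detections too concentrated to identify the chamber")
  ChamberGeometry(xMin, yMin, xMax, yMax)
}

#' Flag out-of-chamber and low-confidence frames
#'
#' A frame is flagged when its detection falls outside the chamber
#' rectangle, its likelihood is below the floor, or the position is
#' missing. Flagged frames are replaced by [interpolateOutOfBounds()].
#' Setting \code{likelihoodFloor = 0} disables confidence filtering and
#' reproduces the purely spatial rule.
#'
#' @param series a [TrackingSeries-class].
#' @param geom a [ChamberGeometry-class].
#' @param likelihoodFloor confidence floor (default 0.9).
#' @return Logical mask, one element per record (TRUE = flagged).
#' @export
flagOutOfBounds <- function(series, geom, likelihoodFloor = 0.9) {
  missing <- !is.finite(series@x) | !is.finite(series@y)
  lowlik <- !is.na(series@likelihood) & series@likelihood < likelihoodFloor
  outside <- !missing & !containsPoint(geom, series@x, series@y)
  missing | lowlik | outside
}

#' Replace flagged frames by the flank-averaged position
#'
#' Every flagged frame's position becomes the coordinate-wise midpoint of
#' the nearest preceding and nearest following unflagged detections, so a
#' run of consecutive flagged frames receives one constant position and
#' contributes zero distance internally — a conservative choice that never
#' invents motion. Leading runs copy the first unflagged position,
#' trailing runs the last. \code{method = "linear"} instead interpolates
#' linearly in frame time across the run.
#'
#' @param series a [TrackingSeries-class].
#' @param mask logical mask from [flagOutOfBounds()].
#' @param geom the [ChamberGeometry-class] recorded in the result.
#' @param method \code{"midpoint"} (default) or \code{"linear"}.
#' @return A [CleanedSeries-class].
#' @export
interpolateOutOfBounds <- function(series, mask, geom,
                                   method = c("midpoint", "linear")) {
  method <- match.arg(method)
  n <- length(series@frame)
  if (length(mask) != n) stop("mask length must equal record count")
  if (n && all(mask))
    stop("unrecoverable series: every frame is flagged")
  x <- series@x; y <- series@y
  if (any(mask)) {
    idx <- seq_len(n)
    keep <- idx; keep[mask] <- 0L
    prv <- cummax(keep)                      # 0 where no preceding unmasked
    nxtKeep <- idx; nxtKeep[mask] <- n + 1L
    nxt <- rev(cummin(rev(nxtKeep)))         # n+1 where no following unmasked
    prv[prv == 0L] <- nxt[prv == 0L]         # leading run: copy next
    nxt[nxt == n + 1L] <- prv[nxt == n + 1L] # trailing run: copy previous
    m <- which(mask)
    if (method == "midpoint") {
      x[m] <- (x[prv[m]] + x[nxt[m]]) / 2
      y[m] <- (y[prv[m]] + y[nxt[m]]) / 2
    } else {
      f <- as.numeric(series@frame)
      w <- ifelse(nxt[m] == prv[m], 0,
                  (f[m] - f[prv[m]]) / (f[nxt[m]] - f[prv[m]]))
      x[m] <- x[prv[m]] + w * (x[nxt[m]] - x[prv[m]])
      y[m] <- y[prv[m]] + w * (y[nxt[m]] - y[prv[m]])
    }
  }
  out <- series
  out@x <- x; out@y <- y
  new("CleanedSeries", series = out, interpolated = as.logical(mask),
      geometryUsed = geom)
}

#' Clean a tracking series (three-step misdetection control)
#'
#' Convenience wrapper running the whole cleaning procedure: (1) identify
#' the chamber limits ([inferChamberLimits()], unless \code{geom} is
#' supplied); (2) flag frames detected outside the chamber (or below the
#' likelihood floor; [flagOutOfBounds()]); (3) replace them by the average
#' of the flanking in-chamber detections ([interpolateOutOfBounds()]).
#'
#' @inheritParams flagOutOfBounds
#' @inheritParams interpolateOutOfBounds
#' @param geom a [ChamberGeometry-class], or NULL to infer it.
#' @param ... passed to [inferChamberLimits()].
#' @return A [CleanedSeries-class].
#' @export
cleanSeries <- function(series, geom = NULL, likelihoodFloor = 0.9,
                        method = "midpoint", ...) {
  if (is.null(geom))
    geom <- inferChamberLimits(series, likelihoodFloor = likelihoodFloor, ...)
  mask <- flagOutOfBounds(series, geom, likelihoodFloor = likelihoodFloor)
  interpolateOutOfBounds(series, mask, geom, method = method)
}

#' Cleaning report for one series
#'
#' @param cleaned a [CleanedSeries-class].
#' @return One-row data.frame: fly_id, n_frames, n_flagged, pct_flagged and
#'   the chamber bounds used.
#' @export
cleaningReport <- function(cleaned) {
  g <- cleaned@geometryUsed
  n <- length(cleaned@series@frame)
  data.frame(
    fly_id = cleaned@series@flyId, n_frames = n,
    n_flagged = sum(cleaned@interpolated),
    pct_flagged = if (n) 100 * mean(cleaned@interpolated) else 0,
    x_min = g@xMin, y_min = g@yMin, x_max = g@xMax, y_max = g@yMax,
    stringsAsFactors = FALSE
  )
}
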