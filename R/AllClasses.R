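#' @import methods
#' @importFrom stats quantile median t.test wilcox.test p.adjust rnorm runif
#' @importFrom utils read.csv write.csv head tail
NULL

.PHASE_KINDS <- c("L", "D", "DD-subjective-day", "DD-subjective-night")
.DAY_KINDS <- c("L", "DD-subjective-day")

#' Arena layout for crop-grid computation
#'
#' Describes how a camera frame is divided into a regular grid of chamber
#' crop rectangles: outer margins, inter-chamber gaps and the grid shape.
#' Pixel coordinates are 0-based with origin at the top-left corner and y
#' increasing downward (image convention); all intervals are half-open
#' \code{[min, max)}.
#'
#' @slot frameWidth,frameHeight frame size in pixels.
#' @slot rows,cols grid shape (counts, each >= 1).
#' @slot marginX,marginY outer margins in pixels (>= 0).
#' @slot gapX,gapY gaps between adjacent chambers in pixels (>= 0).
#' @seealso [computeCropGrid()]
#' @export
setClass("ArenaLayout",
  representation(
    frameWidth = "numeric", frameHeight = "numeric",
    rows = "integer", cols = "integer",
    marginX = "numeric", marginY = "numeric",
    gapX = "numeric", gapY = "numeric"
  )
)

setValidity("ArenaLayout", function(object) {
  msg <- character()
  if (object@rows < 1L || object@cols < 1L)
    msg <- c(msg, "rows and cols must each be >= 1")
  if (any(c(object@marginX, object@marginY, object@gapX, object@gapY) < 0))
    msg <- c(msg, "margins and gaps must be >= 0")
  if (object@frameWidth <= 0 || object@frameHeight <= 0)
    msg <- c(msg, "frame dimensions must be positive")
  if (length(msg)) msg else TRUE
})

#' @param frameWidth,frameHeight,rows,cols,marginX,marginY,gapX,gapY see slots.
#' @rdname ArenaLayout-class
#' @export
ArenaLayout <- function(frameWidth, frameHeight, rows, cols,
                        marginX = 0, marginY = 0, gapX = 0, gapY = 0) {
  new("ArenaLayout",
    frameWidth = as.numeric(frameWidth), frameHeight = as.numeric(frameHeight),
    rows = as.integer(rows), cols = as.integer(cols),
    marginX = as.numeric(marginX), marginY = as.numeric(marginY),
    gapX = as.numeric(gapX), gapY = as.numeric(gapY)
  )
}

#' Chamber geometry
#'
#' A rectangular chamber in pixel coordinates (half-open \code{[min, max)}
#' on both axes), its long-axis orientation, the midline used by the
#' virtual beam-crossing statistic, optional labelled food regions along
#' the long axis, and an optional mm-per-pixel scale.
#'
#' @slot xMin,yMin,xMax,yMax chamber rectangle in pixels.
#' @slot longAxis \code{"horizontal"} or \code{"vertical"}; defaults to the
#'   longer of the two dimensions.
#' @slot midline pixel coordinate of the virtual beam along the long axis,
#'   strictly inside the chamber.
#' @slot foodRegions data.frame with columns \code{label}, \code{start},
#'   \code{end}: non-overlapping intervals along the long axis.
#' @slot mmPerPx optional scale (mm per pixel); \code{NA} when unknown.
#' @export
setClass("ChamberGeometry",
  representation(
    xMin = "numeric", yMin = "numeric", xMax = "numeric", yMax = "numeric",
    longAxis = "character", midline = "numeric",
    foodRegions = "data.frame", mmPerPx = "numeric"
  )
)

setValidity("ChamberGeometry", function(object) {
  msg <- character()
  if (!(object@xMin < object@xMax)) msg <- c(msg, "xMin must be < xMax")
  if (!(object@yMin < object@yMax)) msg <- c(msg, "yMin must be < yMax")
  if (!object@longAxis %in% c("horizontal", "vertical"))
    msg <- c(msg, "longAxis must be 'horizontal' or 'vertical'")
  lo <- if (object@longAxis == "horizontal") object@xMin else object@yMin
  hi <- if (object@longAxis == "horizontal") object@xMax else object@yMax
  if (!(object@midline > lo && object@midline < hi))
    msg <- c(msg, "midline must lie strictly inside the long-axis interval")
  fr <- object@foodRegions
  if (nrow(fr)) {
    if (!all(c("label", "start", "end") %in% names(fr)))
      msg <- c(msg, "foodRegions needs columns label, start, end")
    else {
      if (any(fr$start >= fr$end))
        msg <- c(msg, "food region start must be < end")
      if (any(fr$start < lo) || any(fr$end > hi))
        msg <- c(msg, "food regions must lie within the chamber long axis")
      o <- order(fr$start)
      if (nrow(fr) > 1 && any(fr$start[o][-1] < fr$end[o][-nrow(fr)]))
        msg <- c(msg, "food regions must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param xMin,yMin,xMax,yMax,longAxis,midline,foodRegions,mmPerPx see slots.
#'   \code{longAxis} and \code{midline} default to the longer dimension and
#'   its centre; \code{foodRegions} may be given as a named list of
#'   \code{c(start, end)} intervals.
#' @rdname ChamberGeometry-class
#' @export
ChamberGeometry <- function(xMin, yMin, xMax, yMax, longAxis = NULL,
                            midline = NULL, foodRegions = NULL,
                            mmPerPx = NA_real_) {
  if (is.null(longAxis))
    longAxis <- if ((xMax - xMin) >= (yMax - yMin)) "horizontal" else "vertical"
  lo <- if (longAxis == "horizontal") xMin else yMin
  hi <- if (longAxis == "horizontal") xMax else yMax
  if (is.null(midline)) midline <- (lo + hi) / 2
  if (is.null(foodRegions)) {
    fr <- data.frame(label = character(), start = numeric(), end = numeric(),
                     stringsAsFactors = FALSE)
  } else if (is.data.frame(foodRegions)) {
    fr <- foodRegions
  } else {
    fr <- data.frame(
      label = names(foodRegions),
      start = vapply(foodRegions, `[`, numeric(1), 1L),
      end = vapply(foodRegions, `[`, numeric(1), 2L),
      stringsAsFactors = FALSE
    )
    rownames(fr) <- NULL
  }
  new("ChamberGeometry",
    xMin = as.numeric(xMin), yMin = as.numeric(yMin),
    xMax = as.numeric(xMax), yMax = as.numeric(yMax),
    longAxis = longAxis, midline = as.numeric(midline),
    foodRegions = fr, mmPerPx = as.numeric(mmPerPx)
  )
}

#' Per-frame tracking series for one fly
#'
#' One fly in one chamber at a fixed frame rate: 0-based frame indices
#' (strictly increasing, gaps permitted for dropped frames), pixel
#' positions and the tracking network's per-frame confidence in [0, 1].
#' Missing detections are NA positions.
#'
#' @slot flyId,chamberId labels.
#' @slot fps frames per second (default 5).
#' @slot frame integer, 0-based, strictly increasing.
#' @slot x,y pixel coordinates (NA = missing).
#' @slot likelihood confidence in [0, 1] (NA permitted).
#' @export
setClass("TrackingSeries",
  representation(
    flyId = "character", chamberId = "character", fps = "numeric",
    frame = "integer", x = "numeric", y = "numeric", likelihood = "numeric"
  )
)

setValidity("TrackingSeries", function(object) {
  msg <- character()
  n <- length(object@frame)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@likelihood) != n)
    msg <- c(msg, "frame, x, y, likelihood must have equal length")
  if (n > 1 && any(diff(object@frame) <= 0L))
    msg <- c(msg, "frame indices must be strictly increasing")
  if (n > 0 && object@frame[1L] < 0L)
    msg <- c(msg, "frame indices must be >= 0")
  lk <- object@likelihood
  if (any(lk < 0 | lk > 1, na.rm = TRUE))
    msg <- c(msg, "likelihood must lie in [0, 1]")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param flyId,chamberId,fps,frame,x,y,likelihood see slots.
#' @rdname TrackingSeries-class
#' @export
TrackingSeries <- function(frame, x, y, likelihood, fps = 5,
                           flyId = "fly", chamberId = "chamber") {
  new("TrackingSeries",
    flyId = flyId, chamberId = chamberId, fps = as.numeric(fps),
    frame = as.integer(frame), x = as.numeric(x), y = as.numeric(y),
    likelihood = as.numeric(likelihood)
  )
}

#' Cleaned tracking series
#'
#' A [TrackingSeries-class] after misdetection control: every position lies
#' inside \code{geometryUsed}, and \code{interpolated} marks the frames
#' whose position was replaced by the flank-averaged estimate.
#'
#' @slot series the cleaned [TrackingSeries-class].
#' @slot interpolated logical mask, one element per record.
#' @slot geometryUsed the [ChamberGeometry-class] the series was cleaned
#'   against (supplied or inferred).
#' @export
setClass("CleanedSeries",
  representation(
    series = "TrackingSeries", interpolated = "logical",
    geometryUsed = "ChamberGeometry"
  )
)

setValidity("CleanedSeries", function(object) {
  msg <- character()
  s <- object@series
  if (length(object@interpolated) != length(s@frame))
    msg <- c(msg, "interpolated mask length must equal record count")
  g <- object@geometryUsed
  inside <- s@x >= g@xMin & s@x < g@xMax & s@y >= g@yMin & s@y < g@yMax
  if (!all(inside))
    msg <- c(msg, "all cleaned positions must lie inside geometryUsed")
  if (length(msg)) msg else TRUE
})

#' Light/dark schedule
#'
#' Ordered, contiguous light phases anchored to experiment time (seconds
#' since recording start), plus the Zeitgeber reference \code{zt0} (the
#' experiment time of lights-on, ZT0). Phase kinds are \code{"L"},
#' \code{"D"}, \code{"DD-subjective-day"} and \code{"DD-subjective-night"};
#' phase intervals are half-open \code{[start, end)}.
#'
#' @slot phases data.frame with columns \code{kind}, \code{start},
#'   \code{end} (seconds).
#' @slot zt0 experiment time (s) of the lights-on reference.
#' @seealso [ldSchedule()], [ddSchedule()], [phaseAt()], [ztOf()]
#' @export
setClass("LightSchedule",
  representation(phases = "data.frame", zt0 = "numeric")
)

setValidity("LightSchedule", function(object) {
  p <- object@phases
  msg <- character()
  if (!all(c("kind", "start", "end") %in% names(p)))
    return("phases needs columns kind, start, end")
  if (!nrow(p)) return("schedule must contain at least one phase")
  if (!all(p$kind %in% .PHASE_KINDS))
    msg <- c(msg, paste("phase kinds must be one of:",
                        paste(.PHASE_KINDS, collapse = ", ")))
  if (any(p$start >= p$end)) msg <- c(msg, "each phase must have start < end")
  if (nrow(p) > 1 && any(abs(p$start[-1] - p$end[-nrow(p)]) > 1e-9))
    msg <- c(msg, "phases must be contiguous and non-overlapping")
  if (length(msg)) msg else TRUE
})

#' Build a light schedule from phase kinds and durations
#'
#' @param kinds character vector of phase kinds.
#' @param hours numeric vector of phase durations in hours.
#' @param zt0 experiment time (s) of lights-on (ZT0); default 0, i.e. the
#'   recording starts at lights-on.
#' @param start experiment time (s) at which the first phase begins.
#' @return A [LightSchedule-class].
#' @export
LightSchedule <- function(kinds, hours, zt0 = 0, start = 0) {
  stopifnot(length(kinds) == length(hours))
  ends <- start + cumsum(hours * 3600)
  starts <- c(start, ends[-length(ends)])
  new("LightSchedule",
    phases = data.frame(kind = kinds, start = starts, end = ends,
                        stringsAsFactors = FALSE),
    zt0 = as.numeric(zt0)
  )
}

#' @param nDays number of 24 h cycles.
#' @rdname LightSchedule
#' @export
ldSchedule <- function(nDays, zt0 = 0, start = 0) {
  LightSchedule(rep(c("L", "D"), nDays), rep(12, 2 * nDays),
                zt0 = zt0, start = start)
}

#' @rdname LightSchedule
#' @export
ddSchedule <- function(nDays, zt0 = 0, start = 0) {
  LightSchedule(rep(c("DD-subjective-day", "DD-subjective-night"), nDays),
                rep(12, 2 * nDays), zt0 = zt0, start = start)
}

#' Binned per-fly metric series
#'
#' A metric (summed distance, crossing counts, or sleep minutes) on a
#' regular time grid. Bins are contiguous, equal width, anchored at
#' \code{binStarts[1]}; an incomplete trailing bin is dropped at
#' construction time by the binning functions.
#'
#' @slot flyId label.
#' @slot metric one of \code{"distance"}, \code{"crossings"},
#'   \code{"sleep_min"} (free-form permitted).
#' @slot binSeconds bin width in seconds.
#' @slot binStarts bin start times, experiment seconds.
#' @slot values one value per bin, all >= 0.
#' @export
setClass("BinnedSeries",
  representation(
    flyId = "character", metric = "character",
    binSeconds = "numeric", binStarts = "numeric", values = "numeric"
  )
)

setValidity("BinnedSeries", function(object) {
  msg <- character()
  if (length(object@binStarts) != length(object@values))
    msg <- c(msg, "binStarts and values must have equal length")
  if (object@binSeconds <= 0) msg <- c(msg, "binSeconds must be > 0")
  if (length(object@binStarts) > 1 &&
      any(abs(diff(object@binStarts) - object@binSeconds) > 1e-6))
    msg <- c(msg, "bins must be contiguous and equal width")
  if (any(object@values < -1e-12, na.rm = TRUE))
    msg <- c(msg, "values must be >= 0")
  if (length(msg)) msg else TRUE
})

BinnedSeries <- function(values, binSeconds, binStarts, metric = "distance",
                         flyId = "fly") {
  new("BinnedSeries",
    flyId = flyId, metric = metric, binSeconds = as.numeric(binSeconds),
    binStarts = as.numeric(binStarts), values = as.numeric(values)
  )
}

#' Midline crossing events (virtual beam)
#'
#' Frame indices at which a virtual-beam crossing completed, plus the
#' recording span needed to turn gaps between crossings into sleep bouts.
#'
#' @slot frame integer frame indices, strictly increasing.
#' @slot fps frames per second.
#' @slot spanStart,spanEnd recording span in experiment seconds.
#' @export
setClass("CrossingEvents",
  representation(
    frame = "integer", fps = "numeric",
    spanStart = "numeric", spanEnd = "numeric"
  )
)

setValidity("CrossingEvents", function(object) {
  msg <- character()
  if (length(object@frame) > 1 && any(diff(object@frame) <= 0L))
    msg <- c(msg, "event frames must be strictly increasing")
  if (object@spanEnd < object@spanStart)
    msg <- c(msg, "spanEnd must be >= spanStart")
  if (length(msg)) msg else TRUE
})

#' Per-second (or binned) position trace
#'
#' @slot flyId label.
#' @slot times start time (s) of each second or bin.
#' @slot x,y averaged pixel position per entry.
#' @export
setClass("PositionSeries",
  representation(flyId = "character", times = "numeric",
                 x = "numeric", y = "numeric")
)

setValidity("PositionSeries", function(object) {
  if (length(object@times) != length(object@x) ||
      length(object@times) != length(object@y))
    "times, x, y must have equal length" else TRUE
})

#' Longitudinal food-preference histogram
#'
#' Per-fly occupancy fractions in equal-width bins along the chamber long
#' axis, plus the mapping from food labels to the bin abutting each food.
#'
#' @slot flyId label.
#' @slot edges bin edges (px along the long axis), strictly increasing,
#'   spanning the chamber.
#' @slot fractions per-bin occupancy fractions, summing to 1.
#' @slot foodBins named integer vector: food label -> 1-based bin index of
#'   the bin containing the food region's inner edge.
#' @export
setClass("PreferenceHistogram",
  representation(flyId = "character", edges = "numeric",
                 fractions = "numeric", foodBins = "integer")
)

setValidity("PreferenceHistogram", function(object) {
  msg <- character()
  if (length(object@edges) != length(object@fractions) + 1L)
    msg <- c(msg, "edges must have length(fractions) + 1")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (any(object@fractions < 0))
    msg <- c(msg, "fractions must be >= 0")
  if (length(object@fractions) &&
      abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for a synthetic fly
#'
#' Full ground-truth parameterisation of one synthetic fly: a two-state
#' (rest/move) Markov walker in a rectangular chamber with circadian
#' modulation of the rest-to-move entry rate, startle boosts after each
#' light transition, an optional midday siesta, optional attraction toward
#' a food region, reflecting walls, and rare injected misdetections
#' reported outside the chamber at low likelihood.
#'
#' @slot fps frames per second (default 5).
#' @slot durationS recording duration in seconds.
#' @slot chamber [ChamberGeometry-class].
#' @slot schedule [LightSchedule-class].
#' @slot dayRate,nightRate per-frame probability of entering the move state
#'   during (subjective) day / night.
#' @slot moveExitRate per-frame probability of a move bout ending.
#' @slot startleBoost multiplicative entry-rate increase applied for
#'   \code{startleDurationS} seconds after each L <-> D transition.
#' @slot startleDurationS startle window length (s).
#' @slot siestaDepth multiplicative factor (<= 1) applied during the siesta
#'   window; 1 disables.
#' @slot siestaStartZT,siestaEndZT siesta window in ZT hours.
#' @slot foodBias probability, per move frame, that the heading is redrawn
#'   toward the food target; 0 disables.
#' @slot biasFood label of the food region to bias toward ("" = first).
#' @slot stepScale half-normal step-length scale (px per frame while moving).
#' @slot turnSd heading diffusion (radians per frame).
#' @slot misdetectRate per-frame probability that the reported position is
#'   replaced by a point in a 20 px band outside the chamber with
#'   likelihood drawn from U(0, 0.5).
#' @slot seed integer RNG seed; fixed seed gives bit-identical output.
#' @seealso [simulateFly()], [simulateExperiment()]
#' @export
setClass("SimulationConfig",
  representation(
    fps = "numeric", durationS = "numeric",
    chamber = "ChamberGeometry", schedule = "LightSchedule",
    dayRate = "numeric", nightRate = "numeric", moveExitRate = "numeric",
    startleBoost = "numeric", startleDurationS = "numeric",
    siestaDepth = "numeric", siestaStartZT = "numeric",
    siestaEndZT = "numeric",
    foodBias = "numeric", biasFood = "character",
    stepScale = "numeric", turnSd = "numeric",
    misdetectRate = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(object@dayRate, object@nightRate, object@moveExitRate,
             object@foodBias, object@misdetectRate)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "rates and probabilities must lie in [0, 1]")
  if (object@stepScale <= 0) msg <- c(msg, "stepScale must be > 0")
  if (object@durationS < 1) msg <- c(msg, "durationS must be >= 1 s")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (object@siestaDepth < 0 || object@siestaDepth > 1)
    msg <- c(msg, "siestaDepth must lie in [0, 1]")
  if (object@startleBoost < 1)
    msg <- c(msg, "startleBoost must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated fly
#'
#' @slot trueX,trueY true positions per frame (px).
#' @slot state integer per frame: 0 = rest, 1 = move.
#' @slot misdetected logical mask of frames whose reported position differs
#'   from the true position.
#' @slot expectedRates named list of the per-phase entry rates used.
#' @export
setClass("GroundTruth",
  representation(
    trueX = "numeric", trueY = "numeric", state = "integer",
    misdetected = "logical", expectedRates = "list"
  )
)
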