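#' Frame-to-frame travel distances
#'
#' Euclidean distance between consecutive cleaned positions; element i is
#' the distance covered between record i and record i+1 (length n-1). A
#' gap in the frame index contributes the straight-line distance across
#' the gap. Interpolated runs are constant-position, so they contribute 0
#' internally.
#'
#' @param cleaned a [CleanedSeries-class].
#' @return Numeric vector of length \code{nFrames(cleaned) - 1} (empty for
#'   fewer than 2 records), all values >= 0, in px.
#' @export
frameDistances <- function(cleaned) {
  s <- cleaned@series
  n <- length(s@frame)
  if (n < 2L) return(numeric())
  sqrt(diff(s@x)^2 + diff(s@y)^2)
}

# shared binning core: sums weights w at times t into bins of binSeconds
# anchored at tStart; the incomplete trailing bin (and anything before
# tStart) is dropped. spanEnd defines the recording duration.
.binSum <- function(t, w, binSeconds, tStart, spanEnd) {
  nBins <- floor((spanEnd - tStart) / binSeconds)
  starts <- tStart + (seq_len(nBins) - 1) * binSeconds
  if (nBins < 1L) return(list(starts = numeric(), values = numeric()))
  idx <- floor((t - tStart) / binSeconds) + 1
  ok <- idx >= 1 & idx <= nBins
  values <- numeric(nBins)
  if (any(ok)) {
    sums <- rowsum(w[ok], idx[ok])
    values[as.integer(rownames(sums))] <- sums[, 1L]
  }
  list(starts = starts, values = values)
}

.spanEnd <- function(series) (series@frame[length(series@frame)] + 1) / series@fps

#' Bin summed travel distance on a regular time grid
#'
#' The distance of the interval between records i and i+1 is assigned to
#' the bin containing record i's timestamp; a bin's value is the sum of
#' its assigned distances, so the binned values conserve total distance
#' over complete bins exactly. Bins are anchored at \code{tStart}
#' (recording start by default) and the incomplete trailing bin is
#' dropped.
#'
#' @param cleaned a [CleanedSeries-class].
#' @param binMinutes bin width in minutes (1, 10, 30 and 60 are the usual
#'   choices; any positive value works).
#' @param tStart bin-grid anchor in experiment seconds (default 0).
#' @return A [BinnedSeries-class] with metric \code{"distance"} (px).
#' @export
binActivity <- function(cleaned, binMinutes = 10, tStart = 0) {
  s <- cleaned@series
  d <- frameDistances(cleaned)
  t <- s@frame[-length(s@frame)] / s@fps
  b <- .binSum(t, d, binMinutes * 60, tStart, .spanEnd(s))
  BinnedSeries(b$values, binMinutes * 60, b$starts,
               metric = "distance", flyId = s@flyId)
}

#' Group aggregates over per-fly binned series
#'
#' Element-wise mean or median over flies sharing one bin grid. Flies
#' listed in \code{exclude} (e.g. flagged dead) are dropped first.
#'
#' @param binnedList list of [BinnedSeries-class] on identical grids.
#' @param exclude character vector of flyIds to drop.
#' @return A [BinnedSeries-class] labelled \code{"group_mean"} /
#'   \code{"group_median"}.
#' @export
groupMean <- function(binnedList, exclude = NULL) {
  m <- .groupMatrix(binnedList, exclude)
  BinnedSeries(colMeans(m$values), m$binSeconds, m$binStarts,
               metric = m$metric, flyId = "group_mean")
}

#' @rdname groupMean
#' @export
groupMedian <- function(binnedList, exclude = NULL) {
  m <- .groupMatrix(binnedList, exclude)
  BinnedSeries(apply(m$values, 2L, stats::median), m$binSeconds,
               m$binStarts, metric = m$metric, flyId = "group_median")
}

.groupMatrix <- function(binnedList, exclude = NULL) {
  if (!is.null(exclude))
    binnedList <- Filter(function(b) !(b@flyId %in% exclude), binnedList)
  if (!length(binnedList)) stop("no series left after exclusion")
  ref <- binnedList[[1L]]
  for (b in binnedList) {
    if (length(b@values) != length(ref@values) ||
        b@binSeconds != ref@binSeconds ||
        (length(ref@binStarts) &&
         any(abs(b@binStarts - ref@binStarts) > 1e-9)))
      stop("alignment error: all flies must share the same bin grid")
  }
  list(
    values = do.call(rbind, lapply(binnedList, function(b) b@values)),
    binSeconds = ref@binSeconds, binStarts = ref@binStarts,
    metric = ref@metric,
    flyIds = vapply(binnedList, function(b) b@flyId, character(1))
  )
}

#' Virtual activity-monitor beam crossings
#'
#' Emulates the infrared beam of a Drosophila Activity Monitor with a
#' virtual line at the chamber midline: a crossing is recorded at record
#' i+1 whenever the held side of the midline changes between records i and
#' i+1. The held side uses hysteresis — a position exactly on the midline
#' keeps the previously held side (first-frame ties resolve to the low
#' side) — so grazing the line never registers a crossing. Constant
#' interpolated runs generate no internal crossings.
#'
#' @param cleaned a [CleanedSeries-class] (all positions inside the
#'   chamber).
#' @param geom optional [ChamberGeometry-class]; defaults to the geometry
#'   the series was cleaned against.
#' @return A [CrossingEvents-class].
#' @export
virtualDam <- function(cleaned, geom = NULL) {
  if (is.null(geom)) geom <- cleaned@geometryUsed
  s <- cleaned@series
  if (!all(containsPoint(geom, s@x, s@y)))
    stop("virtualDam requires all positions inside the chamber; ",
         "clean the series first")
  n <- length(s@frame)
  spanStart <- if (n) s@frame[1L] / s@fps else 0
  spanEnd <- if (n) .spanEnd(s) else 0
  if (n < 2L)
    return(new("CrossingEvents", frame = integer(), fps = s@fps,
               spanStart = spanStart, spanEnd = spanEnd))
  coordAlong <- if (geom@longAxis == "horizontal") s@x else s@y
  sides <- .heldSides(coordAlong, geom@midline)
  cross <- which(diff(sides) != 0) + 1L
  new("CrossingEvents", frame = s@frame[cross], fps = s@fps,
      spanStart = spanStart, spanEnd = spanEnd)
}

#' Midline band occupancy (detections near the beam)
#'
#' Alternative reading of a beam-based activity count: the frames whose
#' long-axis position lies within \code{bandPx} of the midline, for
#' comparison with the crossing statistic of [virtualDam()].
#'
#' @inheritParams virtualDam
#' @param bandPx half-width of the band around the midline (px).
#' @return A [CrossingEvents-class] holding the in-band frame indices.
#' @export
midlineBandDetections <- function(cleaned, geom = NULL, bandPx = 2) {
  if (is.null(geom)) geom <- cleaned@geometryUsed
  s <- cleaned@series
  coordAlong <- if (geom@longAxis == "horizontal") s@x else s@y
  hit <- abs(coordAlong - geom@midline) <= bandPx
  new("CrossingEvents", frame = s@frame[hit], fps = s@fps,
      spanStart = if (length(s@frame)) s@frame[1L] / s@fps else 0,
      spanEnd = if (length(s@frame)) .spanEnd(s) else 0)
}

#' Bin crossing events into counts per time bin
#'
#' @param events a [CrossingEvents-class].
#' @param binMinutes bin width in minutes.
#' @param tStart bin-grid anchor (s), default 0.
#' @return A [BinnedSeries-class] with metric \code{"crossings"}.
#' @export
binCrossings <- function(events, binMinutes = 10, tStart = 0) {
  t <- events@frame / events@fps
  b <- .binSum(t, rep(1, length(t)), binMinutes * 60, tStart, events@spanEnd)
  BinnedSeries(b$values, binMinutes * 60, b$starts, metric = "crossings",
               flyId = "fly")
}

#' Sleep bouts from beam-crossing inactivity
#'
#' Applies the standard operational sleep definition: every maximal
#' interval without a beam crossing (bounded by the recording span edges)
#' lasting at least \code{thresholdS} seconds (default 300 s = 5 min) is
#' one sleep bout covering the whole interval.
#'
#' @param events a [CrossingEvents-class].
#' @param thresholdS minimum inactivity duration (s), default 300.
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{duration} (s), carrying \code{spanStart}/\code{spanEnd}
#'   attributes.
#' @export
sleepBouts <- function(events, thresholdS = 300) {
  bounds <- c(events@spanStart, events@frame / events@fps, events@spanEnd)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  keep <- (ends - starts) >= thresholdS
  out <- data.frame(start = starts[keep], end = ends[keep],
                    duration = ends[keep] - starts[keep])
  attr(out, "spanStart") <- events@spanStart
  attr(out, "spanEnd") <- events@spanEnd
  out
}

#' Sleep minutes per time bin
#'
#' A bin's value is the overlap (in minutes) of all sleep bouts with the
#' bin, hence never exceeds the bin width.
#'
#' @param bouts data.frame from [sleepBouts()].
#' @param binMinutes bin width in minutes.
#' @param tStart bin-grid anchor (s), default 0.
#' @param spanEnd recording end (s); defaults to the bouts' span.
#' @return A [BinnedSeries-class] with metric \code{"sleep_min"}.
#' @export
sleepBinned <- function(bouts, binMinutes = 10, tStart = 0,
                        spanEnd = attr(bouts, "spanEnd")) {
  binSec <- binMinutes * 60
  nBins <- floor((spanEnd - tStart) / binSec)
  starts <- tStart + (seq_len(nBins) - 1) * binSec
  values <- numeric(nBins)
  if (nrow(bouts) && nBins) {
    for (k in seq_len(nrow(bouts))) {
      ov <- pmax(0, pmin(bouts$end[k], starts + binSec) -
                      pmax(bouts$start[k], starts))
      values <- values + ov / 60
    }
  }
  BinnedSeries(values, binSec, starts, metric = "sleep_min", flyId = "fly")
}

#' Average-day (ZT-anchored) profile
#'
#' Folds a binned series onto one 24 h Zeitgeber cycle: the value at ZT
#' slot h is the mean over \code{nFullDays} complete days of that fly's
#' bin values at slot h. Requires the bin grid to align with ZT0 and the
#' bin width to divide 24 h.
#'
#' @param binned a [BinnedSeries-class].
#' @param schedule a [LightSchedule-class] (provides the ZT0 anchor).
#' @param nFullDays number of complete 24 h cycles to average (default 2).
#' @return A [BinnedSeries-class] whose binStarts are ZT seconds in
#'   \code{[0, 86400)}.
#' @export
averageDay <- function(binned, schedule, nFullDays = 2) {
  binSec <- binned@binSeconds
  if (86400 %% binSec != 0)
    stop("bin width must divide 24 h for an average-day profile")
  rel <- binned@binStarts - schedule@zt0
  if (any(abs(rel %% binSec) > 1e-6))
    stop("bin grid is not aligned to ZT0")
  dayIdx <- floor(rel / 86400)
  slot <- rel - dayIdx * 86400
  perDay <- 86400 / binSec
  counts <- table(dayIdx)
  complete <- sort(as.numeric(names(counts)[counts == perDay]))
  complete <- complete[complete >= 0]
  if (length(complete) < nFullDays)
    stop("insufficient full days: need ", nFullDays, ", found ",
         length(complete))
  use <- dayIdx %in% complete[seq_len(nFullDays)]
  prof <- rowsum(binned@values[use], slot[use]) / nFullDays
  slots <- as.numeric(rownames(prof))
  o <- order(slots)
  BinnedSeries(prof[o, 1L], binSec, slots[o], metric = binned@metric,
               flyId = binned@flyId)
}

#' Per-fly totals over complete day and night phases
#'
#' Sums the binned metric over every complete (subjective) day phase and
#' every complete night phase of the schedule. A phase counts as complete
#' when all of its bins are present in the series; bins are assigned to
#' the phase covering their start time.
#'
#' @param binned a [BinnedSeries-class].
#' @param schedule a [LightSchedule-class].
#' @return Named numeric \code{c(day = , night = )}.
#' @export
dayNightTotals <- function(binned, schedule) {
  p <- schedule@phases
  starts <- binned@binStarts
  binSec <- binned@binSeconds
  totals <- c(day = 0, night = 0)
  for (k in seq_len(nrow(p))) {
    inPhase <- starts >= p$start[k] & starts < p$end[k]
    nExpected <- floor((p$end[k] - p$start[k]) / binSec)
    if (nExpected == 0L || sum(inPhase) < nExpected) next
    key <- if (isDayPhase(p$kind[k])) "day" else "night"
    totals[key] <- totals[key] + sum(binned@values[inPhase])
  }
  totals
}

#' @param binnedList list of per-fly [BinnedSeries-class].
#' @rdname dayNightTotals
#' @export
dayNightTable <- function(binnedList, schedule) {
  rows <- lapply(binnedList, function(b) {
    tot <- dayNightTotals(b, schedule)
    data.frame(fly_id = b@flyId, day = tot[["day"]], night = tot[["night"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare day/night totals between two groups
#'
#' Two-sided t-test per phase between the per-fly totals of two groups.
#' The Welch (unequal-variance) form is the default; set
#' \code{varEqual = TRUE} for the classical Student form.
#'
#' @param tabA,tabB data.frames from [dayNightTable()].
#' @param varEqual use the pooled-variance Student t-test (default FALSE =
#'   Welch).
#' @return data.frame with one row per phase: group means, t statistic,
#'   degrees of freedom and two-sided p-value.
#' @export
compareTotals <- function(tabA, tabB, varEqual = FALSE) {
  out <- lapply(c("day", "night"), function(phase) {
    a <- tabA[[phase]]; b <- tabB[[phase]]
    if (length(a) < 2L || length(b) < 2L)
      stop("statistic undefined: need at least 2 flies per group")
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("statistic undefined: zero variance in both groups (", phase, ")")
    tt <- stats::t.test(a, b, var.equal = varEqual)
    data.frame(phase = phase, mean_a = mean(a), mean_b = mean(b),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p.value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stack per-fly average-day profiles into a matrix
#'
#' @param profiles list of [BinnedSeries-class] from [averageDay()] on a
#'   shared ZT grid.
#' @return Numeric matrix, one row per fly, one column per ZT bin.
#' @export
profileMatrix <- function(profiles) {
  m <- .groupMatrix(profiles)
  colnames(m$values) <- sprintf("ZT%g", m$binStarts / 3600)
  rownames(m$values) <- m$flyIds
  m$values
}

#' Hour-by-hour group comparison with FDR control
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per ZT hour between two
#' groups of per-fly average-day values, with multiplicity handled as a
#' false-discovery-rate procedure: Benjamini-Hochberg at \code{q}
#' (default 0.05), or the two-stage Benjamini-Krieger-Yekutieli procedure
#' (\code{method = "BKY"}). Exact p-values where the implementation in
#' \code{stats::wilcox.test} permits; ties fall back to the normal
#' approximation with tie correction automatically.
#'
#' @param matA,matB matrices from [profileMatrix()] (flies x hours).
#' @param q FDR level (default 0.05).
#' @param method \code{"BH"} or \code{"BKY"}.
#' @return data.frame with one row per hour: \code{zt_hour}, U statistic,
#'   raw and adjusted p-values, \code{discovery} flag, and \code{higher}
#'   (which group's median is higher, for discovered hours).
#' @export
compareHourly <- function(matA, matB, q = 0.05, method = c("BH", "BKY")) {
  method <- match.arg(method)
  if (ncol(matA) != ncol(matB))
    stop("alignment error: groups must share the hourly grid")
  res <- lapply(seq_len(ncol(matA)), function(h) {
    a <- matA[, h]; b <- matB[, h]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    data.frame(statistic = unname(wt$statistic), p = wt$p.value,
               medA = stats::median(a), medB = stats::median(b))
  })
  res <- do.call(rbind, res)
  if (method == "BH") {
    padj <- stats::p.adjust(res$p, method = "BH")
    disc <- padj <= q
  } else {
    bky <- .adjustBKY(res$p, q)
    padj <- bky$padj
    disc <- bky$discovery
  }
  higher <- ifelse(!disc, "",
                   ifelse(res$medA > res$medB, "A",
                          ifelse(res$medB > res$medA, "B", "tie")))
  hours <- if (!is.null(colnames(matA)))
    sub("^ZT", "", colnames(matA)) else as.character(seq_len(ncol(matA)) - 1)
  data.frame(zt_hour = as.numeric(hours), statistic = res$statistic,
             p = res$p, p_adj = padj, discovery = disc, higher = higher,
             stringsAsFactors = FALSE)
}

# two-stage Benjamini-Krieger-Yekutieli FDR: stage 1 is BH at q/(1+q),
# the discovery count estimates m0, stage 2 is BH at q*m/m0
.adjustBKY <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(stats::p.adjust(p, "BH") <= q1)
  if (r1 == 0L)
    return(list(padj = stats::p.adjust(p, "BH"), discovery = rep(FALSE, m)))
  if (r1 == m)
    return(list(padj = stats::p.adjust(p, "BH"), discovery = rep(TRUE, m)))
  m0 <- m - r1
  padj <- stats::p.adjust(p, "BH") * m0 / m
  list(padj = padj, discovery = padj <= q1)
}

#' Flag a dead (motionless) fly
#'
#' A fly with zero beam crossings and less than \code{minPx} total
#' movement over the final 24 h of the recording is flagged. Exclusion is
#' never automatic: pass flagged ids to the \code{exclude} argument of the
#' group functions explicitly.
#'
#' @param cleaned a [CleanedSeries-class].
#' @param minPx movement threshold (px), default 1.
#' @return TRUE/FALSE.
#' @export
flagDeadFly <- function(cleaned, minPx = 1) {
  s <- cleaned@series
  if (length(s@frame) < 2L) return(TRUE)
  tEnd <- .spanEnd(s)
  inWin <- s@frame / s@fps >= (tEnd - 86400)
  if (sum(inWin) < 2L) return(TRUE)
  sub <- new("CleanedSeries",
             series = TrackingSeries(s@frame[inWin], s@x[inWin], s@y[inWin],
                                     s@likelihood[inWin], fps = s@fps,
                                     flyId = s@flyId,
                                     chamberId = s@chamberId),
             interpolated = cleaned@interpolated[inWin],
             geometryUsed = cleaned@geometryUsed)
  sum(frameDistances(sub)) < minPx &&
    length(virtualDam(sub)@frame) == 0L
}
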