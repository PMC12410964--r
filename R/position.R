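#' Average position per second
#'
#' The position for second s is the mean of all frame positions with
#' timestamps in \code{[s, s+1)}. Seconds inside the covered range with no
#' frames inherit the previous second's value, keeping the trace on a
#' uniform 1 s grid.
#'
#' @param cleaned a [CleanedSeries-class].
#' @return A [PositionSeries-class] with one entry per covered second.
#' @export
positionPerSecond <- function(cleaned) {
  s <- cleaned@series
  n <- length(s@frame)
  if (!n)
    return(new("PositionSeries", flyId = s@flyId, times = numeric(),
               x = numeric(), y = numeric()))
  sec <- floor(s@frame / s@fps)
  secs <- seq(sec[1L], sec[n])
  mx <- rowsum(s@x, sec) / as.vector(table(sec))
  my <- rowsum(s@y, sec) / as.vector(table(sec))
  have <- as.numeric(rownames(mx))
  x <- rep(NA_real_, length(secs)); y <- rep(NA_real_, length(secs))
  pos <- match(have, secs)
  x[pos] <- mx[, 1L]; y[pos] <- my[, 1L]
  # empty seconds inherit the previous second's value
  filled <- !is.na(x)
  idx <- seq_along(x); idx[!filled] <- 0L
  carry <- cummax(idx)
  x <- x[carry]; y <- y[carry]
  new("PositionSeries", flyId = s@flyId, times = as.numeric(secs),
      x = x, y = y)
}

#' Average a per-second position trace over time bins
#'
#' Second-level positions are averaged within each bin (anchored at
#' \code{tStart}; incomplete trailing bin dropped).
#'
#' @param perSecond a [PositionSeries-class] from [positionPerSecond()].
#' @param binMinutes bin width in minutes.
#' @param tStart bin-grid anchor (s), default 0.
#' @return A [PositionSeries-class] with one entry per bin.
#' @export
positionBinned <- function(perSecond, binMinutes, tStart = 0) {
  binSec <- binMinutes * 60
  t <- perSecond@times
  spanEnd <- if (length(t)) t[length(t)] + 1 else 0
  nBins <- floor((spanEnd - tStart) / binSec)
  starts <- tStart + (seq_len(nBins) - 1) * binSec
  idx <- floor((t - tStart) / binSec) + 1
  ok <- idx >= 1 & idx <= nBins
  cnt <- tabulate(idx[ok], nBins)
  if (any(cnt == 0))
    stop("empty bin in per-second trace; trace must cover the bin grid")
  sx <- numeric(nBins); sy <- numeric(nBins)
  rs <- rowsum(cbind(perSecond@x[ok], perSecond@y[ok]), idx[ok])
  at <- as.integer(rownames(rs))
  sx[at] <- rs[, 1L]; sy[at] <- rs[, 2L]
  new("PositionSeries", flyId = perSecond@flyId, times = starts,
      x = sx / cnt, y = sy / cnt)
}

#' Mean position trace across flies
#'
#' @param traces list of [PositionSeries-class] on identical time grids.
#' @return A [PositionSeries-class] labelled \code{"group_mean"}.
#' @export
groupPosition <- function(traces) {
  if (!length(traces)) stop("no traces supplied")
  ref <- traces[[1L]]
  for (tr in traces)
    if (length(tr@times) != length(ref@times) ||
        (length(ref@times) && any(abs(tr@times - ref@times) > 1e-9)))
      stop("alignment error: traces must share the same time grid")
  x <- rowMeans(do.call(cbind, lapply(traces, function(tr) tr@x)))
  y <- rowMeans(do.call(cbind, lapply(traces, function(tr) tr@y)))
  new("PositionSeries", flyId = "group_mean", times = ref@times,
      x = x, y = y)
}

# half-open equal-width cell index along one axis; positions at the upper
# chamber edge cannot occur (half-open chamber), clamp guards float error
.cellIndex <- function(v, lo, hi, n) {
  as.integer(pmin(pmax(floor((v - lo) / (hi - lo) * n), 0), n - 1)) + 1L
}

#' Occupancy heatmap over a chamber grid
#'
#' Fraction of frames whose (cleaned) position falls in each cell of an
#' \code{nx x ny} grid of equal-width, half-open cells spanning the
#' chamber. Fractions sum to 1. Interpolated frames count at their
#' interpolated position unless \code{excludeInterpolated}.
#'
#' @param cleaned a [CleanedSeries-class].
#' @param geom a [ChamberGeometry-class]; defaults to the cleaning
#'   geometry.
#' @param nx,ny grid shape (defaults give roughly 1 mm cells when the
#'   scale is known, else >= 10 cells on the long axis).
#' @param excludeInterpolated drop interpolated frames (default FALSE).
#' @return Matrix of occupancy fractions, \code{ny} rows (y, top to
#'   bottom) by \code{nx} columns (x).
#' @export
occupancyHeatmap <- function(cleaned, geom = NULL, nx = NULL, ny = NULL,
                             excludeInterpolated = FALSE) {
  if (is.null(geom)) geom <- cleaned@geometryUsed
  w <- geom@xMax - geom@xMin; h <- geom@yMax - geom@yMin
  if (is.null(nx) || is.null(ny)) {
    if (!is.na(geom@mmPerPx)) {
      if (is.null(nx)) nx <- max(1L, round(w * geom@mmPerPx))
      if (is.null(ny)) ny <- max(1L, round(h * geom@mmPerPx))
    } else {
      longN <- 20L
      if (is.null(nx)) nx <- if (w >= h) longN else max(1L, round(longN * w / h))
      if (is.null(ny)) ny <- if (h > w) longN else max(1L, round(longN * h / w))
    }
  }
  s <- cleaned@series
  keep <- if (excludeInterpolated) !cleaned@interpolated else
    rep(TRUE, length(s@frame))
  if (!any(keep)) stop("no frames left for the heatmap")
  ix <- .cellIndex(s@x[keep], geom@xMin, geom@xMax, nx)
  iy <- .cellIndex(s@y[keep], geom@yMin, geom@yMax, ny)
  counts <- matrix(0, nrow = ny, ncol = nx)
  tab <- table(factor(iy, levels = seq_len(ny)),
               factor(ix, levels = seq_len(nx)))
  counts[] <- as.numeric(tab)
  counts / sum(counts)
}

#' Longitudinal food-preference histogram
#'
#' Occupancy fraction of one fly in \code{nBins} equal-width bins along
#' the chamber long axis (the 50 mm axis of the two-choice chamber gives
#' ~5 mm per bin at the default 10). Each food region is mapped to the bin
#' containing its inner edge (the edge facing the chamber centre), i.e.
#' the bin abutting that food.
#'
#' @param cleaned a [CleanedSeries-class].
#' @param geom a [ChamberGeometry-class]; defaults to the cleaning
#'   geometry.
#' @param nBins number of longitudinal bins (default 10).
#' @param excludeInterpolated drop interpolated frames (default FALSE).
#' @return A [PreferenceHistogram-class].
#' @export
preferenceHistogram <- function(cleaned, geom = NULL, nBins = 10L,
                                excludeInterpolated = FALSE) {
  if (is.null(geom)) geom <- cleaned@geometryUsed
  s <- cleaned@series
  horiz <- geom@longAxis == "horizontal"
  lo <- if (horiz) geom@xMin else geom@yMin
  hi <- if (horiz) geom@xMax else geom@yMax
  v <- if (horiz) s@x else s@y
  keep <- if (excludeInterpolated) !cleaned@interpolated else
    rep(TRUE, length(v))
  if (!any(keep)) stop("no frames left for the histogram")
  idx <- .cellIndex(v[keep], lo, hi, nBins)
  counts <- tabulate(idx, nBins)
  fr <- geom@foodRegions
  foodBins <- integer()
  if (nrow(fr)) {
    centre <- (lo + hi) / 2
    inner <- ifelse((fr$start + fr$end) / 2 < centre, fr$end, fr$start)
    # the inner edge is a bin boundary when regions align with the grid;
    # nudge inward so the mapped bin is the one abutting the food
    eps <- (hi - lo) * 1e-9
    inner <- ifelse((fr$start + fr$end) / 2 < centre, inner + eps,
                    inner - eps)
    foodBins <- .cellIndex(inner, lo, hi, nBins)
    names(foodBins) <- fr$label
  }
  new("PreferenceHistogram", flyId = s@flyId,
      edges = seq(lo, hi, length.out = nBins + 1L),
      fractions = counts / sum(counts), foodBins = foodBins)
}

#' Between-group test at the food-adjacent bins
#'
#' For each food region, a two-sided Welch t-test compares the per-fly
#' occupancy fractions of the bin closest to that food between two groups
#' of flies.
#'
#' @param histsA,histsB lists of [PreferenceHistogram-class] (>= 2 flies
#'   per group, shared bin grid and food mapping).
#' @param varEqual use the Student form (default FALSE = Welch).
#' @return data.frame with one row per food: \code{food}, \code{bin},
#'   group mean fractions, t statistic, df, p-value.
#' @export
preferenceTest <- function(histsA, histsB, varEqual = FALSE) {
  if (length(histsA) < 2L || length(histsB) < 2L)
    stop("statistic undefined: need at least 2 flies per group")
  ref <- histsA[[1L]]
  frac <- function(hists, bin)
    vapply(hists, function(h) h@fractions[bin], numeric(1))
  if (!length(ref@foodBins)) stop("no food regions mapped to bins")
  out <- lapply(seq_along(ref@foodBins), function(k) {
    bin <- ref@foodBins[k]
    a <- frac(histsA, bin); b <- frac(histsB, bin)
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("statistic undefined: zero variance in both groups at bin ", bin)
    tt <- stats::t.test(a, b, var.equal = varEqual)
    data.frame(food = names(ref@foodBins)[k], bin = unname(bin),
               mean_a = mean(a), mean_b = mean(b),
               statistic = unname(tt$statistic),
               df = unname(tt$parameter), p.value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
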