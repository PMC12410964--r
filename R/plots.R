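#' @importFrom rlang .data
NULL

# light-phase background rectangles in the field's conventional colours:
# L yellow, D grey, subjective day light grey, subjective night grey
.phaseFill <- c("L" = "#FFF3B0", "D" = "#BDBDBD",
                "DD-subjective-day" = "#E8E8E8",
                "DD-subjective-night" = "#BDBDBD")

.phaseLayer <- function(schedule, timeScale = 3600) {
  if (is.null(schedule)) return(NULL)
  p <- schedule@phases
  ggplot2::annotate("rect",
    xmin = p$start / timeScale, xmax = p$end / timeScale,
    ymin = -Inf, ymax = Inf,
    fill = .phaseFill[p$kind], alpha = 0.5)
}

#' Group activity trace with light/dark shading
#'
#' Thin per-fly lines plus a thick group mean over experiment time, with
#' the light schedule shaded behind (light phases yellow, dark grey,
#' subjective day light grey).
#'
#' @param binnedList list of per-fly [BinnedSeries-class] on one grid.
#' @param schedule optional [LightSchedule-class] for the shading.
#' @param stat group line: \code{"mean"} or \code{"median"}.
#' @return A ggplot object.
#' @export
plotGroupTrace <- function(binnedList, schedule = NULL,
                           stat = c("mean", "median")) {
  stat <- match.arg(stat)
  grp <- if (stat == "mean") groupMean(binnedList) else
    groupMedian(binnedList)
  per <- do.call(rbind, lapply(binnedList, binnedTidy))
  gdf <- binnedTidy(grp)
  ggplot2::ggplot() +
    .phaseLayer(schedule) +
    ggplot2::geom_line(data = per,
      ggplot2::aes(x = .data$bin_start / 3600, y = .data$value,
                   group = .data$fly_id),
      linewidth = 0.2, alpha = 0.35, colour = "grey30") +
    ggplot2::geom_line(data = gdf,
      ggplot2::aes(x = .data$bin_start / 3600, y = .data$value),
      linewidth = 0.9, colour = "#1B7837") +
    ggplot2::labs(x = "time (h)", y = grp@metric) +
    ggplot2::theme_classic()
}

#' Average-day bar profile
#'
#' @param profiles list of per-fly ZT profiles from [averageDay()].
#' @param schedule optional [LightSchedule-class]; the first 24 h of
#'   shading is folded onto the ZT axis.
#' @return A ggplot object.
#' @export
plotAverageDay <- function(profiles, schedule = NULL) {
  grp <- groupMean(profiles)
  m <- profileMatrix(profiles)
  se <- apply(m, 2L, stats::sd) / sqrt(nrow(m))
  df <- data.frame(zt = grp@binStarts / 3600, value = grp@values, se = se)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$zt, y = .data$value))
  if (!is.null(schedule)) {
    p <- schedule@phases
    day1 <- p[p$end <= p$start[1L] + 86400, , drop = FALSE]
    day1$start <- day1$start - schedule@zt0
    day1$end <- day1$end - schedule@zt0
    g <- g + ggplot2::annotate("rect",
      xmin = day1$start / 3600, xmax = day1$end / 3600,
      ymin = -Inf, ymax = Inf, fill = .phaseFill[day1$kind], alpha = 0.5)
  }
  g +
    ggplot2::geom_col(width = grp@binSeconds / 3600 * 0.9,
                      fill = "#1B7837") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$value - .data$se, ymax = .data$value + .data$se),
      width = 0.2, linewidth = 0.3) +
    ggplot2::labs(x = "ZT (h)", y = grp@metric) +
    ggplot2::theme_classic()
}

#' Day/night total boxplots for two groups
#'
#' @param tabA,tabB data.frames from [dayNightTable()].
#' @param labels group labels (length 2).
#' @return A ggplot object.
#' @export
plotDayNightTotals <- function(tabA, tabB, labels = c("A", "B")) {
  long <- function(tab, lab) {
    data.frame(group = lab,
               phase = rep(c("day", "night"), each = nrow(tab)),
               total = c(tab$day, tab$night))
  }
  df <- rbind(long(tabA, labels[1L]), long(tabB, labels[2L]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$total,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_fill_manual(values = c("#1B7837", "#762A83")) +
    ggplot2::labs(x = NULL, y = "total distance (px)") +
    ggplot2::theme_classic()
}

#' Occupancy heatmap with food-side annotation
#'
#' @param heat matrix from [occupancyHeatmap()].
#' @param geom optional [ChamberGeometry-class]; labels the food side(s).
#' @return A ggplot object.
#' @export
plotHeatmap <- function(heat, geom = NULL) {
  df <- expand.grid(row = seq_len(nrow(heat)), col = seq_len(ncol(heat)))
  df$value <- as.vector(heat)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "occupancy") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x cell", y = "y cell") +
    ggplot2::theme_minimal()
  if (!is.null(geom) && nrow(geom@foodRegions)) {
    lo <- if (geom@longAxis == "horizontal") geom@xMin else geom@yMin
    hi <- if (geom@longAxis == "horizontal") geom@xMax else geom@yMax
    nAlong <- if (geom@longAxis == "horizontal") ncol(heat) else nrow(heat)
    fr <- geom@foodRegions
    at <- (fr$start + fr$end) / 2
    cells <- .cellIndex(at, lo, hi, nAlong)
    if (geom@longAxis == "horizontal")
      g <- g + ggplot2::annotate("text", x = cells, y = nrow(heat) + 0.8,
                                 label = fr$label, size = 3)
    else
      g <- g + ggplot2::annotate("text", x = ncol(heat) + 0.8, y = cells,
                                 label = fr$label, size = 3)
  }
  g
}

#' Longitudinal preference histogram with food labels
#'
#' @param hists list of [PreferenceHistogram-class] (per-fly); the bars
#'   show the across-fly mean fraction, the error bars one SE.
#' @return A ggplot object.
#' @export
plotPreferenceHistogram <- function(hists) {
  m <- do.call(rbind, lapply(hists, function(h) h@fractions))
  ref <- hists[[1L]]
  mids <- (ref@edges[-1L] + ref@edges[-length(ref@edges)]) / 2
  df <- data.frame(bin = seq_along(mids), mid = mids,
                   value = colMeans(m),
                   se = apply(m, 2L, stats::sd) / sqrt(nrow(m)))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_col(fill = "#762A83", width = 0.85) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.2, linewidth = 0.3) +
    ggplot2::labs(x = "longitudinal bin", y = "occupancy fraction") +
    ggplot2::theme_classic()
  if (length(ref@foodBins))
    g <- g + ggplot2::annotate("text", x = as.numeric(ref@foodBins),
                               y = max(df$value + df$se) * 1.05,
                               label = names(ref@foodBins), size = 3)
  g
}

#' Temporal position trace along the chamber long axis
#'
#' Thin per-fly lines and a thick group mean of the long-axis coordinate
#' over time, light schedule shaded behind.
#'
#' @param traces list of [PositionSeries-class] on one grid.
#' @param geom a [ChamberGeometry-class] (selects the long axis).
#' @param schedule optional [LightSchedule-class].
#' @return A ggplot object.
#' @export
plotPositionTrace <- function(traces, geom, schedule = NULL) {
  axis <- function(tr) if (geom@longAxis == "horizontal") tr@x else tr@y
  per <- do.call(rbind, lapply(traces, function(tr)
    data.frame(fly_id = tr@flyId, t = tr@times, v = axis(tr))))
  grp <- groupPosition(traces)
  gdf <- data.frame(t = grp@times, v = axis(grp))
  ggplot2::ggplot() +
    .phaseLayer(schedule) +
    ggplot2::geom_line(data = per,
      ggplot2::aes(x = .data$t / 3600, y = .data$v, group = .data$fly_id),
      linewidth = 0.2, alpha = 0.35, colour = "grey30") +
    ggplot2::geom_line(data = gdf,
      ggplot2::aes(x = .data$t / 3600, y = .data$v),
      linewidth = 0.9, colour = "#762A83") +
    ggplot2::labs(x = "time (h)", y = "long-axis position (px)") +
    ggplot2::theme_classic()
}
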