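#' Read a pose-tracking CSV (single-animal DeepLabCut dialect)
#'
#' Parses the three-header-row CSV produced by single-animal pose tracking:
#' row 1 \code{scorer}, row 2 \code{bodyparts}, row 3 \code{coords} with
#' \code{x,y,likelihood}, then one data row per frame whose first column is
#' the integer frame index. Exactly one bodypart is supported. Rows with
#' low likelihood are kept as-is; confidence filtering happens downstream
#' in the cleaning step (see [flagOutOfBounds()]). Gaps in the frame index
#' are permitted and treated as missing detections; empty or \code{NA}
#' position cells are read as missing.
#'
#' @param path file path.
#' @param fps frames per second; the dialect has no fps field, so this
#'   comes from the experiment configuration (default 5).
#' @param flyId,chamberId labels; default to the file name.
#' @return A [TrackingSeries-class].
#' @export
readTrackingCsv <- function(path, fps = 5, flyId = NULL, chamberId = NULL) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  id <- sub("\\.csv$", "", basename(path))
  if (is.null(flyId)) flyId <- id
  if (is.null(chamberId)) chamberId <- id
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("format error: expected 3 header rows (scorer/bodyparts/coords), ",
         "got ", length(lines), " lines")
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1L]])
  if (length(hdr[[1L]]) < 1L || hdr[[1L]][1L] != "scorer")
    stop("format error in header row 1: first field must be 'scorer'")
  if (length(hdr[[2L]]) < 1L || hdr[[2L]][1L] != "bodyparts")
    stop("format error in header row 2: first field must be 'bodyparts'")
  if (length(hdr[[3L]]) < 1L || hdr[[3L]][1L] != "coords")
    stop("format error in header row 3: first field must be 'coords'")
  parts <- unique(hdr[[2L]][-1L])
  if (length(parts) != 1L)
    stop("unsupported layout: expected exactly one bodypart, found ",
         length(parts), " (", paste(parts, collapse = ", "), ")")
  if (!identical(hdr[[3L]][-1L], c("x", "y", "likelihood")))
    stop("format error in header row 3: coords must be x,y,likelihood")
  if (length(lines) == 3L || !any(nzchar(lines[-(1:3)]))) {
    warning("empty data section in ", path)
    return(TrackingSeries(integer(), numeric(), numeric(), numeric(),
                          fps = fps, flyId = flyId, chamberId = chamberId))
  }
  m <- tryCatch(
    scan(path, what = list("", "", "", ""), sep = ",", skip = 3,
         quiet = TRUE, multi.line = FALSE),
    error = function(e)
      stop("parse error in data section: ", conditionMessage(e),
           call. = FALSE))
  num <- function(col, name) {
    v <- m[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & !is.na(v) & !(v %in% c("", "NA", "nan", "NaN"))
    if (any(bad))
      stop("parse error at data row ", which(bad)[1L], ": non-numeric ",
           name, " value '", v[which(bad)[1L]], "'")
    out
  }
  frame <- num(1L, "frame index")
  if (any(is.na(frame)) || any(frame != floor(frame)))
    stop("parse error: frame index column must be integer")
  TrackingSeries(
    frame = frame, x = num(2L, "x"), y = num(3L, "y"),
    likelihood = num(4L, "likelihood"),
    fps = fps, flyId = flyId, chamberId = chamberId
  )
}

#' Write a tracking series in the same CSV dialect
#'
#' Inverse of [readTrackingCsv()] up to float formatting (12 significant
#' digits): \code{readTrackingCsv(writeTrackingCsv(s))} reproduces \code{s}.
#'
#' @param series a [TrackingSeries-class].
#' @param path output file path.
#' @param scorer,bodypart strings for the header rows.
#' @return \code{path}, invisibly.
#' @export
writeTrackingCsv <- function(series, path, scorer = "flyVAM",
                             bodypart = "fly") {
  fmt <- function(v) {
    out <- sprintf("%.12g", v)
    out[is.na(v)] <- "NA"
    out
  }
  lines <- c(
    paste(c("scorer", rep(scorer, 3L)), collapse = ","),
    paste(c("bodyparts", rep(bodypart, 3L)), collapse = ","),
    "coords,x,y,likelihood"
  )
  if (length(series@frame))
    lines <- c(lines, paste(series@frame, fmt(series@x), fmt(series@y),
                            fmt(series@likelihood), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Light-phase lookup and Zeitgeber time
#'
#' \code{phaseAt} returns the phase kind covering each time (phase
#' intervals are half-open \code{[start, end)}); \code{ztOf} converts
#' experiment time to Zeitgeber hours, \code{((t - zt0) / 3600) mod 24},
#' periodic with period 24 h. \code{isDayPhase} maps phase kinds to a
#' day/night logical (subjective day counts as day).
#'
#' @param schedule a [LightSchedule-class].
#' @param t experiment time(s) in seconds (vectorised).
#' @return \code{phaseAt}: character vector of phase kinds; \code{ztOf}:
#'   numeric hours in \code{[0, 24)}.
#' @export
phaseAt <- function(schedule, t) {
  p <- schedule@phases
  i <- findInterval(t, p$start)
  bad <- i < 1L | t >= p$end[pmax(i, 1L)]
  if (any(bad))
    stop("time ", t[which(bad)[1L]],
         " s is outside the schedule coverage [", p$start[1L], ", ",
         p$end[nrow(p)], ") s")
  p$kind[i]
}

#' @rdname phaseAt
#' @export
ztOf <- function(schedule, t) {
  ((t - schedule@zt0) / 3600) %% 24
}

#' @param kind character vector of phase kinds.
#' @rdname phaseAt
#' @export
isDayPhase <- function(kind) kind %in% .DAY_KINDS

#' Read / write the experiment configuration
#'
#' The configuration is one YAML file holding arena geometry, per-chamber
#' overrides, the frame rate and the light schedule. Keys:
#' \preformatted{
#' frame:  {width, height}                  # px
#' grid:   {rows, cols, margin_x, margin_y, gap_x, gap_y}
#' fps: 5
#' mm_per_px: 0.2                           # optional
#' likelihood_floor: 0.9
#' schedule:
#'   zt0: 0                                 # s, lights-on reference
#'   start: 0                               # s, first phase start
#'   entries: [{kind: L, hours: 12}, {kind: D, hours: 12}, ...]
#' chambers:                                # optional per-chamber geometry
#'   - {id, x_min, y_min, x_max, y_max, long_axis, midline,
#'      food_regions: [{label, start, end}]}
#' groups: {virgin: [chamber_01, ...], ...} # optional group labels
#' }
#' The file round-trips losslessly through read/write.
#'
#' @param path YAML file path.
#' @return \code{readExperimentConfig}: the configuration as a named list.
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @param config a configuration list.
#' @rdname readExperimentConfig
#' @export
writeExperimentConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readExperimentConfig
#' @export
configSchedule <- function(config) {
  sc <- config$schedule
  if (is.null(sc)) stop("config has no 'schedule' section")
  LightSchedule(
    kinds = vapply(sc$entries, `[[`, character(1), "kind"),
    hours = vapply(sc$entries, `[[`, numeric(1), "hours"),
    zt0 = if (is.null(sc$zt0)) 0 else sc$zt0,
    start = if (is.null(sc$start)) 0 else sc$start
  )
}

#' @rdname readExperimentConfig
#' @export
configLayout <- function(config) {
  if (is.null(config$frame) || is.null(config$grid))
    stop("config needs 'frame' and 'grid' sections for the crop grid")
  g <- config$grid
  pick <- function(x, d = 0) if (is.null(x)) d else x
  ArenaLayout(config$frame$width, config$frame$height,
              rows = g$rows, cols = g$cols,
              marginX = pick(g$margin_x), marginY = pick(g$margin_y),
              gapX = pick(g$gap_x), gapY = pick(g$gap_y))
}

#' @param id chamber id to look up.
#' @rdname readExperimentConfig
#' @export
configChamber <- function(config, id) {
  for (ch in config$chambers) {
    if (identical(ch$id, id)) {
      fr <- NULL
      if (!is.null(ch$food_regions)) {
        fr <- data.frame(
          label = vapply(ch$food_regions, `[[`, character(1), "label"),
          start = vapply(ch$food_regions, `[[`, numeric(1), "start"),
          end = vapply(ch$food_regions, `[[`, numeric(1), "end"),
          stringsAsFactors = FALSE
        )
      }
      return(ChamberGeometry(
        xMin = ch$x_min, yMin = ch$y_min, xMax = ch$x_max, yMax = ch$y_max,
        longAxis = ch$long_axis, midline = ch$midline, foodRegions = fr,
        mmPerPx = if (is.null(config$mm_per_px)) NA_real_ else config$mm_per_px
      ))
    }
  }
  NULL
}
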