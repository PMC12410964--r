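`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a binned series for export
#'
#' @param binned a [BinnedSeries-class].
#' @param schedule optional [LightSchedule-class] to annotate ZT and phase
#'   (bins outside the schedule get NA).
#' @return data.frame: fly_id, metric, bin_start, zt, phase, value.
#' @export
binnedTidy <- function(binned, schedule = NULL) {
  zt <- rep(NA_real_, length(binned@binStarts))
  phase <- rep(NA_character_, length(binned@binStarts))
  if (!is.null(schedule)) {
    zt <- ztOf(schedule, binned@binStarts)
    p <- schedule@phases
    covered <- binned@binStarts >= p$start[1L] &
      binned@binStarts < p$end[nrow(p)]
    if (any(covered))
      phase[covered] <- phaseAt(schedule, binned@binStarts[covered])
  }
  data.frame(fly_id = binned@flyId, metric = binned@metric,
             bin_start = binned@binStarts, zt = zt, phase = phase,
             value = binned@values, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the three-step protocol on a set of tracking CSVs: clean
#' each series against its configured (or inferred) chamber geometry, then
#' compute binned distance, virtual beam-crossing counts and sleep
#' minutes, and — when the configuration defines exactly two groups — the
#' day/night Welch comparison and the hourly Mann-Whitney comparison with
#' FDR control. A failure on one chamber is logged and the remaining
#' chambers are still analysed. Outputs are deterministic for fixed
#' inputs and configuration: every figure's numbers are also written as
#' CSV, and a JSON manifest records the configuration hash, inputs,
#' parameters and per-chamber status.
#'
#' @param configPath path to the experiment configuration YAML (see
#'   [readExperimentConfig()]).
#' @param inputs character vector of tracking CSV paths, or one directory
#'   to scan for \code{*.csv}.
#' @param outDir output directory.
#' @param binMinutes bin width for the metric CSVs (default 10).
#' @param nFullDays days used for average-day profiles (default 2).
#' @param makePlots write figure PDFs (default FALSE).
#' @return Invisibly, a list: \code{status} data.frame (file, ok,
#'   message), \code{metrics}, \code{comparisons}, \code{manifestPath}.
#' @export
runPipeline <- function(configPath, inputs, outDir, binMinutes = 10,
                        nFullDays = 2, makePlots = FALSE) {
  cfg <- readExperimentConfig(configPath)
  if (length(inputs) == 1L && dir.exists(inputs))
    inputs <- sort(list.files(inputs, pattern = "\\.csv$",
                              full.names = TRUE))
  inputs <- inputs[basename(inputs) != "ground_truth.csv"]
  if (!length(inputs)) stop("no input tracking CSVs found")
  dir.create(file.path(outDir, "cleaned"), showWarnings = FALSE,
             recursive = TRUE)
  fpsVal <- cfg$fps %||% 5
  floor <- cfg$likelihood_floor %||% 0.9
  schedule <- if (!is.null(cfg$schedule)) configSchedule(cfg) else NULL

  status <- list(); tidy <- list(); reports <- list()
  perFly <- list()
  for (f in inputs) {
    id <- sub("\\.csv$", "", basename(f))
    res <- tryCatch({
      series <- readTrackingCsv(f, fps = fpsVal)
      geom <- configChamber(cfg, id)
      cleaned <- cleanSeries(series, geom = geom, likelihoodFloor = floor)
      writeTrackingCsv(cleaned@series,
                       file.path(outDir, "cleaned", basename(f)))
      act <- binActivity(cleaned, binMinutes)
      ev <- virtualDam(cleaned)
      crs <- binCrossings(ev, binMinutes)
      crs@flyId <- id
      slp <- sleepBinned(sleepBouts(ev), binMinutes)
      slp@flyId <- id
      perFly[[id]] <- list(cleaned = cleaned, activity = act,
                            crossings = crs, sleep = slp)
      tidy[[id]] <- rbind(binnedTidy(act, schedule),
                           binnedTidy(crs, schedule),
                           binnedTidy(slp, schedule))
      reports[[id]] <- cleaningReport(cleaned)
      message(sprintf("[flyVAM] clean+analyse %-20s frames=%d flagged=%d",
                      id, nFrames(cleaned),
                      sum(interpolatedMask(cleaned))))
      list(ok = TRUE, message = "ok")
    }, error = function(e) {
      message(sprintf("[flyVAM] FAILED %-20s %s", id, conditionMessage(e)))
      list(ok = FALSE, message = conditionMessage(e))
    })
    status[[f]] <- data.frame(file = f, ok = res$ok, message = res$message,
                              stringsAsFactors = FALSE)
  }
  status <- do.call(rbind, status)
  rownames(status) <- NULL
  metrics <- do.call(rbind, tidy)
  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, reports),
                   file.path(outDir, "cleaning_report.csv"),
                   row.names = FALSE)

  comparisons <- NULL
  groups <- cfg$groups
  if (!is.null(groups) && length(groups) == 2L && !is.null(schedule)) {
    comparisons <- tryCatch(
      .compareGroups(perFly, groups, schedule, outDir, nFullDays,
                     makePlots),
      error = function(e) {
        message("[flyVAM] group comparison skipped: ", conditionMessage(e))
        NULL
      })
  }
  if (makePlots) .pipelinePlots(perFly, groups, schedule, outDir)

  manifest <- list(
    package = "flyVAM",
    version = as.character(utils::packageVersion("flyVAM")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = list(path = configPath,
                  md5 = unname(tools::md5sum(configPath))),
    inputs = basename(inputs),
    parameters = list(bin_minutes = binMinutes, fps = fpsVal,
                      likelihood_floor = floor, n_full_days = nFullDays),
    status = status
  )
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(status = status, metrics = metrics,
                 comparisons = comparisons, manifestPath = manifestPath))
}

.compareGroups <- function(perFly, groups, schedule, outDir, nFullDays,
                           makePlots) {
  gnames <- names(groups)
  pick <- function(g) {
    ids <- intersect(unlist(groups[[g]]), names(perFly))
    lapply(ids, function(id) perFly[[id]])
  }
  a <- pick(gnames[1L]); b <- pick(gnames[2L])
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 analysed flies per group")
  actOf <- function(lst) lapply(lst, `[[`, "activity")
  tabA <- dayNightTable(actOf(a), schedule)
  tabB <- dayNightTable(actOf(b), schedule)
  dayNight <- compareTotals(tabA, tabB)
  dayNight$group_a <- gnames[1L]; dayNight$group_b <- gnames[2L]
  utils::write.csv(dayNight, file.path(outDir, "day_night_comparison.csv"),
                   row.names = FALSE)
  hourly <- NULL
  profiles <- function(lst) lapply(lst, function(x) {
    hb <- binActivity(x$cleaned, 60)
    hb@flyId <- x$activity@flyId
    averageDay(hb, schedule, nFullDays)
  })
  hourly <- tryCatch({
    h <- compareHourly(profileMatrix(profiles(a)),
                       profileMatrix(profiles(b)))
    h$group_a <- gnames[1L]; h$group_b <- gnames[2L]
    utils::write.csv(h, file.path(outDir, "hourly_comparison.csv"),
                     row.names = FALSE)
    h
  }, error = function(e) {
    message("[flyVAM] hourly comparison skipped: ", conditionMessage(e))
    NULL
  })
  list(day_night = dayNight, hourly = hourly,
       totals = list(tabA, tabB))
}

.pipelinePlots <- function(perFly, groups, schedule, outDir) {
  dir.create(file.path(outDir, "plots"), showWarnings = FALSE)
  acts <- lapply(perFly, `[[`, "activity")
  if (length(acts) < 1L) return(invisible())
  grp <- tryCatch(groupMean(acts), error = function(e) NULL)
  if (!is.null(grp)) {
    p <- plotGroupTrace(acts, schedule)
    ggplot2::ggsave(file.path(outDir, "plots", "activity_trace.pdf"), p,
                    width = 9, height = 4)
  }
  invisible()
}
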