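#' @useDynLib flyVAM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Build a simulation configuration
#'
#' Defaults emulate a virgin female Drosophila melanogaster in the
#' locomotion chamber under a 12:12 LD cycle at 5 fps: a mostly-resting
#' walker that starts move bouts about twice as often in the light phase
#' as in the dark, with a six-fold startle boost for 5 min after each
#' light transition, a half-depth midday siesta (ZT4-8), no food
#' attraction, and 0.5% of frames reported as misdetections outside the
#' chamber at low likelihood.
#'
#' @param durationS recording duration (s); default 3 days.
#' @param fps frames per second (default 5).
#' @param chamber a [ChamberGeometry-class]; default [locomotionChamber()].
#' @param schedule a [LightSchedule-class] covering the duration; default
#'   a 12:12 LD cycle.
#' @param dayRate,nightRate per-frame rest-to-move entry probabilities.
#' @param moveExitRate per-frame move-to-rest probability (mean move-bout
#'   length = 1/rate frames).
#' @param startleBoost,startleDurationS entry-rate multiplier and window
#'   after each L <-> D transition.
#' @param siestaDepth,siestaStartZT,siestaEndZT midday entry-rate factor
#'   and ZT window; depth 1 disables.
#' @param foodBias per-move-frame probability of redrawing the heading
#'   toward the food target.
#' @param biasFood label of the food region to bias toward (default: the
#'   first region).
#' @param stepScale half-normal step scale (px/frame).
#' @param turnSd heading noise (radians/frame).
#' @param misdetectRate per-frame misdetection probability.
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(durationS = 3 * 86400, fps = 5,
                             chamber = locomotionChamber(),
                             schedule = NULL,
                             dayRate = 0.02, nightRate = 0.01,
                             moveExitRate = 0.2,
                             startleBoost = 6, startleDurationS = 300,
                             siestaDepth = 0.5, siestaStartZT = 4,
                             siestaEndZT = 8,
                             foodBias = 0, biasFood = "",
                             stepScale = 3, turnSd = 0.6,
                             misdetectRate = 0.005, seed = 1L) {
  if (is.null(schedule)) schedule <- ldSchedule(ceiling(durationS / 86400))
  new("SimulationConfig",
    fps = as.numeric(fps), durationS = as.numeric(durationS),
    chamber = chamber, schedule = schedule,
    dayRate = as.numeric(dayRate), nightRate = as.numeric(nightRate),
    moveExitRate = as.numeric(moveExitRate),
    startleBoost = as.numeric(startleBoost),
    startleDurationS = as.numeric(startleDurationS),
    siestaDepth = as.numeric(siestaDepth),
    siestaStartZT = as.numeric(siestaStartZT),
    siestaEndZT = as.numeric(siestaEndZT),
    foodBias = as.numeric(foodBias), biasFood = biasFood,
    stepScale = as.numeric(stepScale), turnSd = as.numeric(turnSd),
    misdetectRate = as.numeric(misdetectRate), seed = as.integer(seed)
  )
}

#' Per-frame move-entry rates of a simulation
#'
#' The circadian-modulated rest-to-move entry probability
#' \code{r(t) = base(phase) * startle(t) * siesta(t)}, clamped to 1.
#' Startle applies for \code{startleDurationS} after each transition
#' between an L and a D phase (subjective transitions in DD do not
#' startle); siesta applies within the ZT window.
#'
#' @param config a [SimulationConfig-class].
#' @return Numeric vector, one rate per frame.
#' @export
entryRates <- function(config) {
  n <- round(config@durationS * config@fps)
  t <- (seq_len(n) - 1) / config@fps
  kind <- phaseAt(config@schedule, t)
  r <- ifelse(isDayPhase(kind), config@dayRate, config@nightRate)
  p <- config@schedule@phases
  if (config@startleBoost > 1 && nrow(p) > 1) {
    boundary <- p$start[-1L]
    kindsAt <- cbind(p$kind[-nrow(p)], p$kind[-1L])
    ld <- kindsAt[, 1L] %in% c("L", "D") & kindsAt[, 2L] %in% c("L", "D") &
      kindsAt[, 1L] != kindsAt[, 2L]
    for (tb in boundary[ld]) {
      w <- t >= tb & t < tb + config@startleDurationS
      r[w] <- r[w] * config@startleBoost
    }
  }
  if (config@siestaDepth < 1) {
    zt <- ztOf(config@schedule, t)
    w <- zt >= config@siestaStartZT & zt < config@siestaEndZT
    r[w] <- r[w] * config@siestaDepth
  }
  pmin(r, 1)
}

#' Simulate one fly
#'
#' Runs the two-state Markov walker (rest: position fixed; move: noisy
#' heading, half-normal steps, reflecting walls), then injects
#' misdetections: with probability \code{misdetectRate} per frame the
#' reported position is replaced by a point in a 20 px band outside a
#' uniformly chosen chamber wall, with likelihood drawn from U(0, 0.5);
#' clean frames report the true position with likelihood U(0.95, 1).
#' A fixed seed gives bit-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @param flyId,chamberId labels for the returned series.
#' @return list with elements \code{series} (a [TrackingSeries-class])
#'   and \code{truth} (a [GroundTruth-class]).
#' @export
simulateFly <- function(config, flyId = "sim_fly", chamberId = flyId) {
  validObject(config)
  rates <- entryRates(config)
  n <- length(rates)
  ch <- config@chamber
  target <- .foodTarget(config)
  set.seed(config@seed)
  walk <- .walkCpp(rates, config@moveExitRate, config@stepScale,
                   config@turnSd, config@foodBias,
                   ch@xMin, ch@xMax, ch@yMin, ch@yMax,
                   target[1L], target[2L])
  mis <- stats::runif(n) < config@misdetectRate
  x <- walk$x; y <- walk$y
  lik <- stats::runif(n, 0.95, 1)
  nm <- sum(mis)
  if (nm) {
    side <- sample.int(4L, nm, replace = TRUE)
    off <- stats::runif(nm, 1e-3, 20)
    along <- stats::runif(nm)
    mx <- x[mis]; my <- y[mis]
    mx[side == 1L] <- ch@xMin - off[side == 1L]
    mx[side == 2L] <- ch@xMax + off[side == 2L]
    my[side <= 2L] <- ch@yMin +
      along[side <= 2L] * (ch@yMax - ch@yMin)
    my[side == 3L] <- ch@yMin - off[side == 3L]
    my[side == 4L] <- ch@yMax + off[side == 4L]
    mx[side >= 3L] <- ch@xMin +
      along[side >= 3L] * (ch@xMax - ch@xMin)
    x[mis] <- mx; y[mis] <- my
    lik[mis] <- stats::runif(nm, 0, 0.5)
  }
  series <- TrackingSeries(seq_len(n) - 1L, x, y, lik, fps = config@fps,
                           flyId = flyId, chamberId = chamberId)
  truth <- new("GroundTruth", trueX = walk$x, trueY = walk$y,
               state = walk$state, misdetected = mis,
               expectedRates = list(day = config@dayRate,
                                    night = config@nightRate))
  list(series = series, truth = truth)
}

.foodTarget <- function(config) {
  ch <- config@chamber
  fr <- ch@foodRegions
  if (config@foodBias > 0 && !nrow(fr))
    stop("foodBias > 0 requires at least one food region in the chamber")
  if (!nrow(fr)) return(c((ch@xMin + ch@xMax) / 2, (ch@yMin + ch@yMax) / 2))
  k <- if (nzchar(config@biasFood)) match(config@biasFood, fr$label) else 1L
  if (is.na(k)) stop("no food region labelled '", config@biasFood, "'")
  centreAlong <- (fr$start[k] + fr$end[k]) / 2
  if (ch@longAxis == "horizontal")
    c(centreAlong, (ch@yMin + ch@yMax) / 2)
  else
    c((ch@xMin + ch@xMax) / 2, centreAlong)
}

#' Simulate a grouped experiment
#'
#' Simulates cohorts of independent flies. Each group inherits the
#' template configuration with its overrides applied (any
#' [SimulationConfig()] argument given by name). Per-fly seeds derive
#' deterministically from the master seed:
#' \code{seed_i = (seed * 1000 + i) mod 2147483647} with \code{i} the
#' global fly index, so the whole experiment reproduces from one integer.
#'
#' @param config template [SimulationConfig-class]; its \code{seed} slot
#'   is the master seed.
#' @param groups named list: each element a list with \code{n} (number of
#'   flies) plus configuration overrides, e.g.
#'   \code{list(virgin = list(n = 16), mated = list(n = 16, nightRate = 0.04))}.
#' @return list with \code{flies} (named list of per-group lists of
#'   \code{simulateFly} results) and \code{summary} (data.frame of
#'   per-fly ground truth: true day/night distance, misdetection
#'   fraction, occupancy fraction of the bias-food region).
#' @export
simulateExperiment <- function(config, groups) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  flyIdx <- 0L
  flies <- list()
  rows <- list()
  for (g in names(groups)) {
    spec <- groups[[g]]
    nFlies <- spec$n
    if (is.null(nFlies) || nFlies < 1L)
      stop("group '", g, "' needs n >= 1")
    overrides <- spec[setdiff(names(spec), "n")]
    flies[[g]] <- vector("list", nFlies)
    for (j in seq_len(nFlies)) {
      flyIdx <- flyIdx + 1L
      cfg <- .applyOverrides(config, overrides)
      cfg@seed <- as.integer((as.numeric(config@seed) * 1000 + flyIdx) %%
                               2147483647)
      id <- sprintf("%s_%02d", g, j)
      sim <- simulateFly(cfg, flyId = id)
      flies[[g]][[j]] <- sim
      rows[[flyIdx]] <- .truthSummary(sim, cfg, g, id)
    }
  }
  list(flies = flies, summary = do.call(rbind, rows))
}

.applyOverrides <- function(config, overrides) {
  cfg <- config
  for (nm in names(overrides)) {
    if (!nm %in% slotNames(cfg))
      stop("unknown simulation parameter '", nm, "'")
    value <- overrides[[nm]]
    if (is(slot(cfg, nm), "numeric")) value <- as.numeric(value)
    slot(cfg, nm) <- value
  }
  validObject(cfg)
  cfg
}

.truthSummary <- function(sim, cfg, group, id) {
  tr <- sim$truth
  n <- length(tr@trueX)
  t <- (seq_len(n) - 1) / cfg@fps
  d <- sqrt(diff(tr@trueX)^2 + diff(tr@trueY)^2)
  day <- isDayPhase(phaseAt(cfg@schedule, t))
  ch <- cfg@chamber
  fr <- ch@foodRegions
  foodFrac <- NA_real_
  if (nrow(fr)) {
    k <- if (nzchar(cfg@biasFood)) match(cfg@biasFood, fr$label) else 1L
    v <- if (ch@longAxis == "horizontal") tr@trueX else tr@trueY
    foodFrac <- mean(v >= fr$start[k] & v < fr$end[k])
  }
  data.frame(
    group = group, fly_id = id, seed = cfg@seed,
    true_day_distance = sum(d[day[-n]]),
    true_night_distance = sum(d[!day[-n]]),
    misdetect_fraction = mean(tr@misdetected),
    food_fraction = foodFrac,
    stringsAsFactors = FALSE
  )
}

#' Write a simulated experiment to disk
#'
#' Writes one tracking CSV per fly (same dialect as [readTrackingCsv()]),
#' the experiment configuration YAML and the ground-truth summary CSV.
#'
#' @param experiment result of [simulateExperiment()].
#' @param config the template [SimulationConfig-class] used.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeExperiment <- function(experiment, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(experiment$flies)) {
    for (sim in experiment$flies[[g]]) {
      writeTrackingCsv(sim$series,
                       file.path(dir, paste0(sim$series@flyId, ".csv")))
    }
  }
  ch <- config@chamber
  p <- config@schedule@phases
  cfg <- list(
    fps = config@fps,
    mm_per_px = if (is.na(ch@mmPerPx)) NULL else ch@mmPerPx,
    schedule = list(
      zt0 = config@schedule@zt0, start = p$start[1L],
      entries = lapply(seq_len(nrow(p)), function(k)
        list(kind = p$kind[k], hours = (p$end[k] - p$start[k]) / 3600))
    ),
    chambers = list(list(
      id = "simulated", x_min = ch@xMin, y_min = ch@yMin,
      x_max = ch@xMax, y_max = ch@yMax, long_axis = ch@longAxis,
      midline = ch@midline,
      food_regions = if (nrow(ch@foodRegions))
        lapply(seq_len(nrow(ch@foodRegions)), function(k)
          list(label = ch@foodRegions$label[k],
               start = ch@foodRegions$start[k],
               end = ch@foodRegions$end[k]))
      else NULL
    )),
    groups = lapply(experiment$flies, function(sims)
      vapply(sims, function(s) s$series@flyId, character(1)))
  )
  writeExperimentConfig(cfg, file.path(dir, "config.yaml"))
  utils::write.csv(experiment$summary, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
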