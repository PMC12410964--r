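# shared fixture builders; everything is generated in code at test time

# random confined walk inside geom with a fraction of frames replaced by
# out-of-chamber detections at low likelihood
randomWalkSeries <- function(n, geom = ChamberGeometry(0, 0, 100, 50),
                             oobFraction = 0, fps = 5, flyId = "fly") {
  w <- geom@xMax - geom@xMin
  h <- geom@yMax - geom@yMin
  x <- geom@xMin + w * (0.5 + 0.4 * sin(cumsum(rnorm(n, sd = 0.3))))
  y <- geom@yMin + h * (0.5 + 0.4 * sin(cumsum(rnorm(n, sd = 0.3)) + 1))
  lik <- runif(n, 0.95, 1)
  if (oobFraction > 0 && n > 1) {
    nOob <- max(1L, round(n * oobFraction))
    at <- sample(n, nOob)
    side <- sample(4L, nOob, replace = TRUE)
    x[at[side == 1L]] <- geom@xMin - runif(sum(side == 1L), 1, 20)
    x[at[side == 2L]] <- geom@xMax + runif(sum(side == 2L), 1, 20)
    y[at[side == 3L]] <- geom@yMin - runif(sum(side == 3L), 1, 20)
    y[at[side == 4L]] <- geom@yMax + runif(sum(side == 4L), 1, 20)
    lik[at] <- runif(nOob, 0, 0.5)
  }
  TrackingSeries(seq_len(n) - 1L, x, y, lik, fps = fps, flyId = flyId)
}

# wrap an in-bounds series as a CleanedSeries without touching it
asCleaned <- function(series, geom) {
  new("CleanedSeries", series = series,
      interpolated = rep(FALSE, length(series@frame)),
      geometryUsed = geom)
}

# CleanedSeries straight from coordinate vectors
cleanedFromXY <- function(x, y, geom, fps = 5, frame = seq_along(x) - 1L) {
  asCleaned(TrackingSeries(frame, x, y, rep(1, length(x)), fps = fps), geom)
}

# brute-force flanking-scan interpolation reference (linear scan per
# masked index, midpoint rule, constant extrapolation at the edges)
bruteInterpolate <- function(x, y, mask) {
  n <- length(x)
  ox <- x; oy <- y
  for (i in which(mask)) {
    p <- i; while (p >= 1L && mask[p]) p <- p - 1L
    q <- i; while (q <= n && mask[q]) q <- q + 1L
    if (p < 1L && q > n) stop("all masked")
    if (p < 1L) { x[i] <- ox[q]; y[i] <- oy[q] }
    else if (q > n) { x[i] <- ox[p]; y[i] <- oy[p] }
    else { x[i] <- (ox[p] + ox[q]) / 2; y[i] <- (oy[p] + oy[q]) / 2 }
  }
  list(x = x, y = y)
}

# brute-force held-side crossing reference with the hysteresis tie rule
bruteCrossings <- function(v, midline) {
  idx <- integer()
  prev <- NA_integer_
  for (i in seq_along(v)) {
    s <- if (v[i] < midline) -1L else if (v[i] > midline) 1L else
      if (is.na(prev)) -1L else prev
    if (!is.na(prev) && s != prev) idx <- c(idx, i)
    prev <- s
  }
  idx
}

# brute-force maximal-gap sleep scan over an event train
bruteSleepBouts <- function(times, spanStart, spanEnd, threshold = 300) {
  bounds <- c(spanStart, times, spanEnd)
  out <- NULL
  for (k in seq_len(length(bounds) - 1L)) {
    if (bounds[k + 1L] - bounds[k] >= threshold)
      out <- rbind(out, c(bounds[k], bounds[k + 1L]))
  }
  out
}

crossingEvents <- function(frames, fps = 5, spanStart = 0, spanEnd) {
  new("CrossingEvents", frame = as.integer(frames), fps = fps,
      spanStart = spanStart, spanEnd = spanEnd)
}

writeTrackingFixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

dlcHeader <- c("scorer,net,net,net", "bodyparts,fly,fly,fly",
               "coords,x,y,likelihood")
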