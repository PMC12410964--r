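test_that("frame distances are Euclidean and gap-spanning", {
  geom <- ChamberGeometry(0, 0, 100, 50)
  still <- cleanedFromXY(rep(10, 50), rep(10, 50), geom)
  expect_equal(frameDistances(still), rep(0, 49))
  tri <- cleanedFromXY(c(0, 3), c(0, 4), geom)
  expect_equal(frameDistances(tri), 5)
  one <- cleanedFromXY(5, 5, geom)
  expect_length(frameDistances(one), 0L)
  # 1000-step random walk equals the brute-force hypotenuse sum
  set.seed(12)
  x <- cumsum(rnorm(1000)); x <- 50 + 40 * sin(x / max(abs(x)) / 2)
  y <- 25 + runif(1000, -20, 20)
  cl <- cleanedFromXY(x, y, geom)
  oracle <- vapply(1:999, function(i)
    sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2), numeric(1))
  expect_equal(frameDistances(cl), oracle)
})

test_that("binned distance is exact for constant speed and conserved", {
  geom <- ChamberGeometry(0, 0, 4000, 50)
  # 1 px/frame zig-zag at 5 fps: every complete 10-min bin sums 3000 px
  n <- 5 * 60 * 25                      # 25 min of recording
  tri <- abs(((seq_len(n) - 1) %% 6000) - 3000) + 100
  cl <- cleanedFromXY(tri, rep(10, n), geom)
  b <- binActivity(cl, 10)
  expect_equal(length(binValues(b)), 2L)      # trailing 5 min dropped
  expect_equal(binValues(b), c(3000, 3000))
  expect_equal(binStarts(b), c(0, 600))

  # conservation: bin sums equal the distances assigned to complete bins
  set.seed(13)
  cl2 <- asCleaned(randomWalkSeries(7000, geom), geom)
  d <- frameDistances(cl2)
  for (bm in c(1, 10)) {
    b2 <- binActivity(cl2, bm)
    nBins <- length(binValues(b2))
    t <- (cl2@series@frame[-7000]) / 5
    keep <- floor(t / (bm * 60)) < nBins
    expect_equal(sum(binValues(b2)), sum(d[keep]))
  }
})

test_that("binning matches a brute-force assignment with frame gaps", {
  set.seed(14)
  geom <- ChamberGeometry(0, 0, 100, 50)
  frame <- sort(sample(0:29999, 9000))
  s <- TrackingSeries(frame, runif(9000, 0, 100), runif(9000, 0, 50),
                      rep(1, 9000), fps = 5)
  cl <- asCleaned(s, geom)
  b <- binActivity(cl, 30, tStart = 0)
  d <- frameDistances(cl)
  t <- frame[-length(frame)] / 5
  nBins <- floor((frame[length(frame)] + 1) / 5 / 1800)
  oracle <- vapply(seq_len(nBins), function(k)
    sum(d[t >= (k - 1) * 1800 & t < k * 1800]), numeric(1))
  expect_equal(binValues(b), oracle)
})

test_that("group mean and median aggregate per bin", {
  mk <- function(v, id) BinnedSeries(v, 600, c(0, 600, 1200), flyId = id)
  one <- groupMean(list(mk(c(1, 2, 3), "a")))
  expect_equal(binValues(one), c(1, 2, 3))
  two <- groupMean(list(mk(c(0, 0, 0), "a"), mk(c(10, 10, 10), "b")))
  expect_equal(binValues(two), c(5, 5, 5))
  expect_equal(binValues(groupMedian(list(mk(c(0, 0, 0), "a"),
                                          mk(c(10, 10, 10), "b")))),
               c(5, 5, 5))
  set.seed(15)
  vals <- matrix(rexp(16 * 3), 16)
  flies <- lapply(1:16, function(i) mk(vals[i, ], paste0("f", i)))
  expect_equal(binValues(groupMean(flies)), colMeans(vals))
  expect_equal(binValues(groupMedian(flies)), apply(vals, 2, median))
  expect_equal(binValues(groupMean(flies, exclude = "f1")),
               colMeans(vals[-1, ]))
  bad <- BinnedSeries(1:2, 600, c(0, 600), flyId = "g")
  expect_error(groupMean(list(mk(c(1, 2, 3), "a"), bad)), "alignment")
})

test_that("virtual beam crossings count held-side changes", {
  geom <- ChamberGeometry(0, 0, 20, 100, longAxis = "vertical",
                          midline = 10)
  cl <- cleanedFromXY(rep(5, 4), c(5, 5, 15, 15), geom)
  ev <- virtualDam(cl)
  expect_equal(eventFrames(ev), 2L)
  alt <- cleanedFromXY(rep(5, 10), rep(c(5, 15), 5), geom)
  expect_length(eventFrames(virtualDam(alt)), 9L)
  # grazing the line must not register
  graze <- cleanedFromXY(rep(5, 5), c(5, 10, 5, 10, 5), geom)
  expect_length(eventFrames(virtualDam(graze)), 0L)
  # touch-then-cross registers once, at the leaving frame
  touch <- cleanedFromXY(rep(5, 4), c(5, 10, 10, 15), geom)
  expect_equal(eventFrames(virtualDam(touch)), 3L)
})

test_that("crossing counts match brute force on random walks with ties", {
  set.seed(16)
  geom <- ChamberGeometry(0, 0, 100, 50, midline = 50)
  for (rep in 1:10) {
    n <- 5000L
    x <- pmin(pmax(round(50 + cumsum(sample(c(-3:3), n, TRUE))), 0), 99)
    cl <- cleanedFromXY(x, runif(n, 0, 50), geom)
    ev <- virtualDam(cl)
    expect_equal(eventFrames(ev), cl@series@frame[bruteCrossings(x, 50)])
    expect_lte(length(eventFrames(ev)), n - 1L)
  }
})

test_that("crossing count is invariant to reflecting the long axis", {
  set.seed(17)
  geom <- ChamberGeometry(0, 0, 100, 50, midline = 50)
  s <- randomWalkSeries(4000, geom)
  cl <- asCleaned(s, geom)
  refl <- cleanedFromXY(100 - s@x, s@y, geom)    # midline-symmetric flip
  expect_equal(length(eventFrames(virtualDam(cl))),
               length(eventFrames(virtualDam(refl))))
})

test_that("scaling positions scales distance, not crossings", {
  set.seed(18)
  geom <- ChamberGeometry(0, 0, 100, 50, midline = 50)
  s <- randomWalkSeries(2000, geom)
  cl <- asCleaned(s, geom)
  c3 <- ChamberGeometry(0, 0, 300, 150, midline = 150)
  cl3 <- cleanedFromXY(3 * s@x, 3 * s@y, c3)
  expect_equal(frameDistances(cl3), 3 * frameDistances(cl))
  expect_equal(eventFrames(virtualDam(cl3)), eventFrames(virtualDam(cl)))
})

test_that("interpolated runs add no distance and at most two crossings", {
  geom <- ChamberGeometry(0, 0, 100, 50, midline = 50)
  x <- c(20, 30, rep(-5, 6), 70, 80)
  s <- TrackingSeries(0:9, x, rep(25, 10), rep(1, 10))
  cl <- cleanSeries(s, geom = geom)
  d <- frameDistances(cl)
  expect_equal(d[3:7], rep(0, 5))                 # inside the run
  run <- which(interpolatedMask(cl))
  ev <- eventFrames(virtualDam(cl))
  expect_lte(sum(ev %in% (min(run) - 1):(max(run) + 1)), 2L)
})

test_that("crossing events bin into counts", {
  ev <- crossingEvents(integer(), spanEnd = 3600)
  expect_equal(binValues(binCrossings(ev, 10)), rep(0, 6))
  # one event per minute for an hour
  ev2 <- crossingEvents(seq(0, 3599, by = 60) * 5, spanEnd = 3600)
  expect_equal(binValues(binCrossings(ev2, 10)), rep(10, 6))
  set.seed(19)
  fr <- sort(sample(0:17999, 400))
  ev3 <- crossingEvents(fr, spanEnd = 3600)
  oracle <- as.vector(table(cut(fr / 5, seq(0, 3600, 600),
                                right = FALSE)))
  expect_equal(binValues(binCrossings(ev3, 10)), oracle)
})

test_that("the five-minute rule extracts sleep bouts", {
  ev <- crossingEvents(c(0, 360 * 5), spanEnd = 360)
  bouts <- sleepBouts(ev)
  expect_equal(nrow(bouts), 1L)
  expect_equal(bouts$duration, 360)
  evB <- crossingEvents(seq(0, 3600, 240) * 5, spanEnd = 3600)
  expect_equal(nrow(sleepBouts(evB)), 0L)
  # random trains match the brute-force gap scan
  set.seed(20)
  for (rep in 1:20) {
    times <- sort(sample(seq(0, 7200, 0.2), 40))
    ev <- crossingEvents(round(times * 5), spanEnd = 7200)
    got <- sleepBouts(ev)
    ref <- bruteSleepBouts(round(times * 5) / 5, 0, 7200)
    expect_equal(nrow(got), NROW(ref))
    if (NROW(ref)) {
      expect_equal(got$start, ref[, 1])
      expect_equal(got$end, ref[, 2])
    }
  }
})

test_that("sleep minutes per bin never exceed the bin width", {
  ev <- crossingEvents(c(100, 40000) , spanEnd = 10800)
  bouts <- sleepBouts(ev)
  for (bm in c(1, 10, 30, 60)) {
    sb <- sleepBinned(bouts, bm)
    expect_true(all(binValues(sb) <= bm + 1e-9))
    expect_true(all(binValues(sb) >= 0))
  }
  # a bout fully covering a bin scores the full bin width
  sb10 <- sleepBinned(bouts, 10)
  expect_true(any(abs(binValues(sb10) - 10) < 1e-9))
})

test_that("average day folds complete cycles onto the ZT grid", {
  sch <- ldSchedule(2)
  mk <- function(v) BinnedSeries(v, 3600, (seq_along(v) - 1) * 3600)
  sameday <- mk(rep(c(1:12, 12:1), 2))
  prof <- averageDay(sameday, sch, 2)
  expect_equal(binValues(prof), c(1:12, 12:1))
  expect_equal(binStarts(prof), (0:23) * 3600)
  twoday <- mk(c(rep(0, 24), rep(10, 24)))
  expect_equal(binValues(averageDay(twoday, sch, 2)), rep(5, 24))
  expect_error(averageDay(mk(rep(1, 30)), sch, 2), "insufficient")
})

test_that("day/night totals sum only complete phases", {
  sch <- ldSchedule(2)
  b <- BinnedSeries(rep(1, 60), 3600, (0:59) * 3600)   # 60 h of 1/h
  tot <- dayNightTotals(b, sch)
  # complete phases inside the 48 h schedule: two L and two D
  expect_equal(tot[["day"]], 24)
  expect_equal(tot[["night"]], 24)
  # a truncated recording drops the incomplete phase
  b2 <- BinnedSeries(rep(1, 30), 3600, (0:29) * 3600)  # 30 h
  tot2 <- dayNightTotals(b2, sch)
  expect_equal(tot2[["day"]], 12)
  expect_equal(tot2[["night"]], 12)
})

test_that("Welch comparison of totals matches the closed form", {
  a <- data.frame(fly_id = letters[1:3], day = c(10, 12, 14),
                  night = c(1, 2, 3))
  b <- data.frame(fly_id = letters[4:6], day = c(20, 21, 25),
                  night = c(1.5, 2.5, 3.5))
  res <- compareTotals(a, b)
  # hand-computed Welch t for the day phase
  m1 <- mean(a$day); m2 <- mean(b$day)
  v1 <- var(a$day) / 3; v2 <- var(b$day) / 3
  tref <- (m1 - m2) / sqrt(v1 + v2)
  dfref <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
  day <- res[res$phase == "day", ]
  expect_equal(day$statistic, tref)
  expect_equal(day$df, dfref)
  expect_equal(day$p.value, 2 * pt(-abs(tref), dfref))
  # identical groups: t = 0, p = 1
  same <- compareTotals(a, a)
  expect_equal(same$statistic, c(0, 0))
  expect_equal(same$p.value, c(1, 1))
  expect_error(compareTotals(a[1, ], b), "at least 2")
})

test_that("a 5 SD shift is detected essentially always", {
  set.seed(21)
  rej <- 0L
  for (i in 1:200) {
    a <- data.frame(day = rnorm(16), night = rnorm(16))
    b <- data.frame(day = rnorm(16, 5), night = rnorm(16, 5))
    res <- compareTotals(a, b)
    if (all(res$p.value < 0.05)) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.99)
})

test_that("hourly comparison flags nothing for single flies", {
  a <- matrix(rnorm(24), 1)
  b <- matrix(rnorm(24), 1)
  res <- compareHourly(a, b)
  expect_equal(nrow(res), 24L)
  expect_false(any(res$discovery))
})

test_that("hourly comparison reports the higher group's direction", {
  set.seed(22)
  a <- matrix(rnorm(16 * 24), 16)
  b <- matrix(rnorm(16 * 24), 16)
  b[, 5] <- b[, 5] + 10
  res <- compareHourly(a, b)
  expect_true(res$discovery[5])
  expect_equal(res$higher[5], "B")
  # the BKY option runs and also finds the planted hour
  res2 <- compareHourly(a, b, method = "BKY")
  expect_true(res2$discovery[5])
})

test_that("a dead fly is flagged, a moving fly is not", {
  geom <- ChamberGeometry(0, 0, 100, 50, midline = 50)
  n <- 5 * 86400 + 100
  dead <- cleanedFromXY(rep(10, 1000), rep(10, 1000), geom,
                        frame = seq(0, n, length.out = 1000))
  expect_true(flagDeadFly(dead))
  set.seed(23)
  alive <- asCleaned(randomWalkSeries(2000, geom), geom)
  expect_false(flagDeadFly(alive))
})
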