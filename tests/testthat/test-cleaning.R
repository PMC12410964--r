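test_that("chamber limits are recovered from uniform detections", {
  set.seed(3)
  n <- 10000L
  s <- TrackingSeries(seq_len(n) - 1L, runif(n, 10, 110), runif(n, 20, 70),
                      rep(1, n))
  g <- inferChamberLimits(s)
  expect_lt(abs(g@xMin - 10), 2)
  expect_lt(abs(g@xMax - 110), 2)
  expect_lt(abs(g@yMin - 20), 2)
  expect_lt(abs(g@yMax - 70), 2)
  expect_equal(g@longAxis, "horizontal")
  expect_equal(g@midline, (g@xMin + g@xMax) / 2)
})

test_that("contaminated detections do not distort the inferred limits", {
  set.seed(4)
  n <- 10000L
  x <- runif(n, 10, 110); y <- runif(n, 20, 70)
  lik <- rep(1, n)
  # 1% misdetections 50 px outside at low confidence (as the tracker
  # reports them): rejected by the likelihood floor
  out <- sample(n, n / 100)
  x[out] <- 110 + 50; y[out] <- 70 + 50
  lik[out] <- runif(length(out), 0, 0.5)
  # plus a few high-confidence strays, thin enough for the 0.999
  # quantile to reject
  hi <- sample(setdiff(seq_len(n), out), 5)
  x[hi] <- -40
  s <- TrackingSeries(seq_len(n) - 1L, x, y, lik)
  g <- inferChamberLimits(s)
  expect_lt(abs(g@xMin - 10), 3)
  expect_lt(abs(g@xMax - 110), 3)
  expect_lt(abs(g@yMin - 20), 3)
  expect_lt(abs(g@yMax - 70), 3)
})

test_that("degenerate or sparse detections abort inference", {
  n <- 200L
  s <- TrackingSeries(seq_len(n) - 1L, rep(5, n), rep(5, n), rep(1, n))
  expect_error(inferChamberLimits(s), "degenerate")
  few <- TrackingSeries(0:9, runif(10), runif(10), rep(1, 10))
  expect_error(inferChamberLimits(few), "at least 100")
})

test_that("out-of-bounds flagging matches a per-frame check", {
  geom <- ChamberGeometry(0, 0, 100, 50)
  set.seed(6)
  n <- 1000L
  x <- runif(n, -10, 110); y <- runif(n, -10, 60)
  lik <- runif(n)
  x[5] <- NA
  s <- TrackingSeries(seq_len(n) - 1L, x, y, lik)
  mask <- flagOutOfBounds(s, geom, likelihoodFloor = 0.9)
  oracle <- vapply(seq_len(n), function(i) {
    is.na(x[i]) || is.na(y[i]) || lik[i] < 0.9 ||
      !(x[i] >= 0 && x[i] < 100 && y[i] >= 0 && y[i] < 50)
  }, logical(1))
  expect_identical(mask, oracle)
  # all-inside, all-confident: nothing flagged
  s2 <- TrackingSeries(0:9, runif(10, 1, 99), runif(10, 1, 49), rep(1, 10))
  expect_false(any(flagOutOfBounds(s2, geom)))
  # a single excursion flags exactly that index
  x3 <- runif(10, 1, 99); x3[4] <- -5
  s3 <- TrackingSeries(0:9, x3, runif(10, 1, 49), rep(1, 10))
  expect_identical(which(flagOutOfBounds(s3, geom)), 4L)
})

test_that("flagged frames take the flank midpoint; runs share one value", {
  geom <- ChamberGeometry(0, 0, 100, 100)
  s <- TrackingSeries(5:7, c(10, -1, 20), c(10, -1, 20), c(1, 1, 1))
  mask <- c(FALSE, TRUE, FALSE)
  cl <- interpolateOutOfBounds(s, mask, geom)
  expect_equal(coords(cl)$x[2], 15)
  expect_equal(coords(cl)$y[2], 15)

  s2 <- TrackingSeries(0:4, c(0, -1, -2, -3, 10), c(0, -1, -2, -3, 10),
                       rep(1, 5))
  cl2 <- interpolateOutOfBounds(s2, c(FALSE, TRUE, TRUE, TRUE, FALSE), geom)
  expect_equal(coords(cl2)$x[2:4], rep(5, 3))
  expect_equal(coords(cl2)$y[2:4], rep(5, 3))

  # leading run copies the first unflagged detection
  s3 <- TrackingSeries(0:3, c(-1, -1, -1, 7), c(-1, -1, -1, 9), rep(1, 4))
  cl3 <- interpolateOutOfBounds(s3, c(TRUE, TRUE, TRUE, FALSE), geom)
  expect_equal(coords(cl3)$x[1:3], rep(7, 3))
  expect_equal(coords(cl3)$y[1:3], rep(9, 3))

  # trailing run copies the last unflagged detection
  s4 <- TrackingSeries(0:2, c(7, -1, -1), c(9, -1, -1), rep(1, 3))
  cl4 <- interpolateOutOfBounds(s4, c(FALSE, TRUE, TRUE), geom)
  expect_equal(coords(cl4)$x, rep(7, 3))

  expect_error(interpolateOutOfBounds(s4, rep(TRUE, 3), geom),
               "unrecoverable")
})

test_that("interpolation equals the brute-force flanking scan", {
  set.seed(8)
  geom <- ChamberGeometry(0, 0, 100, 50)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    s <- randomWalkSeries(n, geom, oobFraction = 0.1)
    mask <- flagOutOfBounds(s, geom)
    if (all(mask)) next
    cl <- interpolateOutOfBounds(s, mask, geom)
    ref <- bruteInterpolate(s@x, s@y, mask)
    expect_identical(coords(cl)$x, ref$x)
    expect_identical(coords(cl)$y, ref$y)
  }
})

test_that("cleaning is idempotent and conserves unflagged positions", {
  set.seed(9)
  geom <- ChamberGeometry(0, 0, 100, 50)
  s <- randomWalkSeries(500, geom, oobFraction = 0.05)
  mask <- flagOutOfBounds(s, geom)
  cl <- interpolateOutOfBounds(s, mask, geom)
  # unflagged positions bit-identical
  expect_identical(coords(cl)$x[!mask], s@x[!mask])
  expect_identical(coords(cl)$y[!mask], s@y[!mask])
  # 100% containment after cleaning
  expect_true(all(containsPoint(geom, coords(cl)$x, coords(cl)$y)))
  # cleaning the cleaned series changes nothing
  s2 <- cl@series
  mask2 <- flagOutOfBounds(s2, geom, likelihoodFloor = 0)
  expect_false(any(mask2))
  cl2 <- interpolateOutOfBounds(s2, mask2, geom)
  expect_identical(coords(cl2), coords(cl))
})

test_that("time-weighted interpolation stays on the flank segment", {
  geom <- ChamberGeometry(0, 0, 100, 100)
  s <- TrackingSeries(0:4, c(0, -1, -1, -1, 8), c(0, -1, -1, -1, 4),
                      rep(1, 5))
  cl <- interpolateOutOfBounds(s, c(FALSE, TRUE, TRUE, TRUE, FALSE), geom,
                               method = "linear")
  expect_equal(coords(cl)$x, c(0, 2, 4, 6, 8))
  expect_equal(coords(cl)$y, c(0, 1, 2, 3, 4))
})

test_that("cleanSeries runs the full three-step procedure", {
  set.seed(10)
  geom <- ChamberGeometry(0, 0, 100, 50)
  s <- randomWalkSeries(5000, geom, oobFraction = 0.02)
  cl <- cleanSeries(s)                  # geometry inferred
  expect_s4_class(cl, "CleanedSeries")
  g <- geometryUsed(cl)
  # inferred rectangle hugs the walk, not the misdetections
  expect_gt(g@xMin, -5); expect_lt(g@xMax, 105)
  expect_gt(g@xMax - g@xMin, 40)
  expect_true(all(containsPoint(g, coords(cl)$x, coords(cl)$y)))
  rep <- cleaningReport(cl)
  expect_equal(rep$n_flagged, sum(interpolatedMask(cl)))
})
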