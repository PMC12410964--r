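test_that("a fly with zero entry rates never moves", {
  cfg <- SimulationConfig(durationS = 600, dayRate = 0, nightRate = 0,
                          startleBoost = 1, misdetectRate = 0, seed = 1)
  sim <- simulateFly(cfg)
  cl <- asCleaned(sim$series, cfg@chamber)
  expect_equal(sum(frameDistances(cl)), 0)
  expect_length(eventFrames(virtualDam(cl)), 0L)
  expect_true(all(sim$truth@state == 0L))
})

test_that("the same seed reproduces the series bit for bit", {
  cfg <- SimulationConfig(durationS = 1200, seed = 99)
  a <- simulateFly(cfg)
  b <- simulateFly(cfg)
  expect_identical(coords(a$series), coords(b$series))
  expect_identical(a$truth@misdetected, b$truth@misdetected)
  cfg2 <- SimulationConfig(durationS = 1200, seed = 100)
  expect_false(identical(coords(simulateFly(cfg2)$series),
                         coords(a$series)))
})

test_that("true positions always stay inside the chamber", {
  cfg <- SimulationConfig(durationS = 3600, dayRate = 0.5, nightRate = 0.5,
                          stepScale = 12, seed = 5)
  sim <- simulateFly(cfg)
  ch <- cfg@chamber
  expect_true(all(containsPoint(ch, sim$truth@trueX, sim$truth@trueY)))
})

test_that("injected misdetections match the configured rate and leave the chamber", {
  cfg <- SimulationConfig(durationS = 10000, misdetectRate = 0.005,
                          seed = 8)
  sim <- simulateFly(cfg)
  mis <- sim$truth@misdetected
  n <- length(mis)
  tol <- 3 * sqrt(0.005 * 0.995 / n)
  expect_lt(abs(mean(mis) - 0.005), tol)
  cs <- coords(sim$series)
  expect_true(all(!containsPoint(cfg@chamber, cs$x[mis], cs$y[mis])))
  expect_true(all(cs$likelihood[mis] < 0.5))
  expect_true(all(cs$likelihood[!mis] >= 0.9))
  # the mask marks exactly the frames whose report differs from truth
  differs <- cs$x != sim$truth@trueX | cs$y != sim$truth@trueY
  expect_identical(differs, mis)
})

test_that("cleaning recovers true positions at misdetected frames", {
  cfg <- SimulationConfig(durationS = 1200, misdetectRate = 0.05,
                          dayRate = 0.05, nightRate = 0.05,
                          stepScale = 1, seed = 11)
  sim <- simulateFly(cfg)
  cl <- cleanSeries(sim$series, geom = cfg@chamber)
  mis <- sim$truth@misdetected
  err <- sqrt((coords(cl)$x[mis] - sim$truth@trueX[mis])^2 +
              (coords(cl)$y[mis] - sim$truth@trueY[mis])^2)
  expect_lt(mean(err), 5 * cfg@stepScale)
})

test_that("entry rates reflect phase, startle and siesta", {
  cfg <- SimulationConfig(durationS = 86400, dayRate = 0.02,
                          nightRate = 0.01, startleBoost = 6,
                          startleDurationS = 300, siestaDepth = 0.5,
                          siestaStartZT = 4, siestaEndZT = 8, seed = 1)
  r <- entryRates(cfg)
  at <- function(h) r[round(h * 3600 * cfg@fps) + 1]
  expect_equal(at(2), 0.02)          # plain day
  expect_equal(at(5), 0.01)          # siesta halves the day rate
  expect_equal(at(12.01), 0.06)      # lights-off startle
  expect_equal(at(13), 0.01)         # plain night
  # DD schedules never startle
  cfgDD <- SimulationConfig(durationS = 86400, schedule = ddSchedule(1),
                            dayRate = 0.02, nightRate = 0.02,
                            siestaDepth = 1, seed = 1)
  expect_true(all(entryRates(cfgDD) == 0.02))
})

test_that("grouped experiments derive per-fly seeds and apply overrides", {
  cfg <- SimulationConfig(durationS = 600, seed = 3,
                          chamber = preferenceChamber(),
                          biasFood = "yeast", siestaDepth = 1)
  exp <- simulateExperiment(cfg, list(a = list(n = 2),
                                      b = list(n = 2, foodBias = 0.8)))
  expect_named(exp$flies, c("a", "b"))
  expect_equal(nrow(exp$summary), 4L)
  expect_equal(exp$summary$seed, (3 * 1000 + 1:4) %% 2147483647)
  # same master seed reproduces the experiment
  exp2 <- simulateExperiment(cfg, list(a = list(n = 2),
                                       b = list(n = 2, foodBias = 0.8)))
  expect_identical(exp$summary, exp2$summary)
  # the biased group occupies the food region more
  expect_gt(mean(exp$summary$food_fraction[exp$summary$group == "b"]),
            mean(exp$summary$food_fraction[exp$summary$group == "a"]))
  expect_error(simulateExperiment(cfg, list(a = list(n = 1, bogus = 2))),
               "unknown simulation parameter")
})

test_that("simulated series survive the writer and reader", {
  cfg <- SimulationConfig(durationS = 300, seed = 21)
  exp <- simulateExperiment(cfg, list(sim = list(n = 1)))
  dir <- file.path(tempdir(), "simexp")
  writeExperiment(exp, cfg, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  f <- file.path(dir, "sim_01.csv")
  expect_true(file.exists(f))
  r <- readTrackingCsv(f, fps = 5)
  expect_equal(coords(r)$x, coords(exp$flies$sim[[1]]$series)$x,
               tolerance = 1e-9)
  cfgBack <- readExperimentConfig(file.path(dir, "config.yaml"))
  expect_equal(configChamber(cfgBack, "simulated")@midline,
               cfg@chamber@midline)
})
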