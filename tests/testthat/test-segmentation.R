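test_that("zero-crossing segmentation recovers analytic sinusoid phases", {
  t <- (0:1999) / 100
  pmo <- SampledSignal(-sin(2 * pi * t / 4), 100, "Pmo", "cmH2O")
  seg <- detectPhases(pmo)
  ph <- phases(seg)
  insp <- ph[ph$label == "inspiratory", ]
  expect_equal(nrow(insp), 5L)
  expect_equal(insp$start, c(0, 4, 8, 12, 16), tolerance = 1 / 100)
  expect_equal(insp$end - insp$start, rep(2, 5), tolerance = 2 / 100)
  # positive rescaling leaves the segmentation unchanged
  seg2 <- detectPhases(SampledSignal(-0.1 * sin(2 * pi * t / 4), 100))
  expect_equal(phases(seg), phases(seg2))
  # polarity flips the labels
  seg3 <- detectPhases(pmo, polarity = "inspiratory-positive")
  expect_equal(sum(phases(seg3)$label == "inspiratory"), 5L)
  expect_equal(phases(seg3)$label[1], "expiratory")
})

test_that("sub-threshold sign flips are absorbed without changing cycle count", {
  t <- (0:1999) / 100
  x <- -sin(2 * pi * t / 4)
  x[t >= 2.5 & t < 2.8] <- -0.05 # 0.3 s flip inside an expiratory phase
  seg <- detectPhases(SampledSignal(x, 100))
  expect_equal(nCycles(seg), 5L)
  expect_true(all(phases(seg)$end - phases(seg)$start >= 0.5 - 1e-9))
})

test_that("no zero crossings is an error", {
  expect_error(detectPhases(SampledSignal(rep(1, 100) + 0.1, 100)),
               "no respiratory cycles")
})

test_that("cycle exclusion removes inspiratory/expiratory pairs", {
  t <- (0:1999) / 100
  seg <- detectPhases(SampledSignal(-sin(2 * pi * t / 4), 100))
  expect_identical(phases(applyExclusions(seg)), phases(seg))
  pruned <- applyExclusions(seg, 2L)
  expect_equal(nCycles(pruned), 4L)
  expect_false(any(abs(phases(pruned)$start - 4) < 1e-6))
  expect_error(applyExclusions(seg, 9L), "out of range")
})

test_that("individual SD equals the explicit concatenation oracle", {
  set.seed(21)
  fs <- 100
  t <- (0:1999) / fs
  pmo <- SampledSignal(-sin(2 * pi * t / 4), fs)
  seg <- detectPhases(pmo)
  mkChan <- function(seed) {
    set.seed(seed)
    SampledSignal(rnorm(2000, sd = runif(1, 0.5, 2)), fs)
  }
  chans <- list(chA = list(c1 = mkChan(1), c2 = mkChan(2)),
                chB = list(c1 = mkChan(3), c2 = mkChan(4)))
  segs <- list(c1 = seg, c2 = seg)
  got <- individualSD(chans, segs)
  oracle <- mean(vapply(chans, function(byCond) {
    xs <- c(phaseSamples(byCond$c1, seg), phaseSamples(byCond$c2, seg))
    oraclePopSD(xs)
  }, 0))
  expect_equal(got, oracle, tolerance = 1e-14)
  # invariant to condition and channel order
  chansR <- list(chB = rev(chans$chB), chA = rev(chans$chA))
  segsR <- list(c2 = seg, c1 = seg)
  expect_equal(individualSD(chansR, segsR), got, tolerance = 1e-14)
  # exclusions change the SD exactly as the oracle predicts
  segX <- applyExclusions(seg, 1L)
  gotX <- individualSD(chans, list(c1 = segX, c2 = seg))
  oracleX <- mean(vapply(chans, function(byCond) {
    oraclePopSD(c(phaseSamples(byCond$c1, segX), phaseSamples(byCond$c2, seg)))
  }, 0))
  expect_equal(gotX, oracleX, tolerance = 1e-14)
  expect_false(isTRUE(all.equal(gotX, got)))
})

test_that("global SD is the mean of individual SDs", {
  expect_equal(globalSD(c(0.002, 0.004)), 0.003)
  expect_equal(globalSD(c(0.002, 0.002)), 0.002)
  expect_equal(globalSD(0.0121), 0.0121)
  expect_error(globalSD(numeric()), "empty")
  # degenerate cohort: identical subjects collapse global onto individual
  expect_equal(globalSD(rep(0.0042, 5)), 0.0042)
})

test_that("shipped general tolerances are r x SD per signal group", {
  expect_equal(tolerance(generalParams("oesEMGdi")), 0.05 * 0.0121)
  expect_equal(tolerance(generalParams("sEMG")), 0.3 * 0.0022)
  expect_equal(tolerance(generalParams("absMMG")), 0.5 * 0.0060)
  gp <- generalParams("sEMG")
  expect_equal(gp@windowLengthS, 0.5)
  expect_equal(gp@overlap, 0.9)
  expect_identical(gp@m, 2L)
})

test_that("subject calibration matches a manual per-group computation", {
  rec <- smallSubject(seed = 8, breaths = 3)
  segs <- segmentSubject(rec)
  cal <- calibrateSubject(rec, segs)
  expect_named(cal, c("sEMG", "absMMG"))
  xs <- unlist(lapply(rec@conditions, function(cond)
    phaseSamples(rec@channels[[cond]]$sEMG1, segs[[cond]])))
  expect_equal(cal[["sEMG"]], oraclePopSD(xs), tolerance = 1e-14)
  expect_true(all(cal > 0))
})
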