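test_that("a series against itself has c_max 1 at lag 0", {
  set.seed(2)
  s <- SampledSignal(rnorm(4000), 500)
  p <- FSampEnParams(m = 2, tolerance = 1, windowLengthS = 0.5, overlap = 0.9)
  es <- movingFSampEn(s, p)
  prs <- SampledSignal(entropyValues(es), fs = 20, t0 = entropyTimes(es)[1])
  mc <- maxCrossCov(es, prs, negatePressure = FALSE)
  expect_equal(mc$cmax, 1, tolerance = 1e-12)
  expect_equal(mc$lagSteps, 0L)
})

test_that("c_max is invariant to positive affine transforms of the pressure", {
  set.seed(6)
  y <- as.numeric(stats::filter(rnorm(300), rep(0.2, 5), circular = TRUE))
  df <- data.frame(time = (0:299) * 0.05, value = y + rnorm(300, sd = 0.2))
  m1 <- maxCrossCov(df, SampledSignal(y, 20), negatePressure = FALSE)
  m2 <- maxCrossCov(df, SampledSignal(3 * y + 10, 20), negatePressure = FALSE)
  expect_equal(m1$cmax, m2$cmax, tolerance = 1e-12)
  expect_equal(m1$lagSteps, m2$lagSteps)
})

test_that("an imposed shift is recovered and matches the brute-force scan", {
  set.seed(3)
  y <- as.numeric(stats::filter(rnorm(300), rep(0.2, 5), circular = TRUE))
  xShift <- c(rep(0, 3), y[1:297]) # delayed by 3 steps
  df <- data.frame(time = (0:299) * 0.05, value = xShift)
  mc <- maxCrossCov(df, SampledSignal(y, 20), negatePressure = FALSE)
  expect_equal(mc$lagSteps, 3L)
  oracle <- brutePearsonScan(xShift, y, 100)
  expect_equal(mc$cmax, oracle$cmax, tolerance = 1e-12)
  expect_equal(mc$lagSteps, oracle$lag)
})

test_that("degenerate series and too-short overlaps are errors", {
  df <- data.frame(time = (0:99) * 0.05, value = rep(1, 100))
  expect_error(maxCrossCov(df, SampledSignal(rnorm(100), 20)), "degenerate")
  df2 <- data.frame(time = (0:5) * 0.05, value = rnorm(6))
  expect_error(maxCrossCov(df2, SampledSignal(rnorm(100), 20)),
               "fewer than 10")
})

test_that("grid enumeration reproduces the montage cardinalities", {
  conds <- c("rest", paste0("L", 1:5))
  healthy <- enumerateGrid(signals = paste0("ch", 1:11),
                           conditionNames = conds)
  expect_equal(nrow(healthy), 14256L)
  copd <- enumerateGrid(signals = paste0("ch", 1:4), conditionNames = conds)
  expect_equal(nrow(copd), 5184L)
  single <- enumerateGrid(signals = "ch1", conditionNames = "rest",
                          windowLengthsS = 0.5, rValues = 0.3,
                          sdModes = "global")
  expect_equal(nrow(single), 1L)
})

test_that("grid evaluation on one cell reduces to one maxCrossCov call", {
  rec <- smallSubject(seed = 4, breaths = 3, loads = 0.6)
  cal <- list(individual = calibrateSubject(rec),
              global = calibrateSubject(rec))
  g <- gridEvaluate(rec, cal, windowLengthsS = 0.5, rValues = 0.3,
                    sdModes = "global", groups = "sEMG")
  expect_named(g, "sEMG.pmo")
  gr <- g[["sEMG.pmo"]]
  expect_equal(dim(cmaxArray(gr)), c(1L, 1L, 1L))
  # manual recomputation: mean over the two conditions of one maxCrossCov
  tol <- 0.3 * cal$global[["sEMG"]]
  p <- FSampEnParams(m = 2, tolerance = tol, windowLengthS = 0.5,
                     overlap = 0.9)
  manual <- mean(vapply(rec@conditions, function(cond) {
    es <- suppressWarnings(movingFSampEn(rec@channels[[cond]]$sEMG1, p))
    maxCrossCov(es, rec@pressures[[cond]]$pmo)$cmax
  }, 0))
  expect_equal(as.numeric(cmaxArray(gr)), manual, tolerance = 1e-12)
})

test_that("cohort summaries average elementwise and re-annotate argmaxes", {
  mk <- function(m) {
    cm <- array(m, dim = c(2, 3, 1),
                dimnames = list(NULL, NULL, "global"))
    fSampEn:::.annotateGrid(cm, c(0.3, 0.5), c(0.1, 0.2, 0.3), "global",
                            "sEMG", "pmo", 6L)
  }
  set.seed(10)
  M <- matrix(runif(6), 2, 3)
  # one subject: identity
  one <- summarizeCohort(list(mk(M)))
  expect_equal(as.vector(cmaxArray(one)), as.vector(M))
  # M and 2 - M: mean is 1 everywhere; ties resolve to smallest r and window
  two <- summarizeCohort(list(mk(M), mk(2 - M)))
  expect_true(all(cmaxArray(two) == 1))
  ga <- globalArgmax(two)
  expect_equal(ga$windowS, 0.3)
  expect_equal(ga$r, 0.1)
  # three subjects against an explicit loop-accumulated mean
  Ms <- replicate(3, matrix(runif(6), 2, 3), simplify = FALSE)
  three <- summarizeCohort(lapply(Ms, mk))
  expect_equal(as.vector(cmaxArray(three)),
               as.vector(Reduce(`+`, Ms) / 3), tolerance = 1e-14)
  expect_error(summarizeCohort(list(mk(M), fSampEn:::.annotateGrid(
    array(0, c(1, 3, 1), dimnames = list(NULL, NULL, "global")),
    0.5, c(0.1, 0.2, 0.3), "global", "sEMG", "pmo", 3L))), "mismatch")
})

test_that("delta c_max follows its defining arithmetic", {
  cm <- array(NA_real_, dim = c(1, 3, 2))
  cm[1, , 1] <- c(0.7, 0.8, 0.75) # individual
  cm[1, , 2] <- c(0.72, 0.76, 0.74) # global
  gr <- fSampEn:::.annotateGrid(cm, 0.5, c(0.1, 0.2, 0.3),
                                c("individual", "global"), "sEMG", "pmo", 6L)
  d <- deltaCmax(gr, windowS = 0.5, globalR = 0.2)
  expect_equal(d$cInd, 0.8)
  expect_equal(d$indR, 0.2)
  expect_equal(d$cGlob, 0.76)
  expect_equal(d$deltaPct, 5.0)
  # identical parameters give exactly zero
  cm2 <- cm
  cm2[1, , 2] <- cm[1, , 1]
  gr2 <- fSampEn:::.annotateGrid(cm2, 0.5, c(0.1, 0.2, 0.3),
                                 c("individual", "global"), "sEMG", "pmo", 6L)
  expect_equal(deltaCmax(gr2, 0.5, 0.2)$deltaPct, 0)
  expect_error(deltaCmax(gr, windowS = 0.4, globalR = 0.2), "grid")
})

test_that("the long-format grid table round-trips the matrix", {
  cm <- array(seq_len(12) / 12, dim = c(2, 3, 2))
  gr <- fSampEn:::.annotateGrid(cm, c(0.3, 0.5), c(0.1, 0.2, 0.3),
                                c("individual", "global"), "absMMG", "pdi",
                                12L)
  tb <- gridTable(gr)
  expect_equal(nrow(tb), 12L)
  expect_setequal(unique(tb$sdMode), c("individual", "global"))
  row <- tb[tb$windowS == 0.5 & tb$r == 0.2 & tb$sdMode == "global", ]
  expect_equal(row$cmax, cm[2, 2, 2])
})
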