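test_that("sampenFixed matches the brute-force pair-counting oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    x <- rnorm(n)
    tol <- runif(1, 0.1, 0.5)
    m <- sample(1:3, 1)
    got <- suppressWarnings(as.numeric(sampenFixed(x, m, tol)))
    expect_equal(got, bruteSampEn(x, m, tol), tolerance = 1e-13)
  }
})

test_that("joint rescaling of signal and tolerance leaves the value unchanged", {
  set.seed(7)
  x <- rnorm(80)
  for (c_ in c(0.01, 3, 1e4)) {
    expect_equal(as.numeric(sampenFixed(c_ * x, 2, c_ * 0.2)),
                 as.numeric(sampenFixed(x, 2, 0.2)), tolerance = 1e-12)
  }
})

test_that("perfect regularity and oversized tolerance both give exactly zero", {
  expect_identical(as.numeric(sampenFixed(rep(5, 100), 2, 0.1)), 0)
  set.seed(1)
  x <- rnorm(60)
  expect_identical(as.numeric(sampenFixed(x, 2, diff(range(x)) + 1)), 0)
})

bruteCountB <- function(x, m, tol) {
  M <- length(x) - m
  B <- 0L
  for (i in seq_len(M - 1)) for (j in (i + 1):M)
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) B <- B + 1L
  B
}

test_that("degenerate counts give NaN (B = 0) or a flagged cap (A = 0)", {
  # strictly spaced ramp: no two length-m templates are within tolerance
  expect_warning(v <- sampenFixed(seq(0, 9), 2, 0.1), "undefined")
  expect_true(is.nan(as.numeric(v)))
  # repeated (0, 0) pairs match at length 2 but never at length 3
  x <- c(0, 0, 1, 0, 0, 2, 0, 0, 4)
  v <- sampenFixed(x, 2, 0.1)
  expect_true(attr(v, "capped"))
  expect_gt(as.numeric(v), 0)
  expect_equal(as.numeric(v), log(bruteCountB(x, 2, 0.1)))
})

test_that("fixed-tolerance entropy increases with noise amplitude", {
  set.seed(11)
  base <- matrix(rnorm(400 * 20), 400)
  meanEnt <- vapply(c(0.5, 1, 2), function(a)
    mean(apply(base * a, 2, function(w) as.numeric(sampenFixed(w, 2, 0.2)))),
    0)
  expect_true(all(diff(meanEnt) > 0))
})

test_that("window positions follow the documented arithmetic", {
  expect_identical(windowPositions(5, 5, 1), 0L)
  expect_identical(windowPositions(7, 5, 1), c(0L, 1L, 2L))
  expect_length(windowPositions(20000, 1000, 100), 191L)
  expect_error(windowPositions(4, 5, 1), "exceeds")
  expect_error(windowPositions(10, 5, 0), "step")
})

test_that("moving fSampEn equals sampenFixed applied to each window", {
  set.seed(3)
  s <- SampledSignal(rnorm(3000), fs = 500, label = "x")
  p <- FSampEnParams(m = 2, tolerance = 0.3, windowLengthS = 0.5,
                     overlap = 0.8)
  es <- movingFSampEn(s, p)
  N <- windowSamples(p, 500)
  step <- max(1L, round((1 - 0.8) * N))
  off <- windowPositions(3000, N, step)
  direct <- vapply(off, function(o)
    as.numeric(sampenFixed(samples(s)[(o + 1):(o + N)], 2, 0.3)), 0)
  expect_equal(entropyValues(es), direct, tolerance = 1e-14)
  # constant step between window centres
  expect_equal(diff(entropyTimes(es)), rep(step / 500, length(off) - 1))
})

test_that("moving fSampEn warns below 200 samples and errors on short signals", {
  set.seed(4)
  s <- SampledSignal(rnorm(2000), fs = 500)
  pShort <- FSampEnParams(m = 2, tolerance = 0.3, windowLengthS = 0.2,
                          overlap = 0.5)
  expect_warning(movingFSampEn(s, pShort), "200 samples")
  pHalf <- FSampEnParams(m = 2, tolerance = 0.3, windowLengthS = 0.5,
                         overlap = 0.5)
  expect_no_warning(movingFSampEn(s, pHalf))
  tiny <- SampledSignal(rnorm(30), fs = 100)
  expect_error(movingFSampEn(tiny, pHalf), "shorter than one window")
})

test_that("a constant signal yields an all-zero entropy series", {
  s <- SampledSignal(rep(2.5, 1500), fs = 500)
  p <- FSampEnParams(m = 2, tolerance = 0.1, windowLengthS = 0.5,
                     overlap = 0.9)
  es <- movingFSampEn(s, p)
  expect_true(all(entropyValues(es) == 0))
})

test_that("movingRMS shares the moving-window geometry", {
  set.seed(5)
  s <- SampledSignal(rnorm(3000), fs = 500)
  p <- FSampEnParams(m = 2, tolerance = 1, windowLengthS = 0.5, overlap = 0.9)
  es <- movingFSampEn(s, p)
  rms <- movingRMS(s, 0.5, 0.9)
  expect_equal(rms$time, entropyTimes(es))
  expect_equal(rms$value[1], sqrt(mean(samples(s)[1:250]^2)))
})
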