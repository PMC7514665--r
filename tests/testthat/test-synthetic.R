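test_that("pressure peaks scale with the imposed load fractions", {
  proto <- protocolSpec(breathsPerCondition = 4L, noiseSD = 0)
  pr <- genPressure(proto, seed = 1)
  n1 <- length(pr) / 6
  peaks <- vapply(1:6, function(i)
    max(-samples(pr)[((i - 1) * n1 + 1):(i * n1)]), 0)
  expect_equal(peaks[6] / peaks[2], 0.60 / 0.12, tolerance = 0.05)
  expect_equal(peaks[-1], c(0.12, 0.24, 0.36, 0.48, 0.60) * 100,
               tolerance = 1e-6)
})

test_that("the generator is deterministic under a fixed seed", {
  proto <- smallProtocol(breaths = 2L)
  expect_identical(samples(genPressure(proto, seed = 3)),
                   samples(genPressure(proto, seed = 3)))
  r1 <- genSubject(proto, montage = "custom", nSemg = 1L, nMmg = 1L, seed = 4)
  r2 <- genSubject(proto, montage = "custom", nSemg = 1L, nMmg = 1L, seed = 4)
  for (cond in r1@conditions) {
    for (ch in names(r1@channels[[cond]]))
      expect_identical(samples(r1@channels[[cond]][[ch]]),
                       samples(r2@channels[[cond]][[ch]]))
    expect_identical(samples(r1@pressures[[cond]]$pmo),
                     samples(r2@pressures[[cond]]$pmo))
  }
  r3 <- genSubject(proto, montage = "custom", nSemg = 1L, nMmg = 1L, seed = 5)
  expect_false(identical(samples(r1@channels$rest$sEMG1),
                         samples(r3@channels$rest$sEMG1)))
})

test_that("noise-free pressure round-trips through phase detection", {
  proto <- protocolSpec(breathsPerCondition = 3L, noiseSD = 0,
                        loadFractions = c(0.24, 0.6))
  pr <- genPressure(proto, seed = 1)
  seg <- detectPhases(SampledSignal(samples(pr)[1:1200], 100))
  ph <- phases(seg)
  insp <- ph[ph$label == "inspiratory", ]
  expect_equal(insp$end - insp$start, rep(proto@inspDurationS, nrow(insp)),
               tolerance = 1.5 / 100)
})

test_that("muscle signal amplitude follows the envelope", {
  env1 <- SampledSignal(rep(1, 500), 100, "env")
  env2 <- SampledSignal(rep(2, 500), 100, "env")
  s1 <- genMuscleSignal(env1, 500, c(10, 200), seed = 1)
  s2 <- genMuscleSignal(env2, 500, c(10, 200), seed = 2)
  expect_equal(sd(samples(s2)) / sd(samples(s1)), 2, tolerance = 0.1)
  # zero envelope and zero floor produce silence
  z <- genMuscleSignal(SampledSignal(rep(0, 500), 100), 500, c(10, 200),
                       seed = 1, floorLevel = 0)
  expect_true(all(samples(z) == 0))
  # same seed, same realization
  expect_identical(samples(genMuscleSignal(env1, 500, c(10, 200), seed = 9)),
                   samples(genMuscleSignal(env1, 500, c(10, 200), seed = 9)))
  expect_error(genMuscleSignal(env1, 500, c(10, 300), seed = 1), "Nyquist")
})

test_that("cardiac trains have the right beat count, spacing and jitter", {
  spec0 <- cardiacSpec(heartRateBpm = 60, jitterSD = 0)
  card <- genCardiac(spec0, 60, 500, seed = 1, amplitude = 1)
  beats <- attr(card, "beatTimes")
  expect_equal(length(beats), 60L)
  expect_equal(diff(beats), rep(1, 59))
  expect_equal(max(abs(samples(card))), 1, tolerance = 1e-9)
  # zero amplitude is silence
  z <- genCardiac(spec0, 10, 500, seed = 1, amplitude = 0)
  expect_true(all(samples(z) == 0))
  # jittered beats stay near nominal and are reproducible
  specJ <- cardiacSpec(heartRateBpm = 60, jitterSD = 0.05)
  cj1 <- genCardiac(specJ, 60, 500, seed = 2, amplitude = 1)
  cj2 <- genCardiac(specJ, 60, 500, seed = 2, amplitude = 1)
  expect_identical(samples(cj1), samples(cj2))
  nominal <- seq(0.5, 60, by = 1)
  expect_true(all(abs(attr(cj1, "beatTimes") - nominal) <= 3 * 0.05))
})

test_that("montages carry the expected myographic signal counts", {
  proto <- smallProtocol(breaths = 2L)
  healthy <- genSubject(proto, montage = "healthy", seed = 1,
                        cardiacEcg = cardiacSpec(amplitudeRel = 0),
                        cardiacMcg = cardiacSpec(template = "mcg",
                                                 amplitudeRel = 0))
  expect_equal(nMyographic(healthy), 11L)
  expect_named(signalGroups(healthy), c("oesEMGdi", "sEMG", "absMMG"))
  expect_true("pdi" %in% names(healthy@pressures$rest))
  copd <- genSubject(proto, montage = "copd", seed = 1,
                     cardiacEcg = cardiacSpec(amplitudeRel = 0),
                     cardiacMcg = cardiacSpec(template = "mcg",
                                              amplitudeRel = 0))
  expect_equal(nMyographic(copd), 4L)
  expect_identical(copd@cohort, "copd")
  expect_false("pdi" %in% names(copd@pressures$rest))
})

test_that("fSampEn at general parameters tracks the ground-truth envelope", {
  rec <- smallSubject(seed = 5, breaths = 4, loads = c(0.24, 0.6))
  es <- suppressWarnings(
    movingFSampEn(rec@channels$L2$sEMG1, generalParams("sEMG")))
  mc <- maxCrossCov(es, rec@envelope$L2, negatePressure = FALSE)
  expect_gt(mc$cmax, 0.8)
})
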