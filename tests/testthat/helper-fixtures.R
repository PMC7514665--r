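# Shared small fixtures, all generated in code.

# a small threshold-loading protocol: rest + two loads, a few breaths each
smallProtocol <- function(breaths = 4L, loads = c(0.24, 0.6), noiseSD = 0.05)
  protocolSpec(loadFractions = loads, breathsPerCondition = breaths,
               noiseSD = noiseSD)

# a cheap single-EMG / single-accelerometer subject
smallSubject <- function(seed = 1L, breaths = 4L, loads = c(0.24, 0.6),
                         cardiac = 3, preprocess = TRUE) {
  rec <- genSubject(smallProtocol(breaths, loads),
                    montage = "custom", nOes = 0L, nSemg = 1L, nMmg = 1L,
                    cardiacEcg = cardiacSpec(template = "ecg",
                                             amplitudeRel = cardiac),
                    cardiacMcg = cardiacSpec(template = "mcg",
                                             amplitudeRel = cardiac),
                    seed = seed)
  if (preprocess) preprocessSubject(rec, copdInterference = FALSE) else rec
}

sineSignal <- function(freq, fs, durS = 10, amp = 1)
  SampledSignal(amp * sin(2 * pi * freq * (0:(durS * fs - 1)) / fs), fs,
                label = paste0("sine", freq), units = "V")
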