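# Seeded synthetic respiratory subjects: inspiratory pressure waveforms under
# incremental threshold loading, amplitude-modulated band-limited Gaussian
# muscle activity, and quasi-periodic cardiac transients. The generator gives
# every other module a deterministic, download-free test bed; it is a
# statistical surrogate, not a physiological simulation.

# one condition's pressure + ground-truth effort envelope
.genPressureCondition <- function(protocol, amplitude, seed) {
  fs <- protocol@fsPressure
  nI <- round(protocol@inspDurationS * fs)
  nE <- round(protocol@expDurationS * fs)
  nb <- protocol@breathsPerCondition
  insp <- -amplitude * sin(pi * (seq_len(nI) - 1) / nI)
  ex <- protocol@expAmplitude * sin(pi * (seq_len(nE) - 1) / nE)
  pmo <- rep(c(insp, ex), nb)
  env <- rep(c(-insp, numeric(nE)), nb)
  if (protocol@noiseSD > 0) {
    set.seed(seed)
    pmo <- pmo + stats::rnorm(length(pmo), 0, protocol@noiseSD)
  }
  list(pmo = pmo, env = env)
}

.conditionAmplitudes <- function(protocol)
  c(protocol@tidalAmplitude, protocol@loadFractions * protocol@pimaxRef)

#' Generate a synthetic mouth-pressure recording
#'
#' Concatenates all protocol conditions (resting breathing followed by the
#' incremental threshold loads). Each breath is a half-sine inspiratory
#' deflection whose peak is the load fraction times the reference PImax
#' (resting breaths use the small tidal amplitude), followed by a smooth
#' positive expiratory return, plus additive low-amplitude Gaussian noise.
#' Deterministic for a given seed. The ground-truth inspiratory effort
#' envelope is attached as attribute `"envelope"` (a
#' [SampledSignal-class]).
#'
#' @param protocol a [ProtocolSpec-class].
#' @param seed integer seed.
#' @return A [SampledSignal-class] labelled "Pmo" (cmH2O) with attribute
#'   `"envelope"`.
#' @export
genPressure <- function(protocol, seed = 1L) {
  stopifnot(is(protocol, "ProtocolSpec"))
  amps <- .conditionAmplitudes(protocol)
  parts <- lapply(seq_along(amps), function(i)
    .genPressureCondition(protocol, amps[i], .subSeed(seed, 1L, i)))
  pmo <- unlist(lapply(parts, `[[`, "pmo"), use.names = FALSE)
  env <- unlist(lapply(parts, `[[`, "env"), use.names = FALSE)
  out <- SampledSignal(pmo, protocol@fsPressure, label = "Pmo",
                       units = "cmH2O")
  attr(out, "envelope") <- SampledSignal(env, protocol@fsPressure,
                                         label = "envelope", units = "cmH2O")
  out
}

#' Generate amplitude-modulated band-limited muscle activity
#'
#' Gaussian white noise band-limited to `band` (zero-phase Butterworth,
#' normalized to unit SD) and multiplied per-sample by the effort envelope
#' (linearly resampled onto the output rate) plus a baseline floor:
#' `gain * (envelope + floorLevel) * noise`. This multiplicative-envelope
#' model is the standard surrogate for the amplitude-tracking premise of
#' fixed sample entropy. Deterministic for a given seed.
#'
#' @param envelope nonnegative effort envelope ([SampledSignal-class]).
#' @param fs output sampling rate in Hz.
#' @param band band limits in Hz (defaults: EMG 10-600 at 2000 Hz;
#'   use `c(5, 40)` at 500 Hz for MMG).
#' @param seed integer seed.
#' @param floorLevel baseline activity floor, in envelope units.
#' @param gain output units per envelope unit.
#' @param label,units channel metadata.
#' @return A [SampledSignal-class].
#' @export
genMuscleSignal <- function(envelope, fs, band = c(10, 600), seed = 1L,
                            floorLevel = 0, gain = 1, label = "muscle",
                            units = "V") {
  stopifnot(is(envelope, "SampledSignal"))
  if (any(samples(envelope) < 0)) stop("envelope must be nonnegative")
  if (band[2L] >= fs / 2) stop("band outside the Nyquist range")
  n <- as.integer(round(duration(envelope) * fs))
  tt <- startTime(envelope) + (seq_len(n) - 1) / fs
  env <- stats::approx(sampleTimes(envelope), samples(envelope), xout = tt,
                       rule = 2)$y
  set.seed(seed)
  noise <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  noise <- .zerophaseFilter(bf$b, bf$a, noise)
  s <- .popSD(noise)
  if (s > 0) noise <- noise / s
  SampledSignal(gain * (env + floorLevel) * noise, fs, label = label,
                units = units, t0 = startTime(envelope))
}

#' Generate a cardiac artifact train
#'
#' A transient template repeated at jittered beat times: a biphasic spike
#' (derivative-of-Gaussian) for ECG-like interference, or a damped
#' oscillation for MCG-like interference. Deterministic per seed.
#'
#' @param spec a [CardiacSpec-class].
#' @param durationS train duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param amplitude peak amplitude in signal units.
#' @return A [SampledSignal-class].
#' @export
genCardiac <- function(spec, durationS, fs, seed = 1L, amplitude = 1) {
  stopifnot(is(spec, "CardiacSpec"))
  n <- as.integer(round(durationS * fs))
  x <- numeric(max(n, 2L))
  if (amplitude > 0) {
    tmpl <- if (spec@template == "ecg") {
      tt <- seq(-0.06, 0.06, by = 1 / fs)
      s <- 0.015
      v <- -(tt / s) * exp(-(tt / s)^2 / 2)
      v / max(abs(v))
    } else {
      tt <- seq(0, 0.25, by = 1 / fs)
      v <- sin(2 * pi * 18 * tt) * exp(-tt / 0.06)
      v / max(abs(v))
    }
    period <- 60 / spec@heartRateBpm
    beats <- seq(period / 2, durationS, by = period)
    if (spec@jitterSD > 0) {
      set.seed(seed)
      beats <- beats + stats::rnorm(length(beats), 0, spec@jitterSD)
    }
    for (b in beats) {
      i0 <- as.integer(round(b * fs))
      idx <- i0 + seq_along(tmpl)
      keep <- idx >= 1L & idx <= n
      x[idx[keep]] <- x[idx[keep]] + amplitude * tmpl[keep]
    }
  }
  out <- SampledSignal(x[seq_len(max(n, 2L))], fs, label = spec@template,
                       units = "")
  if (amplitude > 0) attr(out, "beatTimes") <- beats
  out
}

# default channel gains (output units per cmH2O of effort envelope), chosen
# once so concatenated-inspiratory SDs land near the magnitudes typical of
# each signal type (order 1e-2 V oesophageal EMG, 1e-3 V surface EMG,
# 1e-3 g accelerometer MMG)
.defaultGains <- c(oesEMGdi = 4.6e-4, sEMG = 8.5e-5, sMMG = 1.5e-4)

# montage definitions: channel labels per group, pre-norm
.montage <- function(montage, nOes = NULL, nSemg = NULL, nMmg = NULL) {
  if (montage == "healthy") {
    oes <- paste0("oesEMGdi", 1:5)
    semg <- c("sEMGpara", "sEMGlicR", "sEMGlicL")
    mmg <- c("sMMGpara", "sMMGlicR", "sMMGlicL")
  } else if (montage == "copd") {
    oes <- character()
    semg <- c("sEMGpara", "sEMGlicR")
    mmg <- c("sMMGpara", "sMMGlicR")
  } else { # custom
    oes <- if (nOes > 0) paste0("oesEMGdi", seq_len(nOes)) else character()
    semg <- if (nSemg > 0) paste0("sEMG", seq_len(nSemg)) else character()
    mmg <- if (nMmg > 0) paste0("sMMG", seq_len(nMmg)) else character()
  }
  list(oes = oes, semg = semg, mmg = mmg)
}

#' Generate a complete synthetic subject
#'
#' Builds a [SubjectRecord-class] mimicking either the healthy montage
#' (5 oesophageal diaphragm EMG channels, 3 surface EMG channels, 3 triaxial
#' accelerometers, mouth and transdiaphragmatic pressure: 11 myographic
#' signals after the accelerometer norms) or the COPD montage (2 surface EMG,
#' 2 accelerometers, mouth pressure only: 4 signals), or a reduced custom
#' montage for cheap tests. Per condition it generates the pressure waveform,
#' the ground-truth effort envelope, each muscle channel as
#' envelope-modulated band-limited noise, and a shared cardiac transient
#' train per subject-condition (ECG-like on EMG channels, MCG-like on
#' accelerometer axes) scaled to `amplitudeRel` times that channel's resting
#' muscle SD. Transdiaphragmatic pressure (healthy montage) is the effort
#' envelope with an independent slow diaphragm-weighted modulation, so its
#' correlation with the muscle signals differs from mouth pressure's. The
#' whole record is bit-reproducible for a given seed.
#'
#' @param protocol a [ProtocolSpec-class].
#' @param montage `"healthy"`, `"copd"` or `"custom"`.
#' @param cardiacEcg,cardiacMcg [CardiacSpec-class] for EMG and MMG channels
#'   (set `amplitudeRel = 0` for cardiac-free records).
#' @param seed integer seed.
#' @param nOes,nSemg,nMmg channel counts for the custom montage.
#' @return A raw (unpreprocessed) [SubjectRecord-class].
#' @examples
#' rec <- genSubject(protocolSpec(breathsPerCondition = 3,
#'                                loadFractions = c(0.12, 0.6)),
#'                   montage = "copd", seed = 7)
#' nMyographic(rec)  # 4
#' @export
genSubject <- function(protocol = protocolSpec(),
                       montage = c("healthy", "copd", "custom"),
                       cardiacEcg = cardiacSpec(template = "ecg"),
                       cardiacMcg = cardiacSpec(template = "mcg",
                                                amplitudeRel = 3),
                       seed = 1L, nOes = 0L, nSemg = 1L, nMmg = 1L) {
  stopifnot(is(protocol, "ProtocolSpec"))
  montage <- match.arg(montage)
  mn <- .montage(montage, nOes, nSemg, nMmg)
  conds <- conditionLabels(protocol)
  amps <- .conditionAmplitudes(protocol)
  channels <- list()
  pressures <- list()
  envelope <- list()
  chanIndex <- stats::setNames(seq_along(c(mn$oes, mn$semg, mn$mmg)),
                               c(mn$oes, mn$semg, mn$mmg))
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    pr <- .genPressureCondition(protocol, amps[ci], .subSeed(seed, 1L, ci))
    pmo <- SampledSignal(pr$pmo, protocol@fsPressure, "Pmo", "cmH2O")
    env <- SampledSignal(pr$env, protocol@fsPressure, "envelope", "cmH2O")
    prs <- list(pmo = pmo)
    if (montage == "healthy") {
      # diaphragm-weighted pressure: effort envelope with an independent
      # slow modulation plus noise, effort-positive
      set.seed(.subSeed(seed, 2L, ci))
      slow <- stats::filter(stats::rnorm(length(pr$env)),
                            rep(1 / 201, 201), sides = 2)
      slow[is.na(slow)] <- 0
      slow <- as.numeric(slow) / max(1e-12, stats::sd(slow[slow != 0]))
      pdi <- pr$env * (1 + 0.2 * pmin(pmax(slow, -2), 2)) +
        stats::rnorm(length(pr$env), 0, protocol@noiseSD)
      prs$pdi <- SampledSignal(pdi, protocol@fsPressure, "Pdi", "cmH2O")
    }
    pressures[[cond]] <- prs
    envelope[[cond]] <- env
    chs <- list()
    durS <- duration(env)
    # shared beat times per condition: same seed for all channels
    beatSeed <- .subSeed(seed, 3L, ci)
    for (lab in mn$oes) {
      g <- .defaultGains[["oesEMGdi"]]
      chs[[lab]] <- .addCardiac(
        genMuscleSignal(env, protocol@fsEmg, c(10, 600),
                        seed = .subSeed(seed, 4L, ci, chanIndex[[lab]]),
                        floorLevel = 0.05 * protocol@pimaxRef * 0.12,
                        gain = g, label = lab, units = "V"),
        cardiacEcg, beatSeed, protocol, g)
    }
    for (lab in mn$semg) {
      g <- .defaultGains[["sEMG"]]
      chs[[lab]] <- .addCardiac(
        genMuscleSignal(env, protocol@fsEmg, c(10, 600),
                        seed = .subSeed(seed, 4L, ci, chanIndex[[lab]]),
                        floorLevel = 0.05 * protocol@pimaxRef * 0.12,
                        gain = g, label = lab, units = "V"),
        cardiacEcg, beatSeed, protocol, g)
    }
    axW <- c(X = 1, Y = 0.8, Z = 0.5)
    for (lab in mn$mmg) {
      for (ax in c("X", "Y", "Z")) {
        g <- .defaultGains[["sMMG"]] * axW[[ax]]
        axLab <- paste0(lab, "_", ax)
        chs[[axLab]] <- .addCardiac(
          genMuscleSignal(env, protocol@fsMmg, c(5, 40),
                          seed = .subSeed(seed, 4L, ci,
                                          100L * chanIndex[[lab]] +
                                            match(ax, c("X", "Y", "Z"))),
                          floorLevel = 0.05 * protocol@pimaxRef * 0.12,
                          gain = g, label = axLab, units = "g"),
          cardiacMcg, beatSeed, protocol, g)
      }
    }
    channels[[cond]] <- chs
  }
  groups <- list()
  if (length(mn$oes)) groups$oesEMGdi <- mn$oes
  if (length(mn$semg)) groups$sEMG <- mn$semg
  if (length(mn$mmg)) groups$absMMG <- paste0("|", mn$mmg, "|")
  new("SubjectRecord", conditions = conds, channels = channels,
      pressures = pressures, envelope = envelope, groups = groups,
      cohort = if (montage == "copd") "copd" else "healthy",
      seed = as.integer(seed), preprocessed = FALSE)
}

# add a cardiac train scaled to amplitudeRel x the channel's resting-level
# muscle SD (resting level = floor + tidal effort, approximated analytically
# from the generator model: SD over a rest breath of gain*(env+floor)*unitSD
# noise). Uses the analytic value so the amplitude does not depend on the
# realized noise.
.addCardiac <- function(muscle, spec, beatSeed, protocol, gain) {
  if (spec@amplitudeRel == 0) return(muscle)
  fs <- samplingRate(muscle)
  # analytic resting SD: sqrt(mean((A sin + floor)^2)) over one rest breath
  nI <- round(protocol@inspDurationS * fs)
  nE <- round(protocol@expDurationS * fs)
  A <- protocol@tidalAmplitude
  fl <- 0.05 * protocol@pimaxRef * 0.12
  envBreath <- c(A * sin(pi * (seq_len(nI) - 1) / nI) + fl, rep(fl, nE))
  restSD <- gain * sqrt(mean(envBreath^2))
  card <- genCardiac(spec, duration(muscle), fs, seed = beatSeed,
                     amplitude = spec@amplitudeRel * restSD)
  SampledSignal(samples(muscle) + samples(card)[seq_len(length(muscle))],
                fs, label = signalLabel(muscle), units = signalUnits(muscle),
                t0 = startTime(muscle))
}

#' Ground-truth envelope of a synthetic record
#'
#' @param record a [SubjectRecord-class] built by [genSubject()].
#' @param condition condition label (default: all, concatenated in protocol
#'   order).
#' @return A [SampledSignal-class].
#' @export
groundTruthEnvelope <- function(record, condition = NULL) {
  stopifnot(is(record, "SubjectRecord"))
  if (length(record@envelope) == 0L) stop("record has no stored envelope")
  if (!is.null(condition)) return(record@envelope[[condition]])
  fs <- samplingRate(record@envelope[[1L]])
  SampledSignal(unlist(lapply(record@envelope, samples), use.names = FALSE),
                fs, label = "envelope", units = "cmH2O")
}
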