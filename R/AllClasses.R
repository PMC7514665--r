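#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib fSampEn, .registration = TRUE
NULL

# ---------------------------------------------------------------- SampledSignal

#' SampledSignal: one uniformly sampled channel
#'
#' Container for a single uniformly sampled physiological channel: the sample
#' values, the sampling rate, a channel label, a unit string (V for EMG, g for
#' accelerometer MMG, cmH2O for pressures) and the start time of the first
#' sample.
#'
#' @slot samples numeric vector of finite sample values (length >= 2).
#' @slot fs sampling rate in Hz (> 0).
#' @slot label channel identifier.
#' @slot units unit string.
#' @slot t0 time of the first sample in seconds.
#'
#' @examples
#' s <- SampledSignal(sin(2 * pi * 5 * (0:999) / 100), fs = 100,
#'                    label = "demo", units = "cmH2O")
#' samplingRate(s)
#' duration(s)
#' @name SampledSignal-class
#' @aliases SampledSignal-class
#' @exportClass SampledSignal
setClass("SampledSignal",
         slots = c(samples = "numeric", fs = "numeric", label = "character",
                   units = "character", t0 = "numeric"))

setValidity("SampledSignal", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive finite number")
  if (length(object@samples) < 2L)
    msg <- c(msg, "'samples' must have length >= 2")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must all be finite")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a SampledSignal
#'
#' @param samples numeric vector of sample values.
#' @param fs sampling rate in Hz.
#' @param label channel identifier.
#' @param units unit string (e.g. "V", "g", "cmH2O").
#' @param t0 start time in seconds.
#' @return A [SampledSignal-class] object.
#' @export
SampledSignal <- function(samples, fs, label = "signal", units = "", t0 = 0) {
  new("SampledSignal", samples = as.numeric(samples), fs = as.numeric(fs),
      label = as.character(label)[1L], units = as.character(units)[1L],
      t0 = as.numeric(t0))
}

#' @describeIn SampledSignal-class sample values.
#' @param x,object a `SampledSignal`.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname SampledSignal-class
#' @export
setMethod("samples", "SampledSignal", function(x) x@samples)

#' @describeIn SampledSignal-class sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname SampledSignal-class
#' @export
setMethod("samplingRate", "SampledSignal", function(x) x@fs)

#' @describeIn SampledSignal-class channel label.
#' @export
setGeneric("signalLabel", function(x) standardGeneric("signalLabel"))
#' @rdname SampledSignal-class
#' @export
setMethod("signalLabel", "SampledSignal", function(x) x@label)

#' @describeIn SampledSignal-class unit string.
#' @export
setGeneric("signalUnits", function(x) standardGeneric("signalUnits"))
#' @rdname SampledSignal-class
#' @export
setMethod("signalUnits", "SampledSignal", function(x) x@units)

#' @describeIn SampledSignal-class start time in seconds.
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname SampledSignal-class
#' @export
setMethod("startTime", "SampledSignal", function(x) x@t0)

#' @describeIn SampledSignal-class per-sample time stamps in seconds.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname SampledSignal-class
#' @export
setMethod("sampleTimes", "SampledSignal", function(x)
  x@t0 + (seq_along(x@samples) - 1) / x@fs)

#' @describeIn SampledSignal-class duration in seconds (n / fs).
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname SampledSignal-class
#' @export
setMethod("duration", "SampledSignal", function(x) length(x@samples) / x@fs)

#' @rdname SampledSignal-class
#' @export
setMethod("length", "SampledSignal", function(x) length(x@samples))

setMethod("show", "SampledSignal", function(object) {
  cat(sprintf("SampledSignal '%s': %d samples @ %g Hz (%.3f s)%s\n",
              object@label, length(object@samples), object@fs,
              duration(object),
              if (nzchar(object@units)) paste0(" [", object@units, "]") else ""))
})

# --------------------------------------------------------------- FSampEnParams

#' FSampEnParams: fixed sample entropy parameters
#'
#' Parameter bundle for fixed sample entropy: embedding dimension `m`,
#' tolerance multiplier `r`, reference standard deviation `sdRef` (in signal
#' units), the derived fixed tolerance `r * sdRef`, the moving-window length in
#' seconds and the fractional overlap between adjacent windows. The tolerance
#' is held constant across all windows and all signals of a group, which is
#' what makes the estimator amplitude-sensitive.
#'
#' @slot m embedding dimension (positive integer).
#' @slot r tolerance multiplier (positive real; may be NA when `tolerance`
#'   is supplied directly).
#' @slot sdRef reference SD in signal units (positive real; may be NA).
#' @slot tolerance fixed similarity radius in signal units (> 0).
#' @slot windowLengthS moving-window length in seconds (> 0).
#' @slot overlap fractional overlap in `[0, 1)`.
#' @name FSampEnParams-class
#' @exportClass FSampEnParams
setClass("FSampEnParams",
         slots = c(m = "integer", r = "numeric", sdRef = "numeric",
                   tolerance = "numeric", windowLengthS = "numeric",
                   overlap = "numeric"))

setValidity("FSampEnParams", function(object) {
  msg <- character()
  if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
    msg <- c(msg, "'m' must be a positive integer")
  if (length(object@tolerance) != 1L || !is.finite(object@tolerance) ||
      object@tolerance <= 0)
    msg <- c(msg, "'tolerance' must be a single positive number")
  if (length(object@windowLengthS) != 1L || !is.finite(object@windowLengthS) ||
      object@windowLengthS <= 0)
    msg <- c(msg, "'windowLengthS' must be positive")
  if (length(object@overlap) != 1L || !is.finite(object@overlap) ||
      object@overlap < 0 || object@overlap >= 1)
    msg <- c(msg, "'overlap' must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct FSampEnParams
#'
#' The tolerance defaults to `r * sdRef`; it may also be given directly, in
#' which case `r` and `sdRef` are recorded as supplied (possibly NA).
#'
#' @param m embedding dimension.
#' @param r tolerance multiplier.
#' @param sdRef reference standard deviation in signal units.
#' @param windowLengthS window length in seconds.
#' @param overlap fractional overlap between adjacent windows in `[0, 1)`.
#' @param tolerance fixed tolerance in signal units; default `r * sdRef`.
#' @return An [FSampEnParams-class] object.
#' @examples
#' FSampEnParams(m = 2, r = 0.3, sdRef = 0.0022)
#' @export
FSampEnParams <- function(m = 2L, r = NA_real_, sdRef = NA_real_,
                          windowLengthS = 0.5, overlap = 0.9,
                          tolerance = r * sdRef) {
  new("FSampEnParams", m = as.integer(m), r = as.numeric(r),
      sdRef = as.numeric(sdRef), tolerance = as.numeric(tolerance),
      windowLengthS = as.numeric(windowLengthS), overlap = as.numeric(overlap))
}

#' @describeIn FSampEnParams-class the fixed tolerance in signal units.
#' @param x,object an `FSampEnParams`.
#' @export
setGeneric("tolerance", function(x) standardGeneric("tolerance"))
#' @rdname FSampEnParams-class
#' @export
setMethod("tolerance", "FSampEnParams", function(x) x@tolerance)

#' @describeIn FSampEnParams-class window sample count `round(windowLengthS * fs)`.
#' @param fs sampling rate of the signal the parameters will be applied to.
#' @export
setGeneric("windowSamples", function(x, fs) standardGeneric("windowSamples"))
#' @rdname FSampEnParams-class
#' @export
setMethod("windowSamples", "FSampEnParams", function(x, fs)
  as.integer(round(x@windowLengthS * fs)))

setMethod("show", "FSampEnParams", function(object) {
  cat(sprintf(
    "FSampEnParams: m=%d, r=%s, sdRef=%s, tolerance=%g, window=%g s, overlap=%g\n",
    object@m, format(object@r), format(object@sdRef), object@tolerance,
    object@windowLengthS, object@overlap))
})

# --------------------------------------------------------------- EntropySeries

#' EntropySeries: a moving-window fSampEn time-series
#'
#' Fixed sample entropy values (nats) with window-centre timestamps, the
#' parameters used, and per-window flags marking windows where the
#' length-(m+1) match count was zero and the value was capped at its
#' information-theoretic upper bound `log(B)`.
#'
#' @slot values entropy values in nats (NaN where undefined).
#' @slot times window-centre timestamps in seconds (strictly increasing).
#' @slot params the [FSampEnParams-class] used.
#' @slot sourceLabel label of the source channel.
#' @slot capped logical, TRUE where the value was capped (A = 0, B > 0).
#' @name EntropySeries-class
#' @exportClass EntropySeries
setClass("EntropySeries",
         slots = c(values = "numeric", times = "numeric",
                   params = "FSampEnParams", sourceLabel = "character",
                   capped = "logical"))

setValidity("EntropySeries", function(object) {
  msg <- character()
  n <- length(object@values)
  if (length(object@times) != n || length(object@capped) != n)
    msg <- c(msg, "'values', 'times' and 'capped' must have equal length")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn EntropySeries-class entropy values in nats.
#' @param x,object an `EntropySeries`.
#' @export
setGeneric("entropyValues", function(x) standardGeneric("entropyValues"))
#' @rdname EntropySeries-class
#' @export
setMethod("entropyValues", "EntropySeries", function(x) x@values)

#' @describeIn EntropySeries-class window-centre timestamps in seconds.
#' @export
setGeneric("entropyTimes", function(x) standardGeneric("entropyTimes"))
#' @rdname EntropySeries-class
#' @export
setMethod("entropyTimes", "EntropySeries", function(x) x@times)

#' @describeIn EntropySeries-class the parameters used.
#' @export
setGeneric("entropyParams", function(x) standardGeneric("entropyParams"))
#' @rdname EntropySeries-class
#' @export
setMethod("entropyParams", "EntropySeries", function(x) x@params)

#' @describeIn EntropySeries-class per-window capped flags.
#' @export
setGeneric("cappedFlags", function(x) standardGeneric("cappedFlags"))
#' @rdname EntropySeries-class
#' @export
setMethod("cappedFlags", "EntropySeries", function(x) x@capped)

#' @rdname EntropySeries-class
#' @export
setMethod("length", "EntropySeries", function(x) length(x@values))

setMethod("show", "EntropySeries", function(object) {
  cat(sprintf(
    "EntropySeries from '%s': %d windows, %d capped, %d undefined\n",
    object@sourceLabel, length(object@values), sum(object@capped),
    sum(is.nan(object@values))))
  show(object@params)
})

# ---------------------------------------------------------- BreathSegmentation

#' BreathSegmentation: labelled respiratory phase intervals
#'
#' Ordered, non-overlapping, alternating inspiratory/expiratory intervals
#' (half-open, `[start, end)`, in seconds) obtained by zero-crossing detection
#' on mouth pressure. Every kept phase is at least `minDurationS` long;
#' shorter phases are merged during detection.
#'
#' @slot start phase start times in seconds.
#' @slot end phase end times in seconds.
#' @slot label "inspiratory" or "expiratory" per phase.
#' @slot minDurationS minimum phase duration in seconds.
#' @name BreathSegmentation-class
#' @exportClass BreathSegmentation
setClass("BreathSegmentation",
         slots = c(start = "numeric", end = "numeric", label = "character",
                   minDurationS = "numeric"))

setValidity("BreathSegmentation", function(object) {
  msg <- character()
  n <- length(object@start)
  if (length(object@end) != n || length(object@label) != n)
    msg <- c(msg, "'start', 'end', 'label' must have equal length")
  if (n > 0L) {
    if (any(object@end - object@start < object@minDurationS - 1e-9))
      msg <- c(msg, "phase shorter than minDurationS")
    if (n > 1L) {
      if (any(object@start[-1L] < object@end[-n] - 1e-9))
        msg <- c(msg, "phases overlap or are out of order")
      if (any(object@label[-1L] == object@label[-n]))
        msg <- c(msg, "phase labels must alternate")
    }
    if (!all(object@label %in% c("inspiratory", "expiratory")))
      msg <- c(msg, "labels must be 'inspiratory' or 'expiratory'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BreathSegmentation-class phases as a data.frame
#'   (start, end, label).
#' @param x,object a `BreathSegmentation`.
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))
#' @rdname BreathSegmentation-class
#' @export
setMethod("phases", "BreathSegmentation", function(x)
  data.frame(start = x@start, end = x@end, label = x@label,
             stringsAsFactors = FALSE))

#' @describeIn BreathSegmentation-class number of inspiratory phases.
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))
#' @rdname BreathSegmentation-class
#' @export
setMethod("nCycles", "BreathSegmentation", function(x)
  sum(x@label == "inspiratory"))

setMethod("show", "BreathSegmentation", function(object) {
  cat(sprintf(
    "BreathSegmentation: %d phases (%d inspiratory), min duration %g s\n",
    length(object@start), nCycles(object), object@minDurationS))
})

# ------------------------------------------------------------------ GridResult

#' GridResult: c_max over the (window, r, SD mode) grid
#'
#' For one signal group and one pressure reference: the mean maximum
#' normalized cross-covariance `c_max` over the evaluation grid, as a 3-d
#' array indexed by window length, tolerance multiplier `r` and SD mode
#' ("individual" or "global"), with per-row (best `r` for each window) and
#' global argmax annotations per SD mode. Argmax ties are broken toward
#' smaller `r`, then smaller window.
#'
#' @slot windowLengthsS grid of window lengths in seconds.
#' @slot rValues grid of tolerance multipliers.
#' @slot sdModes SD modes evaluated.
#' @slot cmax numeric array `[window, r, sdMode]`, values in `[-1, 1]`.
#' @slot rowArgmax data.frame (sdMode, windowS, bestR, cmax).
#' @slot globalArgmax data.frame (sdMode, windowS, r, cmax).
#' @slot group signal group label.
#' @slot pressure pressure channel label.
#' @slot nSeries number of entropy series the matrix summarizes.
#' @name GridResult-class
#' @exportClass GridResult
setClass("GridResult",
         slots = c(windowLengthsS = "numeric", rValues = "numeric",
                   sdModes = "character", cmax = "array",
                   rowArgmax = "data.frame", globalArgmax = "data.frame",
                   group = "character", pressure = "character",
                   nSeries = "integer"))

setValidity("GridResult", function(object) {
  d <- dim(object@cmax)
  if (length(d) != 3L ||
      d[1L] != length(object@windowLengthsS) ||
      d[2L] != length(object@rValues) ||
      d[3L] != length(object@sdModes))
    return("'cmax' dimensions must match the grid axes")
  TRUE
})

#' @describeIn GridResult-class the c_max array `[window, r, sdMode]`.
#' @param x,object a `GridResult`.
#' @export
setGeneric("cmaxArray", function(x) standardGeneric("cmaxArray"))
#' @rdname GridResult-class
#' @export
setMethod("cmaxArray", "GridResult", function(x) x@cmax)

#' @describeIn GridResult-class best `r` per window, per SD mode.
#' @export
setGeneric("rowArgmax", function(x) standardGeneric("rowArgmax"))
#' @rdname GridResult-class
#' @export
setMethod("rowArgmax", "GridResult", function(x) x@rowArgmax)

#' @describeIn GridResult-class best (window, r) per SD mode.
#' @export
setGeneric("globalArgmax", function(x) standardGeneric("globalArgmax"))
#' @rdname GridResult-class
#' @export
setMethod("globalArgmax", "GridResult", function(x) x@globalArgmax)

setMethod("show", "GridResult", function(object) {
  cat(sprintf(
    "GridResult %s vs %s: %d windows x %d r x %d SD modes (%d series)\n",
    object@group, object@pressure, length(object@windowLengthsS),
    length(object@rValues), length(object@sdModes), object@nSeries))
  print(object@globalArgmax, row.names = FALSE)
})

# ----------------------------------------------------------------- SignalGroup

#' SignalGroup: a calibrated group of myographic channels
#'
#' A group of channels of like nature ("oesEMGdi", "sEMG" or "absMMG") that
#' share one fixed tolerance, together with the individual (per-subject)
#' standard deviation fixing it.
#'
#' @slot groupLabel one of "oesEMGdi", "sEMG", "absMMG".
#' @slot members channel identifiers.
#' @slot individualSD per-subject reference SD in signal units (NA until
#'   calibrated).
#' @slot cohort "healthy" or "copd".
#' @name SignalGroup-class
#' @exportClass SignalGroup
setClass("SignalGroup",
         slots = c(groupLabel = "character", members = "character",
                   individualSD = "numeric", cohort = "character"))

setValidity("SignalGroup", function(object) {
  msg <- character()
  if (length(object@members) < 1L)
    msg <- c(msg, "'members' must be nonempty")
  if (!is.na(object@individualSD) && object@individualSD <= 0)
    msg <- c(msg, "'individualSD' must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalGroup
#' @param groupLabel group label.
#' @param members channel identifiers.
#' @param individualSD per-subject reference SD (optional).
#' @param cohort cohort label.
#' @return A [SignalGroup-class] object.
#' @export
SignalGroup <- function(groupLabel, members, individualSD = NA_real_,
                        cohort = "healthy") {
  new("SignalGroup", groupLabel = groupLabel, members = members,
      individualSD = as.numeric(individualSD), cohort = cohort)
}

setMethod("show", "SignalGroup", function(object) {
  cat(sprintf("SignalGroup '%s' (%s): %s; individual SD = %s\n",
              object@groupLabel, object@cohort,
              paste(object@members, collapse = ", "),
              format(object@individualSD)))
})

# ---------------------------------------------------------------- ProtocolSpec

#' ProtocolSpec: incremental threshold-loading protocol for the simulator
#'
#' Describes the simulated acquisition: per-channel-type sampling rates,
#' resting breathing plus incremental inspiratory threshold loads expressed as
#' fractions of a reference maximal inspiratory pressure (PImax), breaths per
#' condition and phase durations.
#'
#' @slot fsPressure pressure sampling rate in Hz.
#' @slot fsEmg EMG sampling rate in Hz.
#' @slot fsMmg MMG sampling rate in Hz.
#' @slot loadFractions increasing load fractions of PImax.
#' @slot breathsPerCondition breaths per condition.
#' @slot inspDurationS inspiratory phase duration in seconds.
#' @slot expDurationS expiratory phase duration in seconds.
#' @slot pimaxRef reference PImax in cmH2O.
#' @slot tidalAmplitude resting tidal mouth-pressure deflection in cmH2O.
#' @slot expAmplitude expiratory deflection amplitude in cmH2O.
#' @slot noiseSD additive pressure noise SD in cmH2O.
#' @name ProtocolSpec-class
#' @exportClass ProtocolSpec
setClass("ProtocolSpec",
         slots = c(fsPressure = "numeric", fsEmg = "numeric", fsMmg = "numeric",
                   loadFractions = "numeric", breathsPerCondition = "integer",
                   inspDurationS = "numeric", expDurationS = "numeric",
                   pimaxRef = "numeric", tidalAmplitude = "numeric",
                   expAmplitude = "numeric", noiseSD = "numeric"))

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (is.unsorted(object@loadFractions, strictly = TRUE))
    msg <- c(msg, "'loadFractions' must be strictly increasing")
  if (object@inspDurationS < 0.5 || object@expDurationS < 0.5)
    msg <- c(msg, "phase durations must be >= 0.5 s (minimum phase threshold)")
  if (any(c(object@fsPressure, object@fsEmg, object@fsMmg) <= 0))
    msg <- c(msg, "sampling rates must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ProtocolSpec
#'
#' Defaults mirror the incremental threshold-loading protocol the estimator is
#' designed for: loads at 12/24/36/48/60 % of PImax, at most 30 breaths per
#' condition, pressures at 100 Hz, EMG at 2000 Hz and MMG at 500 Hz.
#'
#' @param fsPressure,fsEmg,fsMmg sampling rates in Hz.
#' @param loadFractions load fractions of PImax (increasing).
#' @param breathsPerCondition breaths per condition (<= 30 in the protocol).
#' @param inspDurationS,expDurationS phase durations in seconds.
#' @param pimaxRef reference PImax in cmH2O.
#' @param tidalAmplitude resting tidal deflection in cmH2O.
#' @param expAmplitude expiratory deflection in cmH2O.
#' @param noiseSD additive pressure noise SD in cmH2O.
#' @return A [ProtocolSpec-class] object.
#' @export
protocolSpec <- function(fsPressure = 100, fsEmg = 2000, fsMmg = 500,
                         loadFractions = c(0.12, 0.24, 0.36, 0.48, 0.60),
                         breathsPerCondition = 30L,
                         inspDurationS = 1.5, expDurationS = 2.5,
                         pimaxRef = 100, tidalAmplitude = 2,
                         expAmplitude = 1, noiseSD = 0.05) {
  new("ProtocolSpec", fsPressure = fsPressure, fsEmg = fsEmg, fsMmg = fsMmg,
      loadFractions = loadFractions,
      breathsPerCondition = as.integer(breathsPerCondition),
      inspDurationS = inspDurationS, expDurationS = expDurationS,
      pimaxRef = pimaxRef, tidalAmplitude = tidalAmplitude,
      expAmplitude = expAmplitude, noiseSD = noiseSD)
}

#' @describeIn ProtocolSpec-class condition labels ("rest", "L1", ...).
#' @param x,object a `ProtocolSpec`.
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @rdname ProtocolSpec-class
#' @export
setMethod("conditionLabels", "ProtocolSpec", function(x)
  c("rest", paste0("L", seq_along(x@loadFractions))))

setMethod("show", "ProtocolSpec", function(object) {
  cat(sprintf(
    "ProtocolSpec: rest + loads %s x PImax(%g), %d breaths/condition, Ti=%g s, Te=%g s\n",
    paste(object@loadFractions, collapse = "/"), object@pimaxRef,
    object@breathsPerCondition, object@inspDurationS, object@expDurationS))
})

# ----------------------------------------------------------------- CardiacSpec

#' CardiacSpec: synthetic cardiac artifact train
#'
#' Parameterizes the quasi-periodic cardiac transients superimposed on the
#' synthetic muscle channels: heart rate, transient template (biphasic spike
#' for ECG-like interference on EMG, damped oscillation for MCG-like
#' interference on MMG), amplitude relative to the resting muscle-signal SD,
#' and beat-time jitter.
#'
#' @slot heartRateBpm heart rate in beats per minute (> 0).
#' @slot template "ecg" or "mcg".
#' @slot amplitudeRel transient amplitude as a multiple of the resting
#'   muscle-signal SD (>= 0).
#' @slot jitterSD beat-time jitter SD in seconds.
#' @name CardiacSpec-class
#' @exportClass CardiacSpec
setClass("CardiacSpec",
         slots = c(heartRateBpm = "numeric", template = "character",
                   amplitudeRel = "numeric", jitterSD = "numeric"))

setValidity("CardiacSpec", function(object) {
  msg <- character()
  if (object@heartRateBpm <= 0) msg <- c(msg, "'heartRateBpm' must be > 0")
  if (object@amplitudeRel < 0) msg <- c(msg, "'amplitudeRel' must be >= 0")
  if (!object@template %in% c("ecg", "mcg"))
    msg <- c(msg, "'template' must be 'ecg' or 'mcg'")
  if (length(msg)) msg else TRUE
})

#' Construct a CardiacSpec
#'
#' The default amplitude (3x the resting muscle-signal SD) makes cardiac
#' contamination dominate the raw trace at rest, which is the regime the
#' estimator is meant to be robust in.
#'
#' @param heartRateBpm heart rate in bpm.
#' @param template "ecg" (biphasic spike) or "mcg" (damped oscillation).
#' @param amplitudeRel amplitude relative to resting muscle SD.
#' @param jitterSD beat-time jitter SD in seconds.
#' @return A [CardiacSpec-class] object.
#' @export
cardiacSpec <- function(heartRateBpm = 75, template = "ecg",
                        amplitudeRel = 3, jitterSD = 0.05) {
  new("CardiacSpec", heartRateBpm = heartRateBpm, template = template,
      amplitudeRel = amplitudeRel, jitterSD = jitterSD)
}

setMethod("show", "CardiacSpec", function(object) {
  cat(sprintf("CardiacSpec: %g bpm, %s template, %gx rest SD, jitter %g s\n",
              object@heartRateBpm, object@template, object@amplitudeRel,
              object@jitterSD))
})

# --------------------------------------------------------------- SubjectRecord

#' SubjectRecord: a multichannel recording of one subject
#'
#' Bundles, per protocol condition, the myographic channels and pressure
#' channels of one subject, the group membership map, and (for synthetic
#' subjects) the ground-truth muscle-activity envelope. Channel lists are
#' named by condition; each element is a named list of
#' [SampledSignal-class] objects.
#'
#' @slot conditions condition labels in protocol order.
#' @slot channels per-condition named lists of myographic channels.
#' @slot pressures per-condition named lists of pressure channels
#'   (`pmo`, optionally `pdi`).
#' @slot envelope per-condition ground-truth envelope (may be empty).
#' @slot groups named list: group label -> member channel labels
#'   (post-preprocessing labels, i.e. accelerometer norms for MMG).
#' @slot cohort "healthy" or "copd".
#' @slot seed integer seed the record was generated from (NA for real data).
#' @slot preprocessed logical: has the conditioning chain been applied.
#' @name SubjectRecord-class
#' @exportClass SubjectRecord
setClass("SubjectRecord",
         slots = c(conditions = "character", channels = "list",
                   pressures = "list", envelope = "list", groups = "list",
                   cohort = "character", seed = "integer",
                   preprocessed = "logical"))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (!all(object@conditions %in% names(object@channels)))
    msg <- c(msg, "every condition needs an entry in 'channels'")
  if (!all(object@conditions %in% names(object@pressures)))
    msg <- c(msg, "every condition needs an entry in 'pressures'")
  if (length(msg)) msg else TRUE
})

#' @describeIn SubjectRecord-class number of myographic signals entering the
#'   evaluation (accelerometers count once, via their norm).
#' @param x,object a `SubjectRecord`.
#' @export
setGeneric("nMyographic", function(x) standardGeneric("nMyographic"))
#' @rdname SubjectRecord-class
#' @export
setMethod("nMyographic", "SubjectRecord", function(x)
  length(unlist(x@groups, use.names = FALSE)))

#' @describeIn SubjectRecord-class group membership map.
#' @export
setGeneric("signalGroups", function(x) standardGeneric("signalGroups"))
#' @rdname SubjectRecord-class
#' @export
setMethod("signalGroups", "SubjectRecord", function(x) x@groups)

#' @describeIn SubjectRecord-class condition labels.
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
#' @rdname SubjectRecord-class
#' @export
setMethod("conditions", "SubjectRecord", function(x) x@conditions)

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf(
    "SubjectRecord (%s%s): %d conditions (%s), %d myographic signals, groups: %s\n",
    object@cohort, if (object@preprocessed) ", preprocessed" else ", raw",
    length(object@conditions), paste(object@conditions, collapse = ", "),
    nMyographic(object), paste(names(object@groups), collapse = ", ")))
})
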