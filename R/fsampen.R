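# Fixed sample entropy: window-level estimator and moving-window series.

#' Fixed-tolerance sample entropy of one window
#'
#' Sample entropy of a single window with an externally fixed tolerance
#' (in signal units, not rescaled by the window's own SD). Counting follows
#' the standard SampEn convention: templates `i = 1..N-m` for both template
#' lengths, self-matches excluded, Chebyshev distance, and
#' `-log(A / B)` where `B` and `A` are the numbers of template pairs within
#' tolerance at lengths `m` and `m + 1`. Because the tolerance is fixed, the
#' value grows with signal amplitude as well as irregularity, which is what
#' lets a moving-window version act as an amplitude estimator.
#'
#' Degenerate counts: if `B = 0` the entropy is undefined and `NaN` is
#' returned with a warning; if `A = 0` with `B > 0` the value is capped at
#' its upper bound `-log(1 / B)` and the `"capped"` attribute is set.
#'
#' @param window numeric vector, length > `m + 1`.
#' @param m embedding dimension.
#' @param tolerance fixed similarity radius in signal units (> 0).
#' @return Entropy in nats (nonnegative), with logical attribute `"capped"`.
#' @examples
#' set.seed(1)
#' sampenFixed(rnorm(100), m = 2, tolerance = 0.2)
#' sampenFixed(rep(5, 100), m = 2, tolerance = 0.1)  # exactly 0
#' @export
sampenFixed <- function(window, m = 2L, tolerance) {
  window <- as.numeric(window)
  m <- as.integer(m)
  .stopifnotScalar(tolerance, "tolerance")
  if (tolerance <= 0) stop("'tolerance' must be positive")
  if (length(window) <= m + 1L)
    stop("window too short: need length > m + 1")
  if (!all(is.finite(window))) stop("window contains non-finite values")
  cnt <- .sampenPairCounts(window, m, tolerance)
  A <- cnt$A[1L]
  B <- cnt$B[1L]
  if (B == 0) {
    warning("no template matches at length m; entropy undefined (NaN)")
    return(structure(NaN, capped = FALSE))
  }
  if (A == 0)
    return(structure(log(B), capped = TRUE))
  structure(-log(A / B), capped = FALSE)
}

#' Moving-window start offsets
#'
#' Zero-based start offsets `0, step, 2*step, ...` of every full window of
#' `N` samples that fits in a signal of `n` samples; the trailing partial
#' window is dropped.
#'
#' @param nSamples total number of samples.
#' @param N window length in samples (`N <= nSamples`).
#' @param step hop size in samples (>= 1).
#' @return Integer vector of zero-based start offsets.
#' @examples
#' windowPositions(7, 5, 1)   # 0 1 2
#' length(windowPositions(20000, 1000, 100))  # 191
#' @export
windowPositions <- function(nSamples, N, step) {
  nSamples <- as.integer(nSamples)
  N <- as.integer(N)
  step <- as.integer(step)
  if (N > nSamples) stop("window length N exceeds the number of samples")
  if (step < 1L) stop("'step' must be >= 1")
  seq.int(0L, nSamples - N, by = step)
}

#' Moving-window fixed sample entropy
#'
#' Computes [sampenFixed()] in a moving window over a signal: window length
#' `N = round(windowLengthS * fs)` samples, hop
#' `step = max(1, round((1 - overlap) * N))`, trailing partial window
#' dropped. The tolerance is the one fixed in `params` and is identical for
#' every window. Each value equals `sampenFixed` applied independently to
#' the extracted window (no cross-window state). A warning (not an error) is
#' emitted when `N < 200` samples, the commonly cited minimum window length
#' for reliable moving-window sample entropy.
#'
#' @param signal a [SampledSignal-class].
#' @param params an [FSampEnParams-class].
#' @return An [EntropySeries-class] with window-centre timestamps.
#' @examples
#' set.seed(1)
#' s <- SampledSignal(rnorm(5000), fs = 500, label = "noise")
#' p <- FSampEnParams(m = 2, tolerance = 0.5, windowLengthS = 0.5,
#'                    overlap = 0.9)
#' es <- movingFSampEn(s, p)
#' length(es)
#' @export
movingFSampEn <- function(signal, params) {
  stopifnot(is(signal, "SampledSignal"), is(params, "FSampEnParams"))
  fs <- samplingRate(signal)
  x <- samples(signal)
  N <- windowSamples(params, fs)
  if (N <= params@m + 1L)
    stop("window of ", N, " samples too short for m = ", params@m)
  if (N > length(x))
    stop("signal shorter than one window (", N, " samples)")
  if (N < 200L)
    warning("window of ", N, " samples is below the recommended minimum of ",
            "200 samples for moving-window sample entropy")
  step <- max(1L, as.integer(round((1 - params@overlap) * N)))
  cnt <- .movingSampenCounts(x, N, step, params@m, tolerance(params))
  .entropySeriesFromCounts(cnt$A[, 1L], cnt$B[, 1L], signal, N, step, params)
}

# shared assembly of an EntropySeries from pair counts
.entropySeriesFromCounts <- function(A, B, signal, N, step, params) {
  values <- rep(NaN, length(B))
  capped <- A == 0 & B > 0
  ok <- A > 0 & B > 0
  values[ok] <- -log(A[ok] / B[ok])
  values[capped] <- log(B[capped])
  if (any(B == 0))
    warning(sum(B == 0), " window(s) had no template matches; NaN returned")
  offsets <- seq.int(0L, by = step, length.out = length(values))
  times <- startTime(signal) + (offsets + (N - 1) / 2) / samplingRate(signal)
  new("EntropySeries", values = values, times = times, params = params,
      sourceLabel = signalLabel(signal), capped = capped)
}

#' Moving-window RMS amplitude estimator
#'
#' Root mean square over the same moving windows as [movingFSampEn()]
#' (same `N`, hop and timestamps). This is the conventional amplitude
#' estimator that fixed sample entropy is compared against: it responds
#' strongly to high-amplitude cardiac transients, whereas the entropy of a
#' quasi-deterministic transient is comparatively low.
#'
#' @param signal a [SampledSignal-class].
#' @param windowLengthS window length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return data.frame with columns `time` (window centre, s) and `value`.
#' @export
movingRMS <- function(signal, windowLengthS = 0.5, overlap = 0.9) {
  stopifnot(is(signal, "SampledSignal"))
  fs <- samplingRate(signal)
  x <- samples(signal)
  N <- as.integer(round(windowLengthS * fs))
  if (N < 1L || N > length(x))
    stop("invalid window length for this signal")
  step <- max(1L, as.integer(round((1 - overlap) * N)))
  off <- windowPositions(length(x), N, step)
  vals <- vapply(off, function(o) sqrt(mean(x[(o + 1L):(o + N)]^2)), 0)
  data.frame(time = startTime(signal) + (off + (N - 1) / 2) / fs,
             value = vals)
}

#' Proposed general fSampEn parameters per signal group
#'
#' The general-purpose parameter set recommended for inspiratory muscle
#' activity estimation: 0.5 s moving window with 90% overlap, `m = 2`, and a
#' group-specific fixed tolerance of `r x SD` with `r = 0.05` and
#' `SD = 0.0121` V for oesophageal diaphragm EMG, `r = 0.3` and
#' `SD = 0.0022` V for surface EMG, and `r = 0.5` and `SD = 0.0060` g for
#' accelerometer MMG norms.
#'
#' @param group one of `"oesEMGdi"`, `"sEMG"`, `"absMMG"`.
#' @return An [FSampEnParams-class].
#' @examples
#' tolerance(generalParams("sEMG"))  # 0.3 * 0.0022
#' @export
generalParams <- function(group = c("oesEMGdi", "sEMG", "absMMG")) {
  group <- match.arg(group)
  pars <- switch(group,
    oesEMGdi = c(r = 0.05, sd = 0.0121),
    sEMG     = c(r = 0.30, sd = 0.0022),
    absMMG   = c(r = 0.50, sd = 0.0060))
  FSampEnParams(m = 2L, r = pars[["r"]], sdRef = pars[["sd"]],
                windowLengthS = 0.5, overlap = 0.9)
}
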