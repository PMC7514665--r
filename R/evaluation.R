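# Scoring of fSampEn time-series against pressure signals by maximum
# normalized cross-covariance, the full (window, r, SD-mode) parameter grid,
# cohort summaries and individual-vs-global parameter comparisons.

# core: per-lag Pearson (or raw covariance) after aligning the pressure onto
# the entropy time grid; windows with undefined entropy are dropped first
.maxCrossCovCore <- function(times, values, pressure, maxLagS, negatePressure,
                             normalized) {
  stopifnot(is(pressure, "SampledSignal"))
  ok <- is.finite(values)
  times <- times[ok]
  values <- values[ok]
  p <- samples(pressure)
  if (negatePressure) p <- -p
  pi <- stats::approx(sampleTimes(pressure), p, xout = times, rule = 2)$y
  n <- length(values)
  if (n < 10L) stop("fewer than 10 overlapping points after alignment")
  if (stats::sd(values) == 0 || stats::sd(pi) == 0)
    stop("degenerate (zero-variance) series")
  dt <- stats::median(diff(times))
  L <- as.integer(floor(maxLagS / dt + 1e-9))
  cc <- .crossPearson(values, pi, L, normalized)
  k <- which.max(cc) # NA lags are never the max
  list(cmax = cc[k], lagS = (k - 1L - L) * dt, lagSteps = k - 1L - L)
}

#' Maximum cross-covariance between an entropy series and a pressure
#'
#' Measures how well an amplitude-estimate time-series tracks the pressure
#' generated by the inspiratory muscles. Because both series have non-zero
#' mean, similarity is the maximum over lags of the mean-removed,
#' variance-normalized cross-covariance (a Pearson correlation at each
#' integer-step lag, values in `[-1, 1]`); the raw mean-removed covariance is
#' available with `normalized = FALSE`. The pressure is linearly interpolated
#' onto the (coarser) entropy time grid, and, when `negatePressure` is TRUE,
#' negated first so that inspiratory-negative mouth-pressure deflections
#' become effort-positive like the entropy bumps. Positive lag means the
#' entropy series is delayed relative to the pressure.
#'
#' The result is invariant to positive affine transforms of either series.
#'
#' @param entropy an [EntropySeries-class], or a data.frame with columns
#'   `time` and `value` (e.g. from [movingRMS()]).
#' @param pressure a [SampledSignal-class].
#' @param maxLagS lag search bound in seconds (default 5, the physiological
#'   breathing-cycle scale).
#' @param negatePressure negate the pressure before correlating (TRUE for
#'   inspiratory-negative mouth pressure; use FALSE for transdiaphragmatic
#'   pressure, which is already effort-positive).
#' @param normalized Pearson-at-lag normalization (default) or raw
#'   mean-removed covariance.
#' @return List with `cmax`, `lagS` and `lagSteps`.
#' @examples
#' set.seed(2)
#' s <- SampledSignal(rnorm(4000), 500)
#' p <- FSampEnParams(m = 2, tolerance = 1, windowLengthS = 0.5, overlap = 0.9)
#' es <- movingFSampEn(s, p)
#' prs <- SampledSignal(-entropyValues(es), fs = 1 / 0.05,
#'                      t0 = entropyTimes(es)[1])
#' maxCrossCov(es, prs)$cmax  # 1 at lag 0
#' @export
maxCrossCov <- function(entropy, pressure, maxLagS = 5,
                        negatePressure = TRUE, normalized = TRUE) {
  if (is(entropy, "EntropySeries")) {
    .maxCrossCovCore(entropyTimes(entropy), entropyValues(entropy), pressure,
                     maxLagS, negatePressure, normalized)
  } else if (is.data.frame(entropy)) {
    .maxCrossCovCore(entropy$time, entropy$value, pressure, maxLagS,
                     negatePressure, normalized)
  } else stop("'entropy' must be an EntropySeries or a time/value data.frame")
}

#' Enumerate the evaluation grid
#'
#' One row per fSampEn time-series the full parameter evaluation computes:
#' every combination of myographic signal, protocol condition, window length,
#' tolerance multiplier `r` and SD mode. For the standard protocol (rest +
#' five loads) this yields 14,256 series for a healthy-montage subject
#' (11 signals) and 5,184 for a COPD-montage subject (4 signals).
#'
#' @param record a [SubjectRecord-class]; alternatively give `signals` and
#'   `conditionNames` directly.
#' @param signals character vector of signal labels.
#' @param conditionNames character vector of condition labels.
#' @param windowLengthsS grid of window lengths in seconds.
#' @param rValues grid of tolerance multipliers.
#' @param sdModes SD modes.
#' @return data.frame with columns signal, condition, windowS, r, sdMode.
#' @examples
#' nrow(enumerateGrid(signals = paste0("ch", 1:11),
#'                    conditionNames = c("rest", paste0("L", 1:5))))
#' @export
enumerateGrid <- function(record = NULL, signals = NULL, conditionNames = NULL,
                          windowLengthsS = seq(0.1, 0.5, by = 0.05),
                          rValues = seq(0.05, 0.6, by = 0.05),
                          sdModes = c("individual", "global")) {
  if (!is.null(record)) {
    stopifnot(is(record, "SubjectRecord"))
    signals <- unlist(record@groups, use.names = FALSE)
    conditionNames <- record@conditions
  }
  if (is.null(signals) || is.null(conditionNames))
    stop("supply either 'record' or both 'signals' and 'conditionNames'")
  expand.grid(signal = signals, condition = conditionNames,
              windowS = windowLengthsS, r = rValues, sdMode = sdModes,
              stringsAsFactors = FALSE)
}

# argmax helpers with deterministic tie-breaking: smaller r, then smaller
# window (grid scanned r-fastest within ascending windows)
.gridArgmax <- function(mat, windows, rs) {
  best <- -Inf
  bi <- c(NA_integer_, NA_integer_)
  for (ri in seq_along(rs)) {
    for (wi in seq_along(windows)) {
      v <- mat[wi, ri]
      if (is.finite(v) && v > best + 1e-15) {
        best <- v
        bi <- c(wi, ri)
      }
    }
  }
  list(wi = bi[1L], ri = bi[2L], value = best)
}

.rowArgmax <- function(row, rs) {
  best <- -Inf
  bi <- NA_integer_
  for (ri in seq_along(rs)) {
    if (is.finite(row[ri]) && row[ri] > best + 1e-15) {
      best <- row[ri]
      bi <- ri
    }
  }
  list(ri = bi, value = best)
}

.annotateGrid <- function(cmax, windows, rs, modes, group, pressure, nSeries) {
  rowA <- do.call(rbind, lapply(seq_along(modes), function(mi) {
    do.call(rbind, lapply(seq_along(windows), function(wi) {
      a <- .rowArgmax(cmax[wi, , mi], rs)
      data.frame(sdMode = modes[mi], windowS = windows[wi], bestR = rs[a$ri],
                 cmax = a$value, stringsAsFactors = FALSE)
    }))
  }))
  glbA <- do.call(rbind, lapply(seq_along(modes), function(mi) {
    a <- .gridArgmax(matrix(cmax[, , mi], length(windows), length(rs)),
                     windows, rs)
    data.frame(sdMode = modes[mi], windowS = windows[a$wi], r = rs[a$ri],
               cmax = a$value, stringsAsFactors = FALSE)
  }))
  new("GridResult", windowLengthsS = windows, rValues = rs, sdModes = modes,
      cmax = cmax, rowArgmax = rowA, globalArgmax = glbA, group = group,
      pressure = pressure, nSeries = as.integer(nSeries))
}

#' Evaluate the full fSampEn parameter grid for one subject
#'
#' For every combination of window length, tolerance multiplier `r` and SD
#' mode, and for every member signal of each group and every condition,
#' computes the moving-window fSampEn series (fixed tolerance
#' `r x SD(group, mode)`) and its maximum normalized cross-covariance against
#' each designated pressure; the `c_max` values are then averaged, unweighted,
#' over member signals and conditions, giving one matrix per (group,
#' pressure) pair.
#'
#' The multi-tolerance Rcpp kernel shares one pair-counting sweep per window
#' across the whole tolerance grid, so the grid costs little more than a
#' single-tolerance pass.
#'
#' @param record a preprocessed [SubjectRecord-class].
#' @param calibration list with `individual` and `global`: named numerics
#'   (group -> reference SD). For a single subject, `individual` is that
#'   subject's calibration ([calibrateSubject()]); `global` the cohort's.
#' @param windowLengthsS,rValues,sdModes the grid axes.
#' @param m embedding dimension.
#' @param overlap window overlap fraction.
#' @param maxLagS lag bound for [maxCrossCov()].
#' @param pressures pressure labels to score against (default: all present,
#'   i.e. `pmo` and, when recorded, `pdi`).
#' @param pressureSigns named logicals: negate this pressure before
#'   correlating (default TRUE for `pmo`, FALSE for `pdi`).
#' @param groups group labels to evaluate (default all).
#' @return Named list `"<group>.<pressure>"` -> [GridResult-class].
#' @export
gridEvaluate <- function(record, calibration,
                         windowLengthsS = seq(0.1, 0.5, by = 0.05),
                         rValues = seq(0.05, 0.6, by = 0.05),
                         sdModes = c("individual", "global"),
                         m = 2L, overlap = 0.9, maxLagS = 5,
                         pressures = NULL, pressureSigns = NULL,
                         groups = names(record@groups)) {
  stopifnot(is(record, "SubjectRecord"))
  if (!record@preprocessed)
    warning("evaluating a raw record; run preprocessSubject() first")
  if (is.null(pressures))
    pressures <- names(record@pressures[[record@conditions[1L]]])
  for (p in pressures)
    if (is.null(record@pressures[[record@conditions[1L]]][[p]]))
      stop("missing pressure channel: ", p)
  if (is.null(pressureSigns))
    pressureSigns <- c(pmo = TRUE, pdi = FALSE)[pressures]
  nw <- length(windowLengthsS)
  nr <- length(rValues)
  nmode <- length(sdModes)
  out <- list()
  for (g in groups) {
    sds <- vapply(sdModes, function(md) {
      v <- calibration[[md]][[g]]
      if (is.null(v) || !is.finite(v) || v <= 0)
        stop("no valid ", md, " SD for group ", g)
      v
    }, 0)
    # flattened tolerance grid, sorted for the kernel
    tolGrid <- as.vector(outer(rValues, sds)) # nr x nmode
    ord <- order(tolGrid)
    tolSorted <- tolGrid[ord]
    inv <- order(ord)
    acc <- lapply(pressures, function(p) array(0, dim = c(nw, nr, nmode)))
    names(acc) <- pressures
    cnt <- 0L
    for (ch in record@groups[[g]]) {
      for (cond in record@conditions) {
        sig <- record@channels[[cond]][[ch]]
        if (is.null(sig)) stop("channel ", ch, " missing in ", cond)
        fs <- samplingRate(sig)
        x <- samples(sig)
        for (wi in seq_len(nw)) {
          N <- as.integer(round(windowLengthsS[wi] * fs))
          step <- max(1L, as.integer(round((1 - overlap) * N)))
          kc <- .movingSampenCounts(x, N, step, m, tolSorted)
          off <- seq.int(0L, by = step, length.out = nrow(kc$A))
          times <- startTime(sig) + (off + (N - 1) / 2) / fs
          for (ri in seq_len(nr)) {
            for (mi in seq_len(nmode)) {
              col <- inv[(mi - 1L) * nr + ri]
              A <- kc$A[, col]
              B <- kc$B[, col]
              vals <- rep(NaN, length(B))
              okc <- A > 0 & B > 0
              vals[okc] <- -log(A[okc] / B[okc])
              cap <- A == 0 & B > 0
              vals[cap] <- log(B[cap])
              for (p in pressures) {
                # a tolerance far above the signal amplitude yields a
                # constant (all-matching) entropy series; such a series
                # carries no amplitude information and contributes c_max = 0
                fin <- vals[is.finite(vals)]
                cm <- if (length(fin) < 10L || stats::sd(fin) == 0) 0 else
                  .maxCrossCovCore(times, vals,
                                   record@pressures[[cond]][[p]],
                                   maxLagS, pressureSigns[[p]], TRUE)$cmax
                acc[[p]][wi, ri, mi] <- acc[[p]][wi, ri, mi] + cm
              }
            }
          }
        }
        cnt <- cnt + 1L
      }
    }
    nSeries <- cnt * nw * nr * nmode
    for (p in pressures) {
      cm <- acc[[p]] / cnt
      dimnames(cm) <- list(windowS = format(windowLengthsS),
                           r = format(rValues), sdMode = sdModes)
      out[[paste(g, p, sep = ".")]] <-
        .annotateGrid(cm, windowLengthsS, rValues, sdModes, g, p, nSeries)
    }
  }
  out
}

#' Average grid results across a cohort
#'
#' Elementwise mean of per-subject `c_max` matrices for the same (group,
#' pressure) pair, with the per-row and global argmax annotations recomputed
#' on the mean matrix (ties broken toward smaller `r`, then smaller window).
#'
#' @param gridResults list of [GridResult-class] objects with identical axes.
#' @return A [GridResult-class] holding the cohort-mean matrix.
#' @export
summarizeCohort <- function(gridResults) {
  if (length(gridResults) == 0L) stop("empty cohort")
  ref <- gridResults[[1L]]
  for (gr in gridResults[-1L]) {
    if (!identical(dim(gr@cmax), dim(ref@cmax)) ||
        !isTRUE(all.equal(gr@windowLengthsS, ref@windowLengthsS)) ||
        !isTRUE(all.equal(gr@rValues, ref@rValues)))
      stop("grid shape mismatch across subjects")
  }
  cm <- Reduce(`+`, lapply(gridResults, cmaxArray)) / length(gridResults)
  .annotateGrid(cm, ref@windowLengthsS, ref@rValues, ref@sdModes, ref@group,
                ref@pressure, sum(vapply(gridResults,
                                         function(g) g@nSeries, 0L)))
}

#' Individual vs global parameter comparison
#'
#' At a fixed window length: `cInd` is the subject's best `c_max` over `r`
#' using the individual SD; `cGlob` is the `c_max` at the cohort-global `r`
#' using the global SD; and the effect of switching to global parameters is
#' `deltaPct = 100 * |cGlob - cInd| / cInd`, which is zero exactly when the
#' global parameters are that subject's optimum.
#'
#' @param grid the subject's [GridResult-class] for one (group, pressure).
#' @param windowS window length at which to compare (default 0.5 s).
#' @param globalR the cohort-global tolerance multiplier.
#' @return data.frame with `windowS`, `indR`, `cInd`, `globalR`, `cGlob`,
#'   `deltaPct`.
#' @export
deltaCmax <- function(grid, windowS = 0.5, globalR) {
  stopifnot(is(grid, "GridResult"))
  wi <- which(abs(grid@windowLengthsS - windowS) < 1e-9)
  if (length(wi) != 1L) stop("windowS not on the evaluated grid")
  ri <- which(abs(grid@rValues - globalR) < 1e-9)
  if (length(ri) != 1L) stop("globalR not on the evaluated grid")
  if (!"individual" %in% grid@sdModes || !"global" %in% grid@sdModes)
    stop("grid must contain both SD modes")
  rowInd <- grid@cmax[wi, , match("individual", grid@sdModes)]
  a <- .rowArgmax(rowInd, grid@rValues)
  cInd <- a$value
  cGlob <- grid@cmax[wi, ri, match("global", grid@sdModes)]
  if (!is.finite(cInd) || cInd == 0)
    stop("individual-optimal c_max is zero or undefined")
  data.frame(windowS = windowS, indR = grid@rValues[a$ri], cInd = cInd,
             globalR = globalR, cGlob = cGlob,
             deltaPct = 100 * abs(cGlob - cInd) / cInd)
}

#' Long-format grid table
#'
#' Flattens one or more [GridResult-class] objects into the long-format
#' exchange table (group, pressure, windowS, r, sdMode, cmax).
#'
#' @param gridResults a [GridResult-class] or list of them.
#' @return data.frame.
#' @export
gridTable <- function(gridResults) {
  if (is(gridResults, "GridResult")) gridResults <- list(gridResults)
  do.call(rbind, lapply(gridResults, function(g) {
    d <- expand.grid(windowS = g@windowLengthsS, r = g@rValues,
                     sdMode = g@sdModes, stringsAsFactors = FALSE)
    d$cmax <- as.vector(g@cmax)
    cbind(data.frame(group = g@group, pressure = g@pressure,
                     stringsAsFactors = FALSE), d)
  }))
}
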