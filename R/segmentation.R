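# Breath segmentation from mouth pressure and tolerance calibration
# (individual / global reference SDs per signal group).

#' Detect respiratory phases by zero-crossing on mouth pressure
#'
#' Splits the record into alternating inspiratory / expiratory phases at the
#' zero crossings of the mouth pressure signal, with sub-sample boundary
#' timing by linear interpolation. Phase labels follow the polarity setting:
#' with `"inspiratory-negative"` (the physiological default for
#' threshold-loaded breathing through a mouthpiece) negative-pressure
#' intervals are inspiratory. Phases shorter than `minDurationS` are merged
#' into the preceding phase (the leading phase, having no predecessor, is
#' merged into the following one), so brief spurious sign flips are absorbed
#' and alternation is preserved. Segmentation is invariant to positive
#' rescaling of the pressure signal.
#'
#' @param pmo mouth pressure ([SampledSignal-class]).
#' @param polarity `"inspiratory-negative"` or `"inspiratory-positive"`.
#' @param minDurationS minimum phase duration in seconds (default 0.5).
#' @return A [BreathSegmentation-class].
#' @examples
#' t <- (0:1999) / 100
#' pmo <- SampledSignal(-sin(2 * pi * t / 4), 100, "Pmo", "cmH2O")
#' seg <- detectPhases(pmo)
#' nCycles(seg)  # 5
#' @export
detectPhases <- function(pmo, polarity = c("inspiratory-negative",
                                           "inspiratory-positive"),
                         minDurationS = 0.5) {
  stopifnot(is(pmo, "SampledSignal"))
  polarity <- match.arg(polarity)
  x <- samples(pmo)
  tt <- sampleTimes(pmo)
  n <- length(x)
  sgn <- sign(x)
  nz <- which(sgn != 0)
  if (length(nz) == 0L) stop("no respiratory cycles detected")
  # carry last nonzero sign across exact zeros (leading zeros take the first)
  filled <- sgn
  filled[seq_len(nz[1L] - 1L)] <- sgn[nz[1L]]
  for (i in seq.int(nz[1L] + 1L, length.out = max(0L, n - nz[1L]))) {
    if (filled[i] == 0) filled[i] <- filled[i - 1L]
  }
  flip <- which(filled[-n] != filled[-1L])
  if (length(flip) == 0L) stop("no respiratory cycles detected")
  crossT <- vapply(flip, function(i) {
    x1 <- x[i]; x2 <- x[i + 1L]
    if (x1 == 0) tt[i]
    else if (x2 == x1) tt[i]
    else tt[i] + (0 - x1) / (x2 - x1) * (tt[i + 1L] - tt[i])
  }, 0)
  bounds <- c(tt[1L], crossT, tt[n] + 1 / samplingRate(pmo))
  segSign <- filled[c(flip, n)] # sign of the samples inside each segment
  start <- bounds[-length(bounds)]
  end <- bounds[-1L]
  keep <- end - start > 0
  start <- start[keep]; end <- end[keep]; segSign <- segSign[keep]
  inspSign <- if (polarity == "inspiratory-negative") -1 else 1
  label <- ifelse(segSign == inspSign, "inspiratory", "expiratory")

  # merge sub-minimum phases into the preceding phase, coalescing equal labels
  repeat {
    dur <- end - start
    if (length(dur) <= 1L) break
    short <- which(dur < minDurationS - 1e-9)
    if (length(short) == 0L) break
    i <- short[1L]
    if (i == 1L) { # absorb into the following phase
      start[2L] <- start[1L]
      start <- start[-1L]; end <- end[-1L]; label <- label[-1L]
    } else {
      end[i - 1L] <- end[i]
      start <- start[-i]; end <- end[-i]; label <- label[-i]
    }
    # coalesce neighbours that now share a label
    j <- 1L
    while (j < length(label)) {
      if (label[j] == label[j + 1L]) {
        end[j] <- end[j + 1L]
        start <- start[-(j + 1L)]; end <- end[-(j + 1L)]
        label <- label[-(j + 1L)]
      } else j <- j + 1L
    }
  }
  new("BreathSegmentation", start = start, end = end, label = label,
      minDurationS = minDurationS)
}

#' Remove excluded breath cycles from a segmentation
#'
#' Cycles are indexed by their inspiratory phase, in time order. Excluding a
#' cycle removes its inspiratory phase and the following expiratory phase
#' from all downstream computations (both SD calibration and evaluation).
#' An empty exclusion list is the identity.
#'
#' @param segmentation a [BreathSegmentation-class].
#' @param excluded integer indices of cycles to drop (1-based).
#' @return The pruned [BreathSegmentation-class].
#' @export
applyExclusions <- function(segmentation, excluded = integer()) {
  stopifnot(is(segmentation, "BreathSegmentation"))
  if (length(excluded) == 0L) return(segmentation)
  excluded <- as.integer(excluded)
  insp <- which(segmentation@label == "inspiratory")
  if (any(excluded < 1L | excluded > length(insp)))
    stop("excluded cycle index out of range (1..", length(insp), ")")
  drop <- integer()
  for (k in excluded) {
    i <- insp[k]
    drop <- c(drop, i)
    if (i < length(segmentation@label) &&
        segmentation@label[i + 1L] == "expiratory")
      drop <- c(drop, i + 1L)
  }
  keep <- setdiff(seq_along(segmentation@label), drop)
  # removing an (inspiratory, expiratory) pair preserves label alternation;
  # the resulting timeline simply has a gap where the cycle was
  new("BreathSegmentation", start = segmentation@start[keep],
      end = segmentation@end[keep], label = segmentation@label[keep],
      minDurationS = segmentation@minDurationS)
}

#' Extract the samples of one phase type from a channel
#'
#' Concatenates the samples of a channel falling inside every kept phase of
#' the requested type (half-open intervals, `[start, end)`), using the
#' channel's own time base.
#'
#' @param signal a [SampledSignal-class].
#' @param segmentation a [BreathSegmentation-class].
#' @param phase `"inspiratory"` or `"expiratory"`.
#' @return Numeric vector of concatenated samples.
#' @export
phaseSamples <- function(signal, segmentation, phase = "inspiratory") {
  stopifnot(is(signal, "SampledSignal"), is(segmentation, "BreathSegmentation"))
  tt <- sampleTimes(signal)
  x <- samples(signal)
  sel <- segmentation@label == phase
  out <- vector("list", sum(sel))
  k <- 0L
  for (i in which(sel)) {
    k <- k + 1L
    out[[k]] <- x[tt >= segmentation@start[i] & tt < segmentation@end[i]]
  }
  unlist(out, use.names = FALSE)
}

#' Individual reference SD of a signal group
#'
#' For each member channel: concatenate all kept inspiratory samples across
#' all conditions (resting breathing and every threshold load) and compute
#' one standard deviation (population formula, divide by n). The individual
#' SD of the group is the arithmetic mean of the member-channel SDs. The
#' result is invariant to the order of conditions and channels.
#'
#' @param signalsByChannel named list: channel label -> named list of
#'   [SampledSignal-class] per condition.
#' @param segByCondition named list: condition -> [BreathSegmentation-class].
#' @return Positive scalar, the group's individual SD in signal units.
#' @export
individualSD <- function(signalsByChannel, segByCondition) {
  if (length(signalsByChannel) == 0L) stop("empty signal group")
  sds <- vapply(signalsByChannel, function(byCond) {
    xs <- unlist(lapply(names(byCond), function(cond) {
      seg <- segByCondition[[cond]]
      if (is.null(seg)) stop("missing segmentation for condition ", cond)
      phaseSamples(byCond[[cond]], seg, "inspiratory")
    }), use.names = FALSE)
    if (length(xs) == 0L) stop("empty inspiratory sample set for a channel")
    .popSD(xs)
  }, 0)
  mean(sds)
}

#' Global reference SD
#'
#' The cohort-level reference SD for a signal group: the arithmetic mean of
#' the per-subject individual SDs.
#'
#' @param individualSDs positive per-subject SDs.
#' @return Their mean.
#' @examples
#' globalSD(c(0.002, 0.004))  # 0.003
#' @export
globalSD <- function(individualSDs) {
  if (length(individualSDs) == 0L) stop("empty set of individual SDs")
  if (any(individualSDs <= 0)) stop("individual SDs must be positive")
  mean(individualSDs)
}

#' Segment every condition of a subject record
#'
#' Runs [detectPhases()] on the mouth pressure of each condition and applies
#' any per-condition exclusion lists.
#'
#' @param record a [SubjectRecord-class].
#' @param polarity passed to [detectPhases()].
#' @param minDurationS passed to [detectPhases()].
#' @param exclusions optional named list: condition -> excluded cycle indices.
#' @return Named list: condition -> [BreathSegmentation-class].
#' @export
segmentSubject <- function(record, polarity = "inspiratory-negative",
                           minDurationS = 0.5, exclusions = list()) {
  stopifnot(is(record, "SubjectRecord"))
  segs <- lapply(record@conditions, function(cond) {
    seg <- detectPhases(record@pressures[[cond]]$pmo, polarity = polarity,
                        minDurationS = minDurationS)
    if (!is.null(exclusions[[cond]]))
      seg <- applyExclusions(seg, exclusions[[cond]])
    seg
  })
  names(segs) <- record@conditions
  segs
}

#' Calibrate individual SDs for every signal group of a subject
#'
#' Computes [individualSD()] for each group of a (preprocessed) subject
#' record, using the subject's breath segmentation.
#'
#' @param record a preprocessed [SubjectRecord-class].
#' @param segmentations named list: condition -> [BreathSegmentation-class]
#'   (default: computed by [segmentSubject()]).
#' @return Named numeric: group label -> individual SD.
#' @export
calibrateSubject <- function(record, segmentations = segmentSubject(record)) {
  stopifnot(is(record, "SubjectRecord"))
  if (!record@preprocessed)
    warning("calibrating on a raw record; reference SDs are normally ",
            "computed on preprocessed signals")
  out <- vapply(names(record@groups), function(g) {
    members <- record@groups[[g]]
    byChan <- lapply(members, function(ch) {
      byCond <- lapply(record@conditions, function(cond) {
        s <- record@channels[[cond]][[ch]]
        if (is.null(s)) stop("channel ", ch, " missing in condition ", cond)
        s
      })
      names(byCond) <- record@conditions
      byCond
    })
    names(byChan) <- members
    individualSD(byChan, segmentations)
  }, 0)
  out
}

#' Cohort calibration: individual and global SDs
#'
#' Collects per-subject individual SDs for every group and derives the
#' cohort's global SD per group as the mean of the individual SDs.
#'
#' @param individualBySubject list of named numerics as returned by
#'   [calibrateSubject()], one per subject.
#' @return List with `individual` (data.frame subjects x groups) and
#'   `global` (named numeric per group).
#' @export
cohortCalibration <- function(individualBySubject) {
  if (length(individualBySubject) == 0L) stop("empty cohort")
  groups <- names(individualBySubject[[1L]])
  ind <- do.call(rbind, lapply(individualBySubject, function(v)
    as.data.frame(as.list(v[groups]))))
  names(ind) <- groups
  rownames(ind) <- names(individualBySubject) %||%
    paste0("S", seq_along(individualBySubject))
  list(individual = ind,
       global = vapply(groups, function(g) globalSD(ind[[g]]), 0))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Export a segmentation as an interval table
#'
#' Writes (or returns) the phases as a three-column table
#' (start s, end s, label), the exchange format used by the command-line
#' pipeline.
#'
#' @param segmentation a [BreathSegmentation-class].
#' @param path optional output path (tab-separated); omit to just get the
#'   data.frame.
#' @return The data.frame, invisibly when written.
#' @export
exportSegmentation <- function(segmentation, path = NULL) {
  df <- phases(segmentation)
  if (!is.null(path)) {
    utils::write.table(format(df, digits = 17), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
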