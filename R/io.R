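# Multichannel recording IO. The reference format is human-inspectable
# delimited text: one directory per recording with a yaml sidecar declaring
# per-channel rate/units and one plain-text sample file per channel (full
# double precision, so a write/read round trip is bit-identical). A minimal
# EDF (European Data Format, 16-bit) reader/writer is provided for realism;
# EDF quantizes to 16 bits, so its round trip is only exact to quantization.

#' Write a multichannel recording as delimited text
#'
#' @param signals named list of [SampledSignal-class] objects (mixed rates
#'   allowed).
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(signals, path) {
  stopifnot(length(signals) > 0)
  if (is.null(names(signals)) || any(!nzchar(names(signals))))
    names(signals) <- vapply(signals, signalLabel, "")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(channels = lapply(names(signals), function(nm) {
    s <- signals[[nm]]
    stopifnot(is(s, "SampledSignal"))
    list(label = signalLabel(s), fs = samplingRate(s),
         units = signalUnits(s), t0 = startTime(s), n = length(s),
         file = paste0(.fileSlug(nm), ".txt"))
  }))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  for (nm in names(signals)) {
    writeLines(sprintf("%.17g", samples(signals[[nm]])),
               file.path(path, paste0(.fileSlug(nm), ".txt")))
  }
  invisible(path)
}

#' Read a multichannel recording
#'
#' @param path recording directory (delimited format) or `.edf` file.
#' @param format `"delimited"` or `"edf"`.
#' @return Named list of [SampledSignal-class] objects with per-channel
#'   rates and units preserved.
#' @export
readRecording <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(readEDF(path))
  metaPath <- file.path(path, "meta.yaml")
  if (!file.exists(metaPath)) stop("no meta.yaml in ", path)
  meta <- yaml::read_yaml(metaPath)
  out <- list()
  for (ch in meta$channels) {
    if (is.null(ch$fs)) stop("channel '", ch$label, "' declares no fs")
    if (is.null(ch$units)) stop("channel '", ch$label, "' declares no units")
    x <- scan(file.path(path, ch$file), what = double(), quiet = TRUE)
    if (!is.null(ch$n) && length(x) != ch$n)
      stop("ragged channel '", ch$label, "': expected ", ch$n,
           " samples, found ", length(x))
    out[[ch$label]] <- SampledSignal(x, ch$fs, label = ch$label,
                                     units = ch$units,
                                     t0 = ch$t0 %||% 0)
  }
  out
}

.edfPad <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  sprintf("%-*s", width, s)
}

# most precise decimal representation of x that fits the 8-char EDF fields
.edf8num <- function(x) {
  for (p in 7:1) {
    s <- sprintf("%.*g", p, x)
    if (nchar(s) <= 8L) return(s)
  }
  stop("value not representable in an 8-character EDF field: ", x)
}

#' Write an EDF file
#'
#' Minimal EDF (16-bit) writer supporting mixed per-channel sampling rates
#' via per-signal samples-per-record counts. Signals are truncated to a whole
#' number of 1-second data records; values are linearly quantized to the
#' 16-bit digital range between each channel's physical min/max.
#'
#' @param signals named list of [SampledSignal-class] objects.
#' @param path output `.edf` file.
#' @param recordDurationS data-record duration in seconds; each channel's
#'   `fs * recordDurationS` must be an integer.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(signals, path, recordDurationS = 1) {
  stopifnot(length(signals) > 0)
  if (is.null(names(signals)) || any(!nzchar(names(signals))))
    names(signals) <- vapply(signals, signalLabel, "")
  ns <- length(signals)
  spr <- vapply(signals, function(s) samplingRate(s) * recordDurationS, 0)
  if (any(abs(spr - round(spr)) > 1e-9))
    stop("fs * recordDurationS must be an integer for every channel")
  spr <- as.integer(round(spr))
  nrec <- min(vapply(signals, function(s)
    floor(duration(s) / recordDurationS), 0))
  if (nrec < 1) stop("signals shorter than one data record")
  physMin <- physMax <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- samples(signals[[i]])[seq_len(spr[i] * nrec)]
    # quantize against the header-precision physical range (widened slightly
    # so header rounding cannot clip the data); de-quantization with the
    # parsed header is then exact to half a digital step
    rng0 <- max(max(x) - min(x), 1e-12)
    lo <- as.numeric(.edf8num(min(x) - 0.002 * rng0))
    hi <- as.numeric(.edf8num(max(x) + 0.002 * rng0))
    if (hi <= lo) hi <- lo + 1
    physMin[i] <- lo; physMax[i] <- hi
    dig[[i]] <- pmin(32767L, pmax(-32768L, as.integer(
      round((x - lo) / (hi - lo) * 65535 - 32768))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  w(.edfPad("0", 8))
  w(.edfPad("synthetic subject", 80))
  w(.edfPad("synthetic recording", 80))
  w(.edfPad("01.01.00", 8))
  w(.edfPad("00.00.00", 8))
  w(.edfPad(256 * (ns + 1), 8))
  w(.edfPad("", 44))
  w(.edfPad(nrec, 8))
  w(.edfPad(format(recordDurationS), 8))
  w(.edfPad(ns, 4))
  labs <- vapply(signals, signalLabel, "")
  for (s in labs) w(.edfPad(s, 16))
  for (s in labs) w(.edfPad("", 80))
  for (i in seq_len(ns)) w(.edfPad(signalUnits(signals[[i]]), 8))
  for (i in seq_len(ns)) w(.edfPad(.edf8num(physMin[i]), 8))
  for (i in seq_len(ns)) w(.edfPad(.edf8num(physMax[i]), 8))
  for (i in seq_len(ns)) w(.edfPad("-32768", 8))
  for (i in seq_len(ns)) w(.edfPad("32767", 8))
  for (s in labs) w(.edfPad("", 80))
  for (i in seq_len(ns)) w(.edfPad(spr[i], 8))
  for (s in labs) w(.edfPad("", 32))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Counterpart of [writeEDF()]; returns the channels de-quantized to
#' physical units.
#'
#' @param path an `.edf` file.
#' @return Named list of [SampledSignal-class] objects.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80) # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  raw <- lapply(seq_len(ns), function(i) integer(spr[i] * nrec))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      raw[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  out <- list()
  for (i in seq_len(ns)) {
    phys <- pmin[i] + (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin[i])
    out[[labs[i]]] <- SampledSignal(phys, spr[i] / recDur, label = labs[i],
                                    units = units[i])
  }
  out
}

# ------------------------------------------------ subject-record persistence

#' Write a SubjectRecord to a directory tree
#'
#' One delimited recording per condition (myographic channels + pressures +
#' ground-truth envelope when present) plus a `record.yaml` with conditions,
#' groups, cohort, seed and preprocessing state.
#'
#' @param record a [SubjectRecord-class].
#' @param path subject directory.
#' @return `path`, invisibly.
#' @export
writeSubject <- function(record, path) {
  stopifnot(is(record, "SubjectRecord"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(conditions = record@conditions,
                        groups = record@groups, cohort = record@cohort,
                        seed = record@seed,
                        preprocessed = record@preprocessed,
                        hasEnvelope = length(record@envelope) > 0),
                   file.path(path, "record.yaml"))
  for (cond in record@conditions) {
    sigs <- c(record@channels[[cond]], record@pressures[[cond]])
    if (length(record@envelope) > 0)
      sigs$envelope <- record@envelope[[cond]]
    writeRecording(sigs, file.path(path, cond))
  }
  invisible(path)
}

#' Read a SubjectRecord written by [writeSubject()]
#'
#' @param path subject directory.
#' @return A [SubjectRecord-class].
#' @export
readSubject <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "record.yaml"))
  channels <- list()
  pressures <- list()
  envelope <- list()
  for (cond in meta$conditions) {
    sigs <- readRecording(file.path(path, cond))
    pr <- sigs[intersect(c("pmo", "pdi", "Pmo", "Pdi"), names(sigs))]
    names(pr) <- tolower(names(pr))
    env <- sigs[["envelope"]]
    ch <- sigs[setdiff(names(sigs),
                       c("pmo", "pdi", "Pmo", "Pdi", "envelope"))]
    channels[[cond]] <- ch
    pressures[[cond]] <- pr
    if (!is.null(env)) envelope[[cond]] <- env
  }
  new("SubjectRecord", conditions = meta$conditions, channels = channels,
      pressures = pressures, envelope = envelope,
      groups = lapply(meta$groups, unlist), cohort = meta$cohort,
      seed = as.integer(meta$seed %||% NA_integer_),
      preprocessed = isTRUE(meta$preprocessed))
}
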