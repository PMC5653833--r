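## Recording I/O, bipolar montage, channel selection, down-sampling.
##
## Two interchange formats are supported: EDF (16-bit, continuous; the
## clinical de-facto standard) and a raw float32 little-endian channel-major
## block with a JSON sidecar carrying rate, labels and units. EDF support is
## a self-contained reader/writer for the plain (non-annotated) variant.

#' Read a recording from disk
#'
#' @param path path to an `.edf` file or to a raw `.f32` block whose JSON
#'   sidecar is `<path>.json`.
#' @param format `"edf"` or `"raw"`; guessed from the extension by default.
#' @return A [Recording-class] in microvolts.
#' @details The raw format is float32 little-endian, channel-major (all
#'   samples of channel 1, then channel 2, ...), with a sidecar JSON object
#'   holding `rate_hz`, `labels`, `units` (must be "uV"), and optionally
#'   `patient_id` and `night_id`.
#' @export
readRecording <- function(path, format = c("auto", "edf", "raw")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "raw"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") readEDF(path) else readRawRecording(path)
}

readRawRecording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  hdr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (k in c("rate_hz", "labels")) if (is.null(hdr[[k]]))
    stop("sidecar missing field '", k, "'")
  if (!is.null(hdr$units) && hdr$units != "uV")
    stop("raw recordings must be in uV, got '", hdr$units, "'")
  labels <- as.character(hdr$labels)
  if (anyDuplicated(labels)) stop("duplicate channel labels in sidecar")
  n <- file.info(path)$size / 4L
  x <- readBin(path, "numeric", n = n, size = 4L, endian = "little")
  nch <- length(labels)
  if (length(x) %% nch != 0L)
    stop("raw block size is not a multiple of the channel count")
  samples <- matrix(x, nrow = nch, byrow = TRUE)
  Recording(samples, rateHz = hdr$rate_hz, labels = labels,
            patientId = if (is.null(hdr$patient_id)) "P" else hdr$patient_id,
            nightId = if (is.null(hdr$night_id)) "N1" else hdr$night_id)
}

#' Write a recording as raw float32 + JSON sidecar
#'
#' @param rec a [Recording-class]
#' @param path output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeRawRecording <- function(rec, path) {
  writeBin(as.numeric(t(signalMatrix(rec))), path, size = 4L,
           endian = "little")
  jsonlite::write_json(
    list(rate_hz = sampleRate(rec), labels = channelLabels(rec),
         units = "uV", patient_id = rec@patientId, night_id = rec@nightId),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## --- minimal EDF (16-bit, continuous, unannotated) ------------------------

padField <- function(x, width) {
  x <- substr(format(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF file
#'
#' Plain EDF only (16-bit samples, no EDF+ annotations). All signals must
#' share the sampling rate; physical dimension must be microvolts (uV).
#'
#' @param path path to the file.
#' @return A [Recording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdStr <- function(n) rawToChar(readBin(con, "raw", n))
  rdNum <- function(n) as.numeric(trimws(rdStr(n)))
  invisible(rdStr(8L))                      # version
  invisible(rdStr(80L)); invisible(rdStr(80L))  # patient, recording
  invisible(rdStr(8L)); invisible(rdStr(8L))    # date, time
  invisible(rdNum(8L))                      # header bytes
  invisible(rdStr(44L))                     # reserved
  nRec <- rdNum(8L)
  recDur <- rdNum(8L)
  ns <- rdNum(4L)
  if (!is.finite(ns) || ns < 1) stop("EDF: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rdStr(w)), "")
  labels <- fld(16L)
  invisible(fld(80L))                       # transducer
  dims <- fld(8L)
  physMin <- as.numeric(fld(8L)); physMax <- as.numeric(fld(8L))
  digMin <- as.numeric(fld(8L)); digMax <- as.numeric(fld(8L))
  invisible(fld(80L))                       # prefilter
  spr <- as.numeric(fld(8L))                # samples per record
  invisible(fld(32L))                       # reserved
  if (anyDuplicated(labels)) stop("EDF: duplicate channel labels")
  if (length(unique(spr)) != 1L)
    stop("EDF: signals with differing sampling rates are not supported")
  if (!is.finite(recDur) || recDur <= 0) stop("EDF: missing record duration")
  bad <- !(dims %in% c("uV", "µV", ""))
  if (any(bad))
    stop("EDF: cannot establish uV units for channel(s) ",
         paste(labels[bad], collapse = ", "))
  rate <- spr[1L] / recDur
  samples <- matrix(0, nrow = ns, ncol = spr[1L] * nRec)
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                   endian = "little")
      cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      samples[s, cols] <- physMin[s] + gain[s] * (d - digMin[s])
    }
  }
  Recording(samples, rateHz = rate, labels = labels)
}

#' Write an EDF file
#'
#' Writes a [Recording-class] as plain 16-bit EDF with 1-second data
#' records (the duration must therefore be a whole number of seconds).
#'
#' @param rec a [Recording-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  x <- signalMatrix(rec)
  ns <- nrow(x)
  spr <- sampleRate(rec)
  if (abs(spr - round(spr)) > 1e-9) stop("EDF writer needs an integer rate")
  spr <- as.integer(round(spr))
  if (ncol(x) %% spr != 0L)
    stop("EDF writer needs a whole number of 1-second records")
  nRec <- ncol(x) %/% spr
  physMin <- apply(x, 1L, min); physMax <- apply(x, 1L, max)
  physMax <- ifelse(physMax > physMin, physMax, physMin + 1)
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(v, w) writeBin(charToRaw(paste0(
    vapply(v, padField, "", width = w), collapse = "")), con)
  wr("0", 8L); wr("X X X X", 80L); wr("Startdate X X X X", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(format(256L + 256L * ns), 8L); wr("", 44L)
  wr(format(nRec), 8L); wr("1", 8L); wr(format(ns), 4L)
  wr(channelLabels(rec), 16L); wr(rep("", ns), 80L); wr(rep("uV", ns), 8L)
  wr(format(physMin, digits = 6), 8L); wr(format(physMax, digits = 6), 8L)
  wr(rep(format(digMin), ns), 8L); wr(rep(format(digMax), ns), 8L)
  wr(rep("", ns), 80L); wr(rep(format(spr), ns), 8L); wr(rep("", ns), 32L)
  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      d <- round(digMin + gain[s] * (x[s, cols] - physMin[s]))
      writeBin(as.integer(pmin(pmax(d, digMin), digMax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

## --- filtering helpers -----------------------------------------------------

## Zero-phase application of a linear-phase FIR with an even order
## (odd-length h): FFT convolution, then removal of the integer group delay.
applyFirZeroPhase <- function(x, h) {
  L <- length(h)
  stopifnot(L %% 2L == 1L)
  gd <- (L - 1L) %/% 2L
  y <- signal::fftfilt(h, c(x, numeric(L - 1L)))
  y[(gd + 1L):(gd + length(x))]
}

#' Down-sample a recording
#'
#' Applies a zero-phase anti-alias FIR low-pass and decimates. The original
#' rate must be an integer multiple of the target.
#'
#' @param rec a [Recording-class]
#' @param targetHz target sampling rate (Hz).
#' @return A [Recording-class] at `targetHz` with
#'   `n_samples * targetHz / rateHz` samples per channel.
#' @details The anti-alias filter is a Hamming-windowed FIR (order 300)
#'   with cutoff at 95% of the target Nyquist, flat to within 1 dB below
#'   90% of the target Nyquist; applied with group-delay compensation so
#'   event times are phase-true.
#' @export
downsample <- function(rec, targetHz) {
  ratio <- sampleRate(rec) / targetHz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("rate ", sampleRate(rec), " is not an integer multiple of ",
         targetHz)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  h <- signal::fir1(300L, 0.95 / ratio)
  x <- signalMatrix(rec)
  idx <- seq(1L, ncol(x), by = ratio)
  out <- t(vapply(seq_len(nrow(x)),
                  function(i) applyFirZeroPhase(x[i, ], h)[idx],
                  numeric(length(idx))))
  Recording(out, rateHz = targetHz, labels = channelLabels(rec),
            patientId = rec@patientId, nightId = rec@nightId)
}

## --- bipolar montage -------------------------------------------------------

#' Build a bipolar montage scheme from contact labels
#'
#' Groups contacts by electrode prefix (the non-numeric part of the label)
#' and pairs adjacent contacts deepest-first: contact 1 is the deepest/most
#' mesial, so an 8-contact electrode "HR" yields HR1-HR2 ... HR7-HR8.
#'
#' @param labels contact labels such as `c("HR1", ..., "HR8")`.
#' @return data.frame with columns `name`, `anode`, `cathode`.
#' @export
bipolarScheme <- function(labels) {
  prefix <- sub("[0-9]+$", "", labels)
  index <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", labels)))
  if (anyNA(index)) stop("contact labels must end in a contact number")
  out <- do.call(rbind, lapply(split(seq_along(labels), prefix), function(i) {
    i <- i[order(index[i])]
    if (length(i) < 2L) return(NULL)
    anode <- labels[i[-length(i)]]; cathode <- labels[i[-1L]]
    data.frame(name = paste0(anode, "-", cathode), anode = anode,
               cathode = cathode, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Apply a bipolar montage
#'
#' Each output channel is `anode - cathode` of two contacts of the source
#' recording; output labels are `"anode-cathode"`.
#'
#' @param rec a referential [Recording-class]
#' @param scheme data.frame with columns `anode`, `cathode` (and optionally
#'   `name`), e.g. from [bipolarScheme()].
#' @return A bipolar [Recording-class].
#' @export
bipolarMontage <- function(rec, scheme = bipolarScheme(channelLabels(rec))) {
  if (is.null(scheme$name))
    scheme$name <- paste0(scheme$anode, scheme$cathode)
  miss <- setdiff(unique(c(scheme$anode, scheme$cathode)),
                  channelLabels(rec))
  if (length(miss))
    stop("montage contacts not in recording: ", paste(miss, collapse = ", "))
  if (any(scheme$anode == scheme$cathode))
    stop("anode and cathode must differ")
  x <- signalMatrix(rec)
  ia <- match(scheme$anode, channelLabels(rec))
  ic <- match(scheme$cathode, channelLabels(rec))
  out <- x[ia, , drop = FALSE] - x[ic, , drop = FALSE]
  Recording(out, rateHz = sampleRate(rec), labels = scheme$name,
            patientId = rec@patientId, nightId = rec@nightId)
}

#' Select analysis channels
#'
#' Removes bipolar channels touching an excluded contact (e.g. contacts
#' where electrical stimulation evoked motor or language responses) and,
#' when `mesialLimit` is given, keeps only the first `mesialLimit` bipolar
#' pairs per electrode counting from the deepest (most mesial) contact.
#'
#' @param channels bipolar channel labels, `"HR1-HR2"` style.
#' @param exclusions contact or channel labels to drop.
#' @param mesialLimit optional integer; keep only this many pairs per
#'   electrode, deepest-first.
#' @param mesialElectrodes electrode prefixes the limit applies to
#'   (default: all).
#' @return The retained channel labels (possibly empty, with a warning).
#' @export
selectChannels <- function(channels, exclusions = character(),
                           mesialLimit = NULL, mesialElectrodes = NULL) {
  parts <- strsplit(channels, "-", fixed = TRUE)
  hit <- vapply(seq_along(channels), function(i)
    channels[i] %in% exclusions || any(parts[[i]] %in% exclusions),
    logical(1L))
  keep <- channels[!hit]
  if (!is.null(mesialLimit)) {
    anode <- vapply(strsplit(keep, "-", fixed = TRUE), `[`, "", 1L)
    prefix <- sub("[0-9]+$", "", anode)
    index <- as.integer(sub("^.*?([0-9]+)$", "\\1", anode))
    limited <- unlist(lapply(split(seq_along(keep), prefix), function(i) {
      pfx <- prefix[i[1L]]
      if (!is.null(mesialElectrodes) && !pfx %in% mesialElectrodes)
        return(i)
      i[order(index[i])][seq_len(min(mesialLimit, length(i)))]
    }), use.names = FALSE)
    keep <- keep[sort(limited)]
  }
  if (!length(keep)) warning("channel selection is empty")
  keep
}

## --- event and rate tables -------------------------------------------------

eventTableColumns <- c("patient", "night", "interval", "channel", "type",
                       "start_s", "end_s", "amp_uvpp")

#' Empty event table
#'
#' @return zero-row data.frame with the canonical event columns
#'   (`patient`, `night`, `interval`, `channel`, `type`, `start_s`,
#'   `end_s`, `amp_uvpp`).
#' @export
emptyEventTable <- function() {
  data.frame(patient = character(), night = character(),
             interval = character(), channel = character(),
             type = character(), start_s = numeric(), end_s = numeric(),
             amp_uvpp = numeric(), stringsAsFactors = FALSE)
}

#' Write / read an event table
#'
#' CSV with columns `patient,night,interval,channel,type,start_s,end_s,
#' amp_uvpp`. The round trip is lossless.
#'
#' @param events event data.frame
#' @param path CSV path
#' @return `readEventTable` returns the data.frame; `writeEventTable`
#'   returns `path` invisibly.
#' @export
writeEventTable <- function(events, path) {
  stopifnot(all(eventTableColumns %in% names(events)))
  utils::write.csv(events[, union(eventTableColumns, names(events))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient = "character",
                                       night = "character",
                                       interval = "character",
                                       channel = "character",
                                       type = "character"))
  stopifnot(all(eventTableColumns %in% names(ev)))
  ev
}

#' Write / read a rate table (channels x intervals, events/min)
#'
#' @param rates numeric matrix channels x intervals with dimnames.
#' @param path CSV path
#' @return `readRateTable` returns the matrix; the writer returns `path`.
#' @export
writeRateTable <- function(rates, path) {
  df <- data.frame(channel = rownames(rates), rates, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRateTable
#' @export
readRateTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
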