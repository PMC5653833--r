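## Two-stage automated HFO detector.
##
## Stage 1 (baseline detection): windows with high Stockwell entropy in the
## 80-500 Hz range mark segments of low oscillatory activity; the amplitude
## threshold for a band is a high quantile of the band-filtered envelope on
## those segments only.
## Stage 2 (event detection): maximal runs of the envelope above the
## threshold, merged across sub-merge-gap dips, are kept when they last at
## least 20 ms (ripple band) / 10 ms (fast-ripple band). Fast ripples
## overlapping a ripple form the third HFO type, FRandR.

#' Band specification for HFO detection
#'
#' The two canonical HFO bands: ripple (pass 80-240 Hz, stop 70/250 Hz,
#' minimum event duration 20 ms) and fast ripple (pass 250-490 Hz, stop
#' 240/500 Hz, minimum duration 10 ms).
#'
#' @param name `"ripple"` or `"FR"`, or pass all edges explicitly.
#' @param passLoHz,passHiHz,stopLoHz,stopHiHz band edges (Hz).
#' @param minDurationS minimum event duration (s).
#' @return list of class `"BandSpec"`.
#' @export
bandSpec <- function(name = c("ripple", "FR"), passLoHz = NULL,
                     passHiHz = NULL, stopLoHz = NULL, stopHiHz = NULL,
                     minDurationS = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    ripple = list(passLoHz = 80, passHiHz = 240, stopLoHz = 70,
                  stopHiHz = 250, minDurationS = 0.020),
    FR     = list(passLoHz = 250, passHiHz = 490, stopLoHz = 240,
                  stopHiHz = 500, minDurationS = 0.010))
  spec <- list(name = name,
               passLoHz = passLoHz %||% def$passLoHz,
               passHiHz = passHiHz %||% def$passHiHz,
               stopLoHz = stopLoHz %||% def$stopLoHz,
               stopHiHz = stopHiHz %||% def$stopHiHz,
               minDurationS = minDurationS %||% def$minDurationS)
  with(spec, {
    if (!(stopLoHz < passLoHz && passLoHz < passHiHz &&
          passHiHz < stopHiHz))
      stop("band edges must satisfy stopLo < passLo < passHi < stopHi")
    if (minDurationS <= 0) stop("minDurationS must be positive")
  })
  structure(spec, class = "BandSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Design the band-pass FIR filter for one HFO band
#'
#' Linear-phase equiripple (Parks-McClellan) FIR meeting >= 60 dB stopband
#' attenuation and <= 1 dB passband ripple at 2000 Hz for the canonical
#' bands; applied zero-phase by group-delay compensation.
#'
#' @param band a [bandSpec()].
#' @param rateHz sampling rate (Hz).
#' @param order filter order (even); default scales with the rate so the
#'   10 Hz transition bands are met (800 at 2000 Hz).
#' @return numeric vector of filter coefficients (length `order + 1`).
#' @export
designBandFilter <- function(band, rateHz, order = NULL) {
  nyq <- rateHz / 2
  if (band$stopHiHz > nyq)
    stop("band extends beyond the Nyquist frequency (", nyq, " Hz)")
  if (is.null(order)) order <- 2L * as.integer(round(0.2 * rateHz))
  if (order %% 2L) order <- order + 1L
  f <- c(0, band$stopLoHz, band$passLoHz, band$passHiHz, band$stopHiHz, nyq)
  h <- signal::remez(order, f / nyq, c(0, 0, 1, 1, 0, 0))
  as.numeric(h)
}

#' Instantaneous amplitude (envelope) of a band-filtered trace
#'
#' Magnitude of the analytic signal, computed by zeroing the negative
#' frequencies of the FFT.
#'
#' @param x band-filtered signal vector.
#' @return envelope vector, same length as `x`.
#' @export
hfoEnvelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric())
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Detect baseline segments and derive the amplitude threshold
#'
#' First detector stage. The Stockwell entropy of the raw signal in the
#' 80-500 Hz range is computed on contiguous windows; windows whose entropy
#' exceeds the `entropyQuantile` of the channel's entropy distribution are
#' taken as baseline (flat spectrum, low oscillatory activity). The
#' amplitude threshold is the `thresholdQuantile` of the band-filtered
#' envelope restricted to baseline samples. When no baseline is found the
#' threshold falls back to the whole-signal envelope quantile (flagged).
#'
#' @param x raw (unfiltered) channel trace (microvolts).
#' @param rateHz sampling rate (Hz).
#' @param band a [bandSpec()].
#' @param entropyQuantile baseline = windows above this entropy quantile
#'   (default 0.90: the top decile).
#' @param thresholdQuantile envelope quantile on baseline (default 0.99).
#' @param windowS entropy window length (s).
#' @param filtered optional precomputed band-filtered trace.
#' @param entropyTrace optional precomputed entropy trace (shared across
#'   bands).
#' @return A [BaselineModel-class].
#' @export
detectBaseline <- function(x, rateHz, band, entropyQuantile = 0.90,
                           thresholdQuantile = 0.99, windowS = 0.125,
                           filtered = NULL, entropyTrace = NULL) {
  if (length(x) < 60 * rateHz)
    warning("signal shorter than 60 s; baseline statistics may be unstable")
  if (all(x == 0)) stop("all-zero signal: no baseline can be defined")
  if (is.null(entropyTrace))
    entropyTrace <- channelEntropyTrace(x, rateHz, windowS)
  if (is.null(filtered))
    filtered <- applyFirZeroPhase(x, designBandFilter(band, rateHz))
  env <- hfoEnvelope(filtered)
  cut <- stats::quantile(entropyTrace$entropy, entropyQuantile, names = FALSE)
  isBase <- entropyTrace$entropy > cut & !entropyTrace$zero_power
  wlen <- as.integer(round(windowS * rateHz))
  fallback <- !any(isBase)
  if (fallback) {
    segments <- matrix(numeric(), ncol = 2L)
    thr <- stats::quantile(env, thresholdQuantile, names = FALSE)
  } else {
    segments <- windowsToSegments(entropyTrace$window_start_s[isBase],
                                  windowS)
    baseIdx <- unlist(lapply(which(isBase), function(w) {
      s <- as.integer(round(entropyTrace$window_start_s[w] * rateHz))
      (s + 1L):(s + wlen)
    }), use.names = FALSE)
    thr <- stats::quantile(env[baseIdx], thresholdQuantile, names = FALSE)
    if (thr <= 0) {
      fallback <- TRUE
      thr <- stats::quantile(env, thresholdQuantile, names = FALSE)
    }
  }
  if (thr <= 0) stop("degenerate signal: envelope threshold is zero")
  new("BaselineModel", segments = segments, ampThresholdUv = thr,
      fallback = fallback, entropy = entropyTrace$entropy,
      windowStartS = entropyTrace$window_start_s)
}

## merge runs of adjacent equal-length windows into [start, end) segments
windowsToSegments <- function(starts, windowS) {
  if (!length(starts)) return(matrix(numeric(), ncol = 2L))
  starts <- sort(starts)
  brk <- c(TRUE, diff(starts) > windowS + 1e-9)
  grp <- cumsum(brk)
  t(vapply(split(starts, grp), function(s)
    c(s[1L], s[length(s)] + windowS), numeric(2L)))
}

#' Detect HFO events in one band
#'
#' Second detector stage: maximal runs where the envelope exceeds the
#' baseline amplitude threshold; runs separated by less than `mergeGapS`
#' are merged before the minimum-duration test. The event amplitude is the
#' peak-to-peak excursion of the band-filtered signal within the run.
#'
#' @param filtered band-filtered trace (microvolts).
#' @param rateHz sampling rate (Hz).
#' @param band a [bandSpec()].
#' @param model a [BaselineModel-class] built on the same channel/band.
#' @param mergeGapS gap below which adjacent supra-threshold runs merge
#'   (default 10 ms).
#' @return data.frame with columns `start_s`, `end_s`, `amp_uvpp`
#'   (half-open times, 0-based samples). Zero rows when nothing is found.
#' @export
detectEvents <- function(filtered, rateHz, band, model, mergeGapS = 0.010) {
  env <- hfoEnvelope(filtered)
  runs <- supraThresholdRuns(env > model@ampThresholdUv,
                             minLen = as.integer(ceiling(
                               band$minDurationS * rateHz)),
                             mergeGap = as.integer(floor(
                               mergeGapS * rateHz)))
  if (!nrow(runs))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      amp_uvpp = numeric()))
  amp <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- filtered[runs[i, 1L]:(runs[i, 2L] - 1L)]
    max(seg) - min(seg)
  }, numeric(1L))
  data.frame(start_s = (runs[, 1L] - 1L) / rateHz,
             end_s = (runs[, 2L] - 1L) / rateHz, amp_uvpp = amp)
}

## maximal TRUE-runs of a logical vector, as 1-based [start, end) sample
## index pairs. Gaps shorter than mergeGap samples are bridged first (an
## envelope dip mid-oscillation must not split one event in two); the
## minimum-duration criterion then counts only the supra-threshold samples
## within each merged run — the event definition requires the envelope to
## EXCEED the threshold for at least the minimum duration, so bridged gap
## samples do not contribute.
supraThresholdRuns <- function(above, minLen, mergeGap = 0L) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(cbind(start = integer(), end = integer()))
  seg <- cbind(start = starts[on], end = ends[on] + 1L)
  if (mergeGap > 0L && nrow(seg) > 1L) {
    keep <- list(seg[1L, ])
    for (i in 2L:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg[i, 1L] - last[2L] < mergeGap)
        keep[[length(keep)]][2L] <- seg[i, 2L]
      else keep[[length(keep) + 1L]] <- seg[i, ]
    }
    seg <- do.call(rbind, keep)
  }
  aboveTime <- vapply(seq_len(nrow(seg)), function(i)
    sum(above[seg[i, 1L]:(seg[i, 2L] - 1L)]), integer(1L))
  seg[aboveTime >= minLen, , drop = FALSE]
}

#' Identify fast ripples co-occurring with ripples (FRandR)
#'
#' One FRandR per fast-ripple event whose half-open time span intersects at
#' least one ripple event of the same channel/interval. The reported event
#' spans the union of the FR and its overlapping ripple(s); the FR's own
#' span is retained (`fr_start_s`, `fr_end_s`) for the spectral analysis.
#'
#' @param ripples,frs event data.frames from [detectEvents()] (same
#'   channel and interval).
#' @return data.frame of FRandR events (`start_s`, `end_s`, `amp_uvpp`,
#'   `fr_start_s`, `fr_end_s`); never more rows than `frs`.
#' @export
cooccurFRandR <- function(ripples, frs) {
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      amp_uvpp = numeric(), fr_start_s = numeric(),
                      fr_end_s = numeric())
  if (!nrow(frs) || !nrow(ripples)) return(empty)
  out <- lapply(seq_len(nrow(frs)), function(i) {
    ov <- ripples$start_s < frs$end_s[i] & frs$start_s[i] < ripples$end_s
    if (!any(ov)) return(NULL)
    data.frame(start_s = min(frs$start_s[i], ripples$start_s[ov]),
               end_s = max(frs$end_s[i], ripples$end_s[ov]),
               amp_uvpp = frs$amp_uvpp[i],
               fr_start_s = frs$start_s[i], fr_end_s = frs$end_s[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Detector configuration
#'
#' @param entropyQuantile,thresholdQuantile,entropyWindowS,mergeGapS see
#'   [detectBaseline()] and [detectEvents()].
#' @param rippleBand,frBand [bandSpec()]s.
#' @param filterOrder optional FIR order override.
#' @return list of class `"HFOConfig"`.
#' @export
hfoConfig <- function(entropyQuantile = 0.90, thresholdQuantile = 0.99,
                      entropyWindowS = 0.125, mergeGapS = 0.010,
                      rippleBand = bandSpec("ripple"),
                      frBand = bandSpec("FR"), filterOrder = NULL) {
  structure(list(entropyQuantile = entropyQuantile,
                 thresholdQuantile = thresholdQuantile,
                 entropyWindowS = entropyWindowS, mergeGapS = mergeGapS,
                 rippleBand = rippleBand, frBand = frBand,
                 filterOrder = filterOrder), class = "HFOConfig")
}

#' Run the full two-stage detector over a recording
#'
#' Per channel and interval: Stockwell-entropy baseline, band-pass
#' filtering, envelope thresholding in the ripple and FR bands, and FRandR
#' co-occurrence. Deterministic given (data, config).
#'
#' @param rec a bipolar [Recording-class].
#' @param intervals data.frame with columns `night`, `interval`,
#'   `start_s`, `duration_s` (half-open, seconds; default: one interval
#'   spanning the whole recording).
#' @param config an [hfoConfig()].
#' @return event data.frame with the canonical columns plus `fr_start_s`,
#'   `fr_end_s` (NA for ripple/FR rows). Event times are relative to the
#'   recording start. Channels without events simply contribute no rows;
#'   rate bookkeeping reinstates them with rate 0 (see [computeRates()]).
#' @export
runDetector <- function(rec, intervals = NULL, config = hfoConfig()) {
  if (is.null(intervals))
    intervals <- data.frame(night = rec@nightId, interval = "1",
                            start_s = 0, duration_s = duration(rec))
  if (!nrow(intervals)) return(cbind(emptyEventTable(),
                                     fr_start_s = numeric(),
                                     fr_end_s = numeric()))
  fs <- sampleRate(rec)
  hR <- designBandFilter(config$rippleBand, fs, config$filterOrder)
  hF <- designBandFilter(config$frBand, fs, config$filterOrder)
  rows <- list()
  for (ch in channelLabels(rec)) {
    full <- rec[ch]
    for (iv in seq_len(nrow(intervals))) {
      i0 <- as.integer(round(intervals$start_s[iv] * fs))
      n <- as.integer(round(intervals$duration_s[iv] * fs))
      if (i0 + n > length(full)) stop("interval extends beyond recording")
      x <- full[(i0 + 1L):(i0 + n)]
      ent <- channelEntropyTrace(x, fs, config$entropyWindowS)
      fR <- applyFirZeroPhase(x, hR)
      fF <- applyFirZeroPhase(x, hF)
      detect1 <- function(filt, band) {
        model <- suppressWarnings(detectBaseline(
          x, fs, band, config$entropyQuantile, config$thresholdQuantile,
          config$entropyWindowS, filtered = filt, entropyTrace = ent))
        detectEvents(filt, fs, band, model, config$mergeGapS)
      }
      evR <- detect1(fR, config$rippleBand)
      evF <- detect1(fF, config$frBand)
      evB <- cooccurFRandR(evR, evF)
      mk <- function(ev, type) {
        if (!nrow(ev)) return(NULL)
        data.frame(patient = rec@patientId, night = intervals$night[iv],
                   interval = as.character(intervals$interval[iv]),
                   channel = ch, type = type,
                   start_s = ev$start_s + intervals$start_s[iv],
                   end_s = ev$end_s + intervals$start_s[iv],
                   amp_uvpp = ev$amp_uvpp,
                   fr_start_s = if (type == "FRandR")
                     ev$fr_start_s + intervals$start_s[iv] else NA_real_,
                   fr_end_s = if (type == "FRandR")
                     ev$fr_end_s + intervals$start_s[iv] else NA_real_,
                   stringsAsFactors = FALSE)
      }
      rows <- c(rows, list(mk(evR, "ripple"), mk(evF, "FR"),
                           mk(evB, "FRandR")))
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(cbind(emptyEventTable(), fr_start_s = numeric(),
                 fr_end_s = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
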