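## Ground-truthed synthetic iEEG.
##
## The generator emulates the signal regime of long-term clinical iEEG:
## 1/f^beta background (the acquisition passband flattens it below
## 0.5 Hz), with band-limited Hann-windowed sinusoidal bursts injected at
## Poisson-drawn times with a refractory spacing. FRandR events are a
## ripple burst and a shorter fast-ripple burst superposed with
## overlapping supports. Every injected event is recorded in a ground
## truth table, so detector sensitivity/precision and area recovery are
## measurable exactly.

## run expr with a locally-seeded RNG, restoring the caller's RNG state
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Synthetic recording configuration
#'
#' @param nChannels number of (bipolar) channels.
#' @param rateHz sampling rate (default 2000 Hz).
#' @param durationS duration in seconds (default 300 s = one interval).
#' @param backgroundExponent 1/f^beta exponent of the background
#'   (default 1, pink noise).
#' @param backgroundRmsUv background RMS amplitude (default 15 uV).
#' @param events list of per-channel event specs, each a list/data.frame
#'   with `channel` (label or index), `type` ("ripple", "FR", "FRandR"),
#'   `rate_per_min`, and optionally `carrier_hz`, `duration_s`,
#'   `amp_uvpp`. Defaults per type: ripple 140 Hz / 80 ms / 27.4 uVpp,
#'   FR 350 Hz / 30 ms / 9.2 uVpp (amplitudes at the clinical medians).
#' @param spikeRatePerMin,spikeAmpUv rate and amplitude of sharp transient
#'   artifacts (default none).
#' @param refractoryS minimum spacing between event onsets (default
#'   0.2 s).
#' @param labels channel labels (default CH1..CHn).
#' @param seed RNG seed; a fixed seed makes the recording bit-exact.
#' @return list of class `"SynthConfig"`.
#' @export
synthConfig <- function(nChannels = 8, rateHz = 2000, durationS = 300,
                        backgroundExponent = 1, backgroundRmsUv = 15,
                        events = list(), spikeRatePerMin = 0,
                        spikeAmpUv = 100, refractoryS = 0.2,
                        labels = paste0("CH", seq_len(nChannels)),
                        seed = NULL) {
  stopifnot(nChannels >= 1, rateHz > 0, durationS > 0,
            backgroundRmsUv >= 0, length(labels) == nChannels)
  defaults <- list(
    ripple = list(carrier_hz = 140, duration_s = 0.080, amp_uvpp = 27.4),
    FR     = list(carrier_hz = 350, duration_s = 0.030, amp_uvpp = 9.2))
  events <- lapply(events, function(e) {
    e <- as.list(e)
    stopifnot(!is.null(e$channel), !is.null(e$type),
              !is.null(e$rate_per_min))
    base <- if (e$type == "FR") defaults$FR else defaults$ripple
    e$carrier_hz <- e$carrier_hz %||%
      if (e$type == "FRandR") defaults$ripple$carrier_hz else
        base$carrier_hz
    e$duration_s <- e$duration_s %||% base$duration_s
    e$amp_uvpp <- e$amp_uvpp %||% base$amp_uvpp
    if (e$type == "FRandR") {
      e$fr_carrier_hz <- e$fr_carrier_hz %||% defaults$FR$carrier_hz
      e$fr_duration_s <- e$fr_duration_s %||% defaults$FR$duration_s
      e$fr_amp_uvpp <- e$fr_amp_uvpp %||% defaults$FR$amp_uvpp
    }
    band <- if (e$type == "FR") c(250, 500) else c(80, 250)
    if (e$carrier_hz < band[1L] || e$carrier_hz > band[2L])
      stop("carrier ", e$carrier_hz, " Hz outside the ", e$type, " band")
    if (e$amp_uvpp < 0) stop("amplitude must be non-negative")
    e
  })
  structure(list(nChannels = nChannels, rateHz = rateHz,
                 durationS = durationS,
                 backgroundExponent = backgroundExponent,
                 backgroundRmsUv = backgroundRmsUv, events = events,
                 spikeRatePerMin = spikeRatePerMin,
                 spikeAmpUv = spikeAmpUv, refractoryS = refractoryS,
                 labels = labels, seed = seed), class = "SynthConfig")
}

## 1/f^(beta/2) amplitude-shaped Gaussian noise, flat below 0.5 Hz,
## scaled to the requested RMS
pinkNoise <- function(n, rateHz, beta, rmsUv) {
  if (rmsUv == 0) return(numeric(n))
  X <- stats::fft(stats::rnorm(n))
  f <- c(1e-12, seq_len(n - 1)) * rateHz / n
  f <- pmin(f, rateHz - f)              # two-sided
  shape <- pmax(f, 0.5)^(-beta / 2)
  shape[1L] <- 0                        # no DC
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  x * rmsUv / stats::sd(x)
}

## Poisson event onsets with refractory spacing inside [margin, dur-margin)
drawEventTimes <- function(ratePerMin, durationS, eventDurS,
                           refractoryS = 0.2, marginS = 0.5) {
  lo <- marginS
  hi <- durationS - marginS - eventDurS
  if (hi <= lo) return(numeric())
  nCand <- stats::rpois(1L, ratePerMin * durationS / 60)
  if (nCand == 0L) return(numeric())
  t0 <- sort(stats::runif(nCand, lo, hi))
  keep <- numeric()
  last <- -Inf
  for (t in t0) {
    if (t - last >= eventDurS + refractoryS) {
      keep <- c(keep, t); last <- t
    }
  }
  keep
}

hannBurst <- function(rateHz, carrierHz, durationS, ampUvpp) {
  n <- as.integer(round(durationS * rateHz))
  t <- (seq_len(n) - 1L) / rateHz
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  (ampUvpp / 2) * w * sin(2 * pi * carrierHz * t)
}

#' Generate a synthetic recording with ground truth
#'
#' @param cfg a [synthConfig()].
#' @return list with `recording` (a [Recording-class]) and `groundTruth`:
#'   `events` (one row per injected burst component: `channel`, `type`
#'   "ripple"/"FR", `group` "ripple"/"FR"/"FRandR", `event_id`,
#'   `start_s`, `end_s`, `carrier_hz`, `amp_uvpp`) and `trueRates`
#'   (channels x c(ripple, FR, FRandR) events/min, counting each FRandR
#'   injection once per constituent band and once as FRandR).
#' @export
generateRecording <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  withLocalSeed(cfg$seed, {
    n <- as.integer(round(cfg$durationS * cfg$rateHz))
    x <- t(vapply(seq_len(cfg$nChannels), function(i)
      pinkNoise(n, cfg$rateHz, cfg$backgroundExponent,
                cfg$backgroundRmsUv), numeric(n)))
    gt <- list()
    eid <- 0L
    for (spec in cfg$events) {
      ch <- spec$channel
      if (is.character(ch)) ch <- match(ch, cfg$labels)
      if (is.na(ch) || ch < 1 || ch > cfg$nChannels)
        stop("unknown event channel")
      times <- drawEventTimes(spec$rate_per_min, cfg$durationS,
                              spec$duration_s, cfg$refractoryS)
      for (t0 in times) {
        eid <- eid + 1L
        addBurst <- function(carrier, dur, amp, start, type) {
          b <- hannBurst(cfg$rateHz, carrier, dur, amp)
          i0 <- as.integer(round(start * cfg$rateHz))
          x[ch, (i0 + 1L):(i0 + length(b))] <<-
            x[ch, (i0 + 1L):(i0 + length(b))] + b
          data.frame(channel = cfg$labels[ch], type = type,
                     group = spec$type, event_id = eid, start_s = start,
                     end_s = start + dur, carrier_hz = carrier,
                     amp_uvpp = amp, stringsAsFactors = FALSE)
        }
        if (spec$type == "FRandR") {
          # FR burst centred within the ripple burst
          frStart <- t0 + (spec$duration_s - spec$fr_duration_s) / 2
          gt <- c(gt, list(
            addBurst(spec$carrier_hz, spec$duration_s, spec$amp_uvpp,
                     t0, "ripple"),
            addBurst(spec$fr_carrier_hz, spec$fr_duration_s,
                     spec$fr_amp_uvpp, frStart, "FR")))
        } else {
          gt <- c(gt, list(addBurst(spec$carrier_hz, spec$duration_s,
                                    spec$amp_uvpp, t0, spec$type)))
        }
      }
    }
    if (cfg$spikeRatePerMin > 0) {
      for (ch in seq_len(cfg$nChannels)) {
        times <- drawEventTimes(cfg$spikeRatePerMin, cfg$durationS,
                                0.02, cfg$refractoryS)
        for (t0 in times) {
          i0 <- as.integer(round(t0 * cfg$rateHz))
          k <- as.integer(round(0.02 * cfg$rateHz))
          spike <- cfg$spikeAmpUv * exp(-abs(seq_len(k) - k / 2) /
                                          (0.002 * cfg$rateHz))
          x[ch, (i0 + 1L):(i0 + k)] <- x[ch, (i0 + 1L):(i0 + k)] + spike
        }
      }
    }
    events <- if (length(gt)) do.call(rbind, gt) else
      data.frame(channel = character(), type = character(),
                 group = character(), event_id = integer(),
                 start_s = numeric(), end_s = numeric(),
                 carrier_hz = numeric(), amp_uvpp = numeric())
    minutes <- cfg$durationS / 60
    trueRates <- t(vapply(cfg$labels, function(lb) {
      e <- events[events$channel == lb, , drop = FALSE]
      c(ripple = sum(e$type == "ripple" & e$group == "ripple"),
        FR = sum(e$type == "FR" & e$group == "FR"),
        FRandR = length(unique(e$event_id[e$group == "FRandR"]))) /
        minutes
    }, numeric(3L)))
    list(recording = Recording(x, cfg$rateHz, cfg$labels),
         groundTruth = list(events = events, trueRates = trueRates))
  })
}

#' In-band SNR of an injected burst (dB)
#'
#' Peak envelope amplitude of the burst relative to the RMS of the
#' 1/f^beta background inside the detection band,
#' `20 log10((amp_uvpp/2) / sigma_band)`. Used to express generator
#' amplitudes in the detector's natural units.
#'
#' @param ampUvpp burst peak-to-peak amplitude (uV).
#' @param backgroundRmsUv total background RMS (uV).
#' @param band numeric `c(lo, hi)` detection band (Hz).
#' @param beta background exponent.
#' @param fullBand band over which `backgroundRmsUv` is defined
#'   (default 0.5-1000 Hz, the acquisition passband).
#' @return SNR in dB.
#' @export
burstSnrDb <- function(ampUvpp, backgroundRmsUv, band,
                       beta = 1, fullBand = c(0.5, 1000)) {
  frac <- bandPowerFraction(band, beta, fullBand)
  20 * log10((ampUvpp / 2) / (backgroundRmsUv * sqrt(frac)))
}

#' @rdname burstSnrDb
#' @param snrDb target SNR (dB); returns the peak-to-peak amplitude that
#'   achieves it.
#' @export
ampForSnrDb <- function(snrDb, backgroundRmsUv, band,
                        beta = 1, fullBand = c(0.5, 1000)) {
  frac <- bandPowerFraction(band, beta, fullBand)
  2 * backgroundRmsUv * sqrt(frac) * 10^(snrDb / 20)
}

bandPowerFraction <- function(band, beta, fullBand) {
  ip <- function(f1, f2) if (abs(beta - 1) < 1e-9) log(f2 / f1) else
    (f2^(1 - beta) - f1^(1 - beta)) / (1 - beta)
  ip(band[1L], band[2L]) / ip(fullBand[1L], fullBand[2L])
}

#' Match detected events to ground truth
#'
#' A detected event matches a truth event of the same channel and band
#' when their half-open time spans intersect. Sensitivity = matched truth
#' events / truth events; precision = detected events matching any truth
#' event / detected events.
#'
#' @param detected event table from [runDetector()].
#' @param truth ground-truth event table from [generateRecording()].
#' @param type band to evaluate: "ripple" or "FR".
#' @return list with `sensitivity`, `precision`, `n_truth`,
#'   `n_detected`.
#' @export
evaluateDetection <- function(detected, truth, type = c("ripple", "FR")) {
  type <- match.arg(type)
  det <- detected[detected$type == type, , drop = FALSE]
  tru <- truth[truth$type == type, , drop = FALSE]
  overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1
  truHit <- vapply(seq_len(nrow(tru)), function(i) {
    d <- det[det$channel == tru$channel[i], , drop = FALSE]
    any(overlaps(d$start_s, d$end_s, tru$start_s[i], tru$end_s[i]))
  }, logical(1L))
  detHit <- vapply(seq_len(nrow(det)), function(i) {
    t0 <- tru[tru$channel == det$channel[i], , drop = FALSE]
    any(overlaps(det$start_s[i], det$end_s[i], t0$start_s, t0$end_s))
  }, logical(1L))
  list(sensitivity = if (nrow(tru)) mean(truHit) else NA_real_,
       precision = if (nrow(det)) mean(detHit) else NA_real_,
       n_truth = nrow(tru), n_detected = nrow(det))
}

#' Generate a synthetic patient cohort
#'
#' Emulates the structure of the clinical characteristics table: per
#' patient a hot-channel FRandR rate topography observed over several
#' intervals and nights (stable with probability `areaStability` per
#' interval, otherwise the hot channel is redrawn), a resection set that
#' covers the hot channel or not, and an ILAE outcome class drawn
#' conditioned on coverage, yielding a known TP/FP/TN/FN composition.
#'
#' @param nPatients number of patients.
#' @param nChannels channels per patient.
#' @param nightsPerPatient,intervalsPerNight monitoring layout.
#' @param hotRate events/min of the hot channel.
#' @param coldRate mean events/min of the remaining channels; each draws
#'   its own base rate from an exponential with this mean, so the spatial
#'   profile is heterogeneous (as clinical rate maps are), not one-hot.
#' @param areaStability probability per interval that the spatial profile
#'   keeps its layout (1 = perfectly stable topography; below 1 the
#'   channel assignment of the profile is rescrambled).
#' @param composition named counts `c(TN=, FN=, TP=, FP=)` fixing each
#'   patient's (coverage, outcome) cell; recycled in order TN, FN, TP,
#'   FP. Alternatively `NULL`: coverage Bernoulli(0.7), outcome from
#'   `outcomeModel`.
#' @param outcomeModel function(covered) returning an ILAE class; default
#'   draws ILAE 1 with probability 0.85 when covered, 0.2 otherwise.
#' @param intervalMinutes interval duration (default 5).
#' @param seed RNG seed.
#' @return list with `patients` (a table with the resection flags and
#'   ILAE columns used by [validateCohort()]), `rates` (per patient a
#'   channels x intervals matrix with the night attribute), and
#'   `hotChannel` (per patient, per interval).
#' @export
generateCohort <- function(nPatients = 20, nChannels = 20,
                           nightsPerPatient = 3, intervalsPerNight = 6,
                           hotRate = 2, coldRate = 0.1,
                           areaStability = 1, composition = NULL,
                           outcomeModel = NULL, intervalMinutes = 5,
                           seed = NULL) {
  stopifnot(nPatients >= 1)
  if (is.null(outcomeModel))
    outcomeModel <- function(covered)
      if (stats::runif(1) < (if (covered) 0.85 else 0.2)) 1L else
        sample(2:6, 1L)
  cells <- NULL
  if (!is.null(composition)) {
    stopifnot(sum(composition) == nPatients)
    cells <- rep(names(composition), composition)
  }
  withLocalSeed(seed, {
    patients <- list(); rates <- list(); hot <- list()
    for (p in seq_len(nPatients)) {
      labels <- paste0("CH", seq_len(nChannels))
      nIv <- nightsPerPatient * intervalsPerNight
      nights <- rep(paste0("N", seq_len(nightsPerPatient)),
                    each = intervalsPerNight)
      # per-patient spatial rate profile: one hot channel plus
      # heterogeneous background rates
      baseLam <- stats::rexp(nChannels, rate = 1 / coldRate)
      baseLam[sample.int(nChannels, 1L)] <- hotRate
      hotIdx <- integer(nIv)
      m <- matrix(0, nChannels, nIv, dimnames = list(labels, NULL))
      for (iv in seq_len(nIv)) {
        lam <- if (stats::runif(1) < areaStability) baseLam else
          sample(baseLam)
        hotIdx[iv] <- which.max(lam)
        m[, iv] <- stats::rpois(nChannels, lam * intervalMinutes) /
          intervalMinutes
      }
      colnames(m) <- paste(nights, rep(seq_len(intervalsPerNight),
                                       nightsPerPatient), sep = ".")
      attr(m, "night") <- nights
      area <- suppressWarnings(delineateArea(m, 95, "FRandR"))
      if (!is.null(cells)) {
        cell <- cells[p]
        covered <- cell %in% c("TN", "FN")
        ilae <- if (cell %in% c("TN", "FP")) 1L else sample(2:6, 1L)
      } else {
        covered <- stats::runif(1) < 0.7
        ilae <- outcomeModel(covered)
      }
      resected <- if (covered)
        unique(c(area@channels, sample(labels, max(1L, nChannels %/% 4))))
      else setdiff(labels, area@channels)
      flag <- if (length(area@channels))
        areaFullyResected(area, resected) else NA
      patients[[p]] <- data.frame(
        patient = p, epilepsy = sample(c("TLE", "ETE"), 1L),
        nights = nightsPerPatient, intervals = nIv,
        frandr_resected = flag, fr_resected = flag,
        ripple_resected = flag, ilae = ilae,
        followup_months = stats::rpois(1L, 24),
        stringsAsFactors = FALSE)
      rates[[p]] <- m
      hot[[p]] <- labels[hotIdx]
    }
    list(patients = do.call(rbind, patients), rates = rates,
         hotChannel = hot)
  })
}
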