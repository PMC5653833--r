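## Spectral classification of FRandR events.
##
## For each FRandR we take the Stockwell transform of a 0.6 s window
## centred on the event, average the power over the duration of the fast
## ripple, and classify the resulting instantaneous spectrum in the
## 80-500 Hz range after fitting a sum of four Gaussian bumps:
## bimodal  - a trough between 150 and 250 Hz with at least one prominent
##            peak above 200 Hz (separate ripple and FR spectral entities);
## unimodal - a single prominent peak > 100 Hz detectable in the ripple
##            band (its energy spreads into the FR band);
## none     - no prominent peak above 100 Hz.

#' Instantaneous spectrum of one FRandR event
#'
#' S-transform power on a `windowS` window centred on the event,
#' time-averaged over the fast-ripple duration, restricted to
#' `[fminHz, fmaxHz]`.
#'
#' @param x the channel trace the event was detected on (microvolts).
#' @param rateHz sampling rate (Hz).
#' @param event one event row (list or 1-row data.frame) with `start_s`,
#'   `end_s` and, for FRandR, `fr_start_s`, `fr_end_s` (falls back to the
#'   full span when absent).
#' @param windowS analysis window length (default 0.6 s).
#' @param fminHz,fmaxHz spectral range (default 80-500 Hz).
#' @return list of class `"InstantSpectrum"` with `freqs_hz`, `power`,
#'   `fr_duration_s`, or `NULL` (with a warning) when the window does not
#'   fit inside the trace.
#' @export
eventSpectrum <- function(x, rateHz, event, windowS = 0.6,
                          fminHz = 80, fmaxHz = 500) {
  frStart <- event$fr_start_s
  frEnd <- event$fr_end_s
  if (is.null(frStart) || is.na(frStart)) frStart <- event$start_s
  if (is.null(frEnd) || is.na(frEnd)) frEnd <- event$end_s
  centre <- (event$start_s + event$end_s) / 2
  w0 <- as.integer(round((centre - windowS / 2) * rateHz))
  n <- as.integer(round(windowS * rateHz))
  if (w0 < 0L || w0 + n > length(x)) {
    warning("event too close to the recording edge; skipped")
    return(NULL)
  }
  tf <- stockwellTransform(x[(w0 + 1L):(w0 + n)], rateHz, fminHz, fmaxHz)
  tt <- tf@timesS + w0 / rateHz
  inFR <- tt >= frStart & tt < frEnd
  if (!any(inFR)) inFR <- rep(TRUE, length(tt))  # degenerate FR span
  structure(list(freqs_hz = tf@freqsHz,
                 power = rowMeans(tf@power[, inFR, drop = FALSE]),
                 fr_duration_s = frEnd - frStart),
            class = "InstantSpectrum")
}

## sum of four Gaussian bumps on the frequency axis
gauss4 <- function(f, p) {
  a <- p[1:4]; c0 <- p[5:8]; w <- p[9:12]
  rowSums(vapply(1:4, function(i)
    a[i] * exp(-(f - c0[i])^2 / (2 * w[i]^2)), numeric(length(f))))
}

#' Fit the four-Gaussian peak model and classify a spectrum
#'
#' Least-squares fit of a sum of four Gaussian components to the power
#' spectrum over 80-500 Hz (centres initialised at the four highest local
#' maxima of the lightly smoothed raw spectrum, widths bounded to
#' `[10, 200]` Hz), followed by peak/trough location on the fitted curve
#' via sign changes of its derivative. A peak is *prominent* when the
#' fitted curve rises by at least `prominenceFrac` of its own maximum
#' above the flanking troughs. Classification is scale-invariant.
#'
#' @param spec an `"InstantSpectrum"` (see [eventSpectrum()]), or any list
#'   with `freqs_hz` and `power`.
#' @param prominenceFrac prominence floor as a fraction of the curve
#'   maximum (default 0.20).
#' @param nRestarts restarts with jittered initial centres on
#'   non-convergence.
#' @return list of class `"SpectralClass"`: `label` ("bimodal",
#'   "unimodal" or "none"), `peak_freqs_hz`, `trough_freqs_hz`,
#'   `fit_params` (4 x 3 matrix amplitude/centre/width), `converged`.
#' @export
fitPeakModel <- function(spec, prominenceFrac = 0.20, nRestarts = 5L) {
  f <- spec$freqs_hz; y <- spec$power
  if (length(f) < 20L) stop("need at least 20 frequency samples")
  scale <- max(y)
  if (scale <= 0)
    return(structure(list(label = "none", peak_freqs_hz = numeric(),
                          trough_freqs_hz = numeric(),
                          fit_params = matrix(NA_real_, 4, 3),
                          converged = FALSE), class = "SpectralClass"))
  ys <- y / scale
  sm <- stats::filter(ys, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- ys[is.na(sm)]
  locmax <- which(diff(sign(diff(sm))) < 0) + 1L
  locmax <- locmax[order(sm[locmax], decreasing = TRUE)]
  # up to four initial centres from the highest local maxima, kept at
  # least 40 Hz apart; the remainder spread over the band away from them
  centres <- numeric()
  for (i in locmax) {
    if (length(centres) == 4L) break
    if (!length(centres) || all(abs(f[i] - centres) >= 40))
      centres <- c(centres, f[i])
  }
  if (length(centres) < 4L) {
    pad <- seq(min(f) + 40, max(f) - 40, length.out = 8L)
    pad <- pad[order(-vapply(pad, function(p0)
      if (length(centres)) min(abs(p0 - centres)) else Inf, numeric(1)))]
    centres <- c(centres, pad)[1:4]
  }
  p0 <- c(pmax(stats::approx(f, ys, centres)$y, 0.05),
          centres, rep(30, 4))
  lower <- c(rep(0, 4), rep(min(f), 4), rep(10, 4))
  upper <- c(rep(2, 4), rep(max(f), 4), rep(200, 4))
  fit <- NULL
  for (r in 0:nRestarts) {
    cand <- minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = function(p) gauss4(f, p) - ys,
      control = minpack.lm::nls.lm.control(maxiter = 300))
    if (cand$info %in% 1:4) { fit <- cand; break }
    # deterministic re-spacing of the initial centres between restarts
    p0[5:8] <- seq(min(f) + 20 * (r + 1), max(f) - 20, length.out = 4L)
  }
  if (is.null(fit))
    return(structure(list(label = "none", peak_freqs_hz = numeric(),
                          trough_freqs_hz = numeric(),
                          fit_params = matrix(NA_real_, 4, 3),
                          converged = FALSE), class = "SpectralClass"))
  p <- fit$par
  grid <- seq(min(f), max(f), by = 1)
  curve <- gauss4(grid, p)
  cls <- classifyCurve(grid, curve, prominenceFrac)
  structure(list(label = cls$label, peak_freqs_hz = cls$peaks,
                 trough_freqs_hz = cls$troughs,
                 fit_params = matrix(c(p[1:4] * scale, p[5:8], p[9:12]),
                                     ncol = 3,
                                     dimnames = list(NULL,
                                       c("amplitude", "centre", "width"))),
                 converged = TRUE), class = "SpectralClass")
}

## peak/trough extraction and the bimodal/unimodal/none decision on a
## densely evaluated fitted curve
classifyCurve <- function(grid, curve, prominenceFrac) {
  d <- diff(curve)
  s <- sign(d)
  pk <- which(diff(s) < 0) + 1L   # local maxima
  tr <- which(diff(s) > 0) + 1L   # local minima
  cmax <- max(curve)
  prominent <- vapply(pk, function(i) {
    leftTr <- tr[tr < i]; rightTr <- tr[tr > i]
    leftBase <- if (length(leftTr)) curve[max(leftTr)] else curve[1L]
    rightBase <- if (length(rightTr)) curve[min(rightTr)] else
      curve[length(curve)]
    curve[i] - max(leftBase, rightBase) >= prominenceFrac * cmax
  }, logical(1L))
  peaks <- grid[pk[prominent]]
  peaks <- peaks[peaks > 100]
  troughs <- grid[tr]
  label <- "none"
  if (length(peaks) >= 1L) {
    bimodalTrough <- any(vapply(troughs, function(t0)
      t0 >= 150 && t0 <= 250 &&
        any(peaks > pmax(200, t0)) && any(peaks < t0), logical(1L)))
    if (bimodalTrough) label <- "bimodal"
    else if (length(peaks) == 1L && peaks <= 250) label <- "unimodal"
  }
  list(label = label, peaks = peaks, troughs = troughs)
}

#' Channel selection for the cohort spectral analysis
#'
#' The bipolar channel with the highest FRandR mean rate among the
#' channels of the patient's HFO area.
#'
#' @param area an [HFOArea-class] (type FRandR).
#' @return a channel label, or `NA` when the area is empty.
#' @export
selectSpectralChannel <- function(area) {
  if (!length(area@channels)) return(NA_character_)
  r <- area@meanRates[area@channels]
  names(which.max(r))
}

#' Cohort summary of spectral classes
#'
#' @param classes list of `"SpectralClass"` results (non-empty).
#' @return list with `proportions` (named bimodal/unimodal/none fractions),
#'   `n`, `median_second_peak_hz` (highest prominent peak of bimodal
#'   events) and `median_sole_peak_hz` (unimodal events).
#' @export
cohortSpectralSummary <- function(classes) {
  if (!length(classes)) stop("empty class list")
  labels <- vapply(classes, `[[`, "", "label")
  prop <- c(bimodal = mean(labels == "bimodal"),
            unimodal = mean(labels == "unimodal"),
            none = mean(labels == "none"))
  secondPeaks <- unlist(lapply(classes[labels == "bimodal"], function(cl)
    max(cl$peak_freqs_hz)))
  solePeaks <- unlist(lapply(classes[labels == "unimodal"], function(cl)
    cl$peak_freqs_hz[1L]))
  list(proportions = prop, n = length(classes),
       median_second_peak_hz = if (length(secondPeaks))
         stats::median(secondPeaks) else NA_real_,
       median_sole_peak_hz = if (length(solePeaks))
         stats::median(solePeaks) else NA_real_)
}
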