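## Stockwell (S-) transform and Stockwell entropy.
##
## The S-transform is the time-frequency backbone of the detector: its
## frequency-dependent Gaussian window (sigma(f) = 1/f) gives wavelet-like
## time resolution while retaining absolutely-referenced phase/frequency.
## We use the standard discrete frequency-domain formulation: for voice k
## (frequency k/N * fs) the transform row is the inverse FFT of the
## spectrum shifted by k and weighted by a Gaussian exp(-2 pi^2 m^2 / k^2).

#' Stockwell transform
#'
#' Computes the discrete S-transform power map of a single-channel signal
#' on the natural frequency grid (spacing `rateHz / length(signal)`)
#' restricted to `[fminHz, fmaxHz]`.
#'
#' @param x numeric signal vector (microvolts).
#' @param rateHz sampling rate (Hz).
#' @param fminHz,fmaxHz frequency band of interest; `fmaxHz` must not
#'   exceed the Nyquist frequency.
#' @return A [TimeFrequencyMap-class] with `power = |S|^2`.
#' @examples
#' fs <- 2000
#' t <- seq(0, 0.6, by = 1 / fs)
#' tf <- stockwellTransform(sin(2 * pi * 350 * t), fs, 80, 500)
#' tf@freqsHz[which.max(rowMeans(tf@power))]   # ~350 Hz
#' @export
stockwellTransform <- function(x, rateHz, fminHz, fmaxHz) {
  n <- length(x)
  if (fminHz >= fmaxHz) stop("fminHz must be below fmaxHz")
  if (fmaxHz > rateHz / 2) stop("band extends beyond the Nyquist frequency")
  kmin <- max(1L, as.integer(ceiling(fminHz * n / rateHz)))
  kmax <- as.integer(floor(fmaxHz * n / rateHz))
  if (kmax < kmin) stop("no frequency bins inside the requested band")
  if (n < 2 * rateHz / fminHz)
    warning("signal shorter than two cycles of fminHz")
  X <- stats::fft(x)
  m <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))  # signed bin index
  ks <- kmin:kmax
  power <- matrix(0, nrow = length(ks), ncol = n)
  for (j in seq_along(ks)) {
    k <- ks[j]
    g <- exp(-2 * pi^2 * m^2 / k^2)
    shifted <- X[((seq_len(n) - 1L + k) %% n) + 1L]
    voice <- stats::fft(shifted * g, inverse = TRUE) / n
    power[j, ] <- Re(voice)^2 + Im(voice)^2
  }
  new("TimeFrequencyMap", power = power, freqsHz = ks * rateHz / n,
      timesS = (seq_len(n) - 1L) / rateHz)
}

#' Stockwell entropy trace
#'
#' Splits a time-frequency map into contiguous windows and computes, per
#' window, the Shannon entropy of the time-averaged, sum-normalised power
#' spectrum. High entropy = flat spectrum = baseline-like; a pure tone
#' concentrates power in one bin and drives the entropy towards zero. A
#' window with zero total power is assigned the maximal entropy
#' `log(n_freqs)` and flagged in the `zero_power` column.
#'
#' @param tf a [TimeFrequencyMap-class].
#' @param windowS window length in seconds; must span at least 2 time bins.
#' @return data.frame with columns `window_start_s`, `entropy`,
#'   `zero_power`.
#' @export
stockwellEntropy <- function(tf, windowS) {
  dt <- tf@timesS[2L] - tf@timesS[1L]
  wlen <- as.integer(floor(windowS / dt + 1e-9))
  if (wlen < 2L) stop("windowS must span at least 2 time bins")
  n <- ncol(tf@power)
  nwin <- n %/% wlen
  if (nwin < 1L) stop("windowS longer than the map")
  starts <- (seq_len(nwin) - 1L) * wlen
  ent <- numeric(nwin); zp <- logical(nwin)
  for (w in seq_len(nwin)) {
    cols <- (starts[w] + 1L):(starts[w] + wlen)
    spec <- rowMeans(tf@power[, cols, drop = FALSE])
    h <- spectrumEntropy(spec)
    ent[w] <- h$entropy; zp[w] <- h$zero
  }
  data.frame(window_start_s = tf@timesS[starts + 1L], entropy = ent,
             zero_power = zp)
}

spectrumEntropy <- function(spec) {
  tot <- sum(spec)
  if (tot <= 0 || !is.finite(tot))
    return(list(entropy = log(length(spec)), zero = TRUE))
  p <- spec / tot
  p <- p[p > 0]
  list(entropy = -sum(p * log(p)), zero = FALSE)
}

## Fast per-window entropy of a raw signal: each contiguous window is
## S-transformed on its own grid, and only the time-averaged power per
## voice is needed. By Parseval the time average of |voice|^2 equals
## (1/N^2) * sum_m |X[m+k] G_k[m]|^2, so no inverse FFTs are required.
## Equivalent to stockwellEntropy(stockwellTransform(window), window) per
## window; used by the detector on 5-minute traces.
channelEntropyTrace <- function(x, rateHz, windowS = 0.125,
                                fminHz = 80, fmaxHz = 500) {
  wlen <- as.integer(round(windowS * rateHz))
  if (wlen < 2L) stop("windowS too short for the sampling rate")
  nwin <- length(x) %/% wlen
  if (nwin < 1L) stop("signal shorter than one entropy window")
  seg <- matrix(x[seq_len(nwin * wlen)], nrow = wlen)
  X2 <- Mod(stats::mvfft(seg))^2            # wlen x nwin
  m <- c(0:(ceiling(wlen / 2) - 1L), -(floor(wlen / 2):1))
  kmin <- max(1L, as.integer(ceiling(fminHz * wlen / rateHz)))
  kmax <- as.integer(floor(fmaxHz * wlen / rateHz))
  if (kmax < kmin) stop("no frequency bins inside the entropy band")
  ks <- kmin:kmax
  avg <- matrix(0, nrow = length(ks), ncol = nwin)
  for (j in seq_along(ks)) {
    k <- ks[j]
    g2 <- exp(-4 * pi^2 * m^2 / k^2)
    idx <- ((seq_len(wlen) - 1L + k) %% wlen) + 1L
    avg[j, ] <- colSums(X2[idx, , drop = FALSE] * g2) / wlen^2
  }
  ent <- numeric(nwin); zp <- logical(nwin)
  for (w in seq_len(nwin)) {
    h <- spectrumEntropy(avg[, w])
    ent[w] <- h$entropy; zp[w] <- h$zero
  }
  data.frame(window_start_s = (seq_len(nwin) - 1L) * wlen / rateHz,
             entropy = ent, zero_power = zp)
}
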