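# Small signal builders shared across tests.

toneRecording <- function(freqHz, durationS = 1, rateHz = 2000, amp = 1,
                          label = "CH1") {
  t <- seq(0, durationS - 1 / rateHz, by = 1 / rateHz)
  Recording(matrix(amp * sin(2 * pi * freqHz * t), nrow = 1),
            rateHz = rateHz, labels = label)
}

# white-noise trace with Hann-windowed bursts injected at known times;
# returns the trace and the truth table
noiseWithBursts <- function(durationS, rateHz = 2000, noiseSd = 10,
                            burstTimes = numeric(), carrierHz = 140,
                            burstDurS = 0.05, burstAmp = 60, seed = 1) {
  set.seed(seed)
  n <- as.integer(durationS * rateHz)
  x <- rnorm(n, sd = noiseSd)
  nb <- as.integer(round(burstDurS * rateHz))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nb) - 1) / (nb - 1)))
  for (t0 in burstTimes) {
    i0 <- as.integer(round(t0 * rateHz))
    tt <- (seq_len(nb) - 1) / rateHz
    x[(i0 + 1):(i0 + nb)] <- x[(i0 + 1):(i0 + nb)] +
      burstAmp * w * sin(2 * pi * carrierHz * tt)
  }
  list(x = x,
       truth = data.frame(start_s = burstTimes,
                          end_s = burstTimes + burstDurS))
}

# frequency response magnitude of an FIR at one frequency (dB)
firGainDb <- function(h, fHz, rateHz) {
  H <- sum(h * exp(-2i * pi * fHz / rateHz * (seq_along(h) - 1)))
  20 * log10(Mod(H))
}

gaussBump <- function(f, a, c0, w) a * exp(-(f - c0)^2 / (2 * w^2))
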