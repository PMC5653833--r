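fsTest <- 2000

test_that("band filters meet the stopband/passband specification", {
  hR <- designBandFilter(bandSpec("ripple"), fsTest)
  expect_lt(firGainDb(hR, 70, fsTest), -60)
  expect_lt(firGainDb(hR, 250, fsTest), -60)
  expect_gt(firGainDb(hR, 150, fsTest), -1)
  hF <- designBandFilter(bandSpec("FR"), fsTest)
  expect_lt(firGainDb(hF, 150, fsTest), -60)
  expect_lt(firGainDb(hF, 240, fsTest), -60)
  expect_gt(firGainDb(hF, 350, fsTest), -1)
  # DC sits in the stopband: attenuated by >= 60 dB in steady state
  expect_lt(max(abs(applyFirZeroPhase(rep(5, 4000), hR)[1500:2500])),
            5 * 10^(-60 / 20))
  expect_error(designBandFilter(bandSpec("FR"), 900), "Nyquist")
})

test_that("band edges must be ordered and durations positive", {
  expect_error(bandSpec("ripple", stopLoHz = 90), "edges")
  expect_error(bandSpec("FR", minDurationS = 0), "positive")
})

test_that("the envelope recovers tone and modulation amplitudes", {
  t <- seq(0, 1 - 1 / fsTest, by = 1 / fsTest)
  core <- 200:1800
  env <- hfoEnvelope(3.7 * sin(2 * pi * 200 * t))
  expect_lt(max(abs(env[core] - 3.7) / 3.7), 0.02)
  expect_equal(hfoEnvelope(numeric(100)), numeric(100))
  A <- 10 + 5 * sin(2 * pi * 2 * t)   # modulation far below carrier
  envAM <- hfoEnvelope(A * sin(2 * pi * 200 * t))
  expect_lt(max(abs(envAM[core] - A[core]) / A[core]), 0.05)
})

test_that("baseline on homogeneous noise matches the full-signal
           quantile", {
  set.seed(10)
  x <- rnorm(fsTest * 90, sd = 10)
  band <- bandSpec("ripple")
  filt <- applyFirZeroPhase(x, designBandFilter(band, fsTest))
  m <- detectBaseline(x, fsTest, band, filtered = filt)
  expect_false(m@fallback)
  # top-decile entropy windows = 10% of the signal
  expect_equal(sum(m@segments[, 2] - m@segments[, 1]) / 90, 0.1,
               tolerance = 0.02)
  naive <- quantile(hfoEnvelope(filt), 0.99, names = FALSE)
  expect_equal(m@ampThresholdUv, naive, tolerance = 0.15 * naive)
})

test_that("oscillatory bursts are excluded from baseline, pulling the
           threshold to the masked-noise level", {
  burstTimes <- seq(5, 85, length.out = 25)
  sim <- noiseWithBursts(90, fsTest, noiseSd = 10,
                         burstTimes = burstTimes, burstDurS = 0.4,
                         burstAmp = 40, seed = 4)
  band <- bandSpec("ripple")
  filt <- applyFirZeroPhase(sim$x, designBandFilter(band, fsTest))
  env <- hfoEnvelope(filt)
  m <- detectBaseline(sim$x, fsTest, band, filtered = filt)
  naive <- quantile(env, 0.99, names = FALSE)
  mask <- rep(TRUE, length(sim$x))
  for (i in seq_len(nrow(sim$truth))) {
    i0 <- round(sim$truth$start_s[i] * fsTest)
    i1 <- round(sim$truth$end_s[i] * fsTest)
    mask[(i0 + 1):i1] <- FALSE
  }
  oracle <- quantile(env[mask], 0.99, names = FALSE)
  expect_lt(m@ampThresholdUv, naive)
  expect_equal(m@ampThresholdUv, oracle, tolerance = 0.3 * oracle)
})

test_that("an all-zero signal has no definable baseline", {
  expect_error(suppressWarnings(
    detectBaseline(numeric(fsTest * 10), fsTest, bandSpec("ripple"))),
    "all-zero")
})

test_that("the minimum-duration rule separates ripples from
           sub-duration bursts", {
  band <- bandSpec("ripple")
  h <- designBandFilter(band, fsTest)
  # 30 ms high-SNR 140 Hz burst -> exactly one ripple
  sim <- noiseWithBursts(60, fsTest, 5, burstTimes = 30,
                         burstDurS = 0.03, burstAmp = 80, seed = 2)
  filt <- applyFirZeroPhase(sim$x, h)
  m <- detectBaseline(sim$x, fsTest, band, filtered = filt)
  ev <- detectEvents(filt, fsTest, band, m)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start_s, 30.03)
  expect_gt(ev$end_s, 30.0)
  # 12 ms burst fails the 20 ms rule in the ripple band...
  sim12 <- noiseWithBursts(60, fsTest, 5, burstTimes = 30,
                           burstDurS = 0.012, burstAmp = 40, seed = 2)
  filt12 <- applyFirZeroPhase(sim12$x, h)
  m12 <- detectBaseline(sim12$x, fsTest, band, filtered = filt12)
  expect_equal(nrow(detectEvents(filt12, fsTest, band, m12)), 0)
  # ...but the same burst at 300 Hz passes the 10 ms FR rule
  bandF <- bandSpec("FR")
  simF <- noiseWithBursts(60, fsTest, 5, burstTimes = 30,
                          burstDurS = 0.012, burstAmp = 40,
                          carrierHz = 300, seed = 2)
  filtF <- applyFirZeroPhase(simF$x, designBandFilter(bandF, fsTest))
  mF <- detectBaseline(simF$x, fsTest, bandF, filtered = filtF)
  expect_equal(nrow(detectEvents(filtF, fsTest, bandF, mF)), 1)
})

test_that("well-separated high-SNR bursts are counted exactly", {
  burstTimes <- seq(4, 56, by = 4)
  sim <- noiseWithBursts(60, fsTest, 5, burstTimes = burstTimes,
                         burstDurS = 0.05, burstAmp = 80, seed = 3)
  band <- bandSpec("ripple")
  filt <- applyFirZeroPhase(sim$x, designBandFilter(band, fsTest))
  m <- detectBaseline(sim$x, fsTest, band, filtered = filt)
  ev <- detectEvents(filt, fsTest, band, m)
  expect_equal(nrow(ev), length(burstTimes))
  # amplitude monotonicity: louder bursts never yield fewer events
  simUp <- noiseWithBursts(60, fsTest, 5, burstTimes = burstTimes,
                           burstDurS = 0.05, burstAmp = 120, seed = 3)
  filtUp <- applyFirZeroPhase(simUp$x, designBandFilter(band, fsTest))
  evUp <- detectEvents(filtUp, fsTest, band, m)
  expect_gte(nrow(evUp), nrow(ev))
})

test_that("detectEvents equals a brute-force supra-threshold scan", {
  band <- bandSpec("ripple")
  set.seed(5)
  for (rep in 1:5) {
    filt <- rnorm(fsTest)  # 1 s toy "filtered" trace
    thr <- quantile(abs(filt), 0.8, names = FALSE)
    model <- new("BaselineModel", segments = matrix(numeric(), ncol = 2),
                 ampThresholdUv = thr, fallback = TRUE,
                 entropy = numeric(), windowStartS = numeric())
    ev <- detectEvents(filt, fsTest, band, model, mergeGapS = 0)
    # oracle: explicit scan over the envelope
    env <- hfoEnvelope(filt)
    above <- env > thr
    runs <- list(); i <- 1
    while (i <= length(above)) {
      if (above[i]) {
        j <- i
        while (j < length(above) && above[j + 1]) j <- j + 1
        if (j - i + 1 >= ceiling(band$minDurationS * fsTest))
          runs[[length(runs) + 1]] <- c(i, j + 1)
        i <- j + 1
      }
      i <- i + 1
    }
    expect_equal(nrow(ev), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(ev$start_s[k], (runs[[k]][1] - 1) / fsTest)
      expect_equal(ev$end_s[k], (runs[[k]][2] - 1) / fsTest)
    }
  }
})

test_that("FRandR co-occurrence follows half-open overlap semantics", {
  r <- function(s, e) data.frame(start_s = s, end_s = e,
                                 amp_uvpp = 1)
  # containment: event spans the union
  out <- cooccurFRandR(r(1.00, 1.06), r(1.02, 1.04))
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start_s, out$end_s), c(1.00, 1.06))
  expect_equal(c(out$fr_start_s, out$fr_end_s), c(1.02, 1.04))
  # disjoint
  expect_equal(nrow(cooccurFRandR(r(1.00, 1.06), r(2.00, 2.02))), 0)
  # touching at the boundary is NOT overlap (half-open)
  expect_equal(nrow(cooccurFRandR(r(1.00, 1.06), r(1.06, 1.08))), 0)
  # one ripple overlapped by two FRs -> two FRandR
  frs <- r(c(1.01, 1.05), c(1.03, 1.07))
  out2 <- cooccurFRandR(r(1.00, 1.06), frs)
  expect_equal(nrow(out2), 2)
  # brute-force pairwise overlap count always bounds FRandR by FR count
  set.seed(6)
  for (rep in 1:20) {
    rip <- r(runif(5, 0, 10), 0); rip$end_s <- rip$start_s + runif(5, .02, .1)
    fr <- r(runif(8, 0, 10), 0); fr$end_s <- fr$start_s + runif(8, .01, .05)
    got <- cooccurFRandR(rip, fr)
    oracle <- sum(vapply(seq_len(8), function(i)
      any(rip$start_s < fr$end_s[i] & fr$start_s[i] < rip$end_s),
      logical(1)))
    expect_equal(nrow(got), oracle)
    expect_lte(nrow(got), nrow(fr))
  }
})

test_that("runDetector localizes events to the injected channel and is
           deterministic", {
  amp <- ampForSnrDb(16, 15, c(80, 250))
  cfg <- synthConfig(nChannels = 4, durationS = 60,
                     events = list(list(channel = 3, type = "ripple",
                                        rate_per_min = 6,
                                        amp_uvpp = amp)),
                     seed = 21)
  g <- generateRecording(cfg)
  ev <- runDetector(g$recording)
  expect_gt(sum(ev$channel == "CH3" & ev$type == "ripple"), 0)
  expect_equal(sum(ev$channel != "CH3"), 0)
  ev2 <- runDetector(g$recording)
  expect_identical(ev, ev2)
  # empty interval list -> empty table
  expect_equal(nrow(runDetector(g$recording,
                                intervals = data.frame(night = character(),
                                                       interval = character(),
                                                       start_s = numeric(),
                                                       duration_s = numeric()))),
               0)
})
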