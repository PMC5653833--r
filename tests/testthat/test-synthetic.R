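test_that("generation is bit-exact under a fixed seed", {
  cfg <- synthConfig(nChannels = 2, durationS = 20,
                     events = list(list(channel = 1, type = "ripple",
                                        rate_per_min = 6)),
                     seed = 33)
  g1 <- generateRecording(cfg)
  g2 <- generateRecording(cfg)
  expect_identical(signalMatrix(g1$recording),
                   signalMatrix(g2$recording))
  expect_identical(g1$groundTruth$events, g2$groundTruth$events)
})

test_that("ground-truth rates equal injected counts over duration", {
  cfg <- synthConfig(nChannels = 4, durationS = 120,
                     events = list(list(channel = 2, type = "FRandR",
                                        rate_per_min = 3)),
                     seed = 12)
  g <- generateRecording(cfg)
  ev <- g$groundTruth$events
  nInj <- length(unique(ev$event_id[ev$group == "FRandR"]))
  expect_equal(g$groundTruth$trueRates["CH2", "FRandR"], nInj / 2)
  expect_equal(sum(g$groundTruth$trueRates[c("CH1", "CH3", "CH4"), ]), 0)
  # FRandR injections put a ripple and an FR burst with overlapping spans
  pairs <- split(ev, ev$event_id)
  for (p in pairs) {
    expect_setequal(p$type, c("ripple", "FR"))
    expect_lt(p$start_s[p$type == "FR"], p$end_s[p$type == "ripple"])
    expect_gt(p$end_s[p$type == "FR"], p$start_s[p$type == "ripple"])
  }
})

test_that("zero event rates give pure background at the configured
           scale", {
  cfg <- synthConfig(nChannels = 2, durationS = 30, seed = 3)
  g <- generateRecording(cfg)
  expect_equal(nrow(g$groundTruth$events), 0)
  expect_equal(apply(signalMatrix(g$recording), 1, sd),
               c(CH1 = 15, CH2 = 15), tolerance = 1e-6)
})

test_that("a generated burst's spectrum peaks at its carrier", {
  cfg <- synthConfig(nChannels = 1, durationS = 30,
                     events = list(list(channel = 1, type = "ripple",
                                        rate_per_min = 10,
                                        carrier_hz = 160,
                                        amp_uvpp = 200)),
                     seed = 9)
  g <- generateRecording(cfg)
  tru <- g$groundTruth$events[1, ]
  i0 <- round(tru$start_s * 2000)
  n <- round((tru$end_s - tru$start_s) * 2000)
  seg <- g$recording["CH1"][(i0 + 1):(i0 + n)]
  tf <- stockwellTransform(seg, 2000, 80, 500)
  peak <- tf@freqsHz[which.max(rowMeans(tf@power))]
  expect_lte(abs(peak - 160), 2000 / n + 1e-9)
})

test_that("carriers outside their band are rejected", {
  expect_error(synthConfig(events = list(list(channel = 1,
                                              type = "ripple",
                                              rate_per_min = 1,
                                              carrier_hz = 300))),
               "outside")
  expect_error(synthConfig(events = list(list(channel = 1, type = "FR",
                                              rate_per_min = 1,
                                              carrier_hz = 100))),
               "outside")
})

test_that("amplitude helpers invert each other and track the background
           spectrum", {
  amp <- ampForSnrDb(12, 15, c(80, 250))
  expect_equal(burstSnrDb(amp, 15, c(80, 250)), 12)
  # empirical band RMS of generated pink noise matches the analytic value
  cfg <- synthConfig(nChannels = 1, durationS = 60, seed = 22)
  g <- generateRecording(cfg)
  filt <- applyFirZeroPhase(g$recording["CH1"],
                            designBandFilter(bandSpec("ripple"), 2000))
  analytic <- 15 * sqrt(log(250 / 80) / log(1000 / 0.5))
  expect_equal(sd(filt), analytic, tolerance = 0.15 * analytic)
})

test_that("a cohort built to the clinical composition reproduces the
           target metric column", {
  co <- generateCohort(nPatients = 20, nChannels = 12,
                       nightsPerPatient = 2, intervalsPerNight = 3,
                       composition = c(TN = 13, FN = 3, TP = 4, FP = 0),
                       seed = 40)
  v <- validateCohort(co$patients, "FRandR", "ILAE-1")
  expect_equal(v$counts, c(tp = 4, fp = 0, tn = 13, fn = 3))
  m <- v$metrics
  expect_equal(round(m$specificity$value), 100)
  expect_equal(round(m$sensitivity$value), 57)
  expect_equal(round(m$npv$value), 81)
  expect_equal(round(m$ppv$value), 100)
  expect_equal(round(m$accuracy$value), 85)
})

test_that("degenerate cohorts surface undefined metrics rather than
           numbers", {
  co <- generateCohort(nPatients = 5, nChannels = 12,
                       composition = c(TN = 5), seed = 41)
  v <- validateCohort(co$patients, "FRandR", "ILAE-1")
  expect_equal(v$metrics$specificity$value, 100)
  expect_true(is.na(v$metrics$sensitivity$value))
})

test_that("the end-to-end pipeline recovers the injected hot channel", {
  amp <- ampForSnrDb(16, 15, c(80, 250))
  ampF <- ampForSnrDb(16, 15, c(250, 500))
  cfg <- synthConfig(nChannels = 12, durationS = 120,
                     events = c(
                       list(list(channel = 2, type = "FRandR",
                                 rate_per_min = 4, amp_uvpp = amp,
                                 fr_amp_uvpp = ampF)),
                       lapply(setdiff(1:12, 2), function(ch)
                         list(channel = ch, type = "FRandR",
                              rate_per_min = 0.5, amp_uvpp = amp,
                              fr_amp_uvpp = ampF))),
                     seed = 77)
  g <- generateRecording(cfg)
  ev <- runDetector(g$recording)
  rates <- computeRates(ev, channelLabels(g$recording), 120, "FRandR")
  area <- delineateArea(rates)
  expect_equal(areaChannels(area), "CH2")
})
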