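specGrid <- seq(80, 500, by = 2)

test_that("constructed two-peak spectra classify bimodal with the trough
           between 150 and 250 Hz", {
  sp <- list(freqs_hz = specGrid,
             power = gaussBump(specGrid, 1, 150, 30) +
               gaussBump(specGrid, 0.6, 320, 40))
  cl <- fitPeakModel(sp)
  expect_equal(cl$label, "bimodal")
  expect_true(any(cl$peak_freqs_hz > 200))
  expect_true(any(cl$trough_freqs_hz >= 150 & cl$trough_freqs_hz <= 250))
  # noiseless center recovery within 5 Hz
  expect_lt(min(abs(cl$peak_freqs_hz - 150)), 5)
  expect_lt(min(abs(cl$peak_freqs_hz - 320)), 5)
})

test_that("a single ripple-band peak classifies unimodal", {
  sp <- list(freqs_hz = specGrid, power = gaussBump(specGrid, 1, 184, 40))
  cl <- fitPeakModel(sp)
  expect_equal(cl$label, "unimodal")
  expect_length(cl$peak_freqs_hz, 1)
  expect_lt(abs(cl$peak_freqs_hz - 184), 5)
})

test_that("flat spectra classify none in the vast majority of noisy
           draws", {
  set.seed(14)
  labels <- vapply(1:40, function(i) {
    sp <- list(freqs_hz = specGrid,
               power = 1 + rnorm(length(specGrid), 0, 0.02))
    fitPeakModel(sp)$label
  }, "")
  expect_gte(mean(labels == "none"), 0.95)
})

test_that("classification is invariant to power scaling and labels are
           exhaustive", {
  set.seed(15)
  for (rep in 1:8) {
    pw <- gaussBump(specGrid, runif(1, .5, 2), runif(1, 100, 450),
                    runif(1, 20, 80)) +
      gaussBump(specGrid, runif(1, 0, 1), runif(1, 100, 450),
                runif(1, 20, 80)) + 0.02
    cl1 <- fitPeakModel(list(freqs_hz = specGrid, power = pw))
    cl2 <- fitPeakModel(list(freqs_hz = specGrid, power = 1e4 * pw))
    expect_true(cl1$label %in% c("bimodal", "unimodal", "none"))
    expect_equal(cl1$label, cl2$label)
  }
})

test_that("the event spectrum separates ripple and FR carriers of an
           injected FRandR", {
  amp <- ampForSnrDb(18, 15, c(80, 250))
  ampF <- ampForSnrDb(18, 15, c(250, 500))
  cfg <- synthConfig(nChannels = 1, durationS = 60,
                     events = list(list(channel = 1, type = "FRandR",
                                        rate_per_min = 4, amp_uvpp = amp,
                                        fr_amp_uvpp = ampF)),
                     seed = 6)
  g <- generateRecording(cfg)
  ev <- runDetector(g$recording)
  frandr <- ev[ev$type == "FRandR", ]
  expect_gt(nrow(frandr), 0)
  sp <- eventSpectrum(g$recording["CH1"], 2000, frandr[1, ])
  expect_true(all(sp$freqs_hz >= 80 & sp$freqs_hz <= 500))
  # local maxima near both carriers (140 and 350 Hz)
  peaks <- sp$freqs_hz[which(diff(sign(diff(sp$power))) < 0) + 1]
  expect_lt(min(abs(peaks - 140)), 25)
  expect_lt(min(abs(peaks - 350)), 25)
  cl <- fitPeakModel(sp)
  expect_equal(cl$label, "bimodal")
  # events at the recording edge are skipped with a warning
  edge <- frandr[1, ]
  edge$start_s <- 0.05; edge$end_s <- 0.11
  edge$fr_start_s <- 0.07; edge$fr_end_s <- 0.09
  expect_warning(out <- eventSpectrum(g$recording["CH1"], 2000, edge),
                 "edge")
  expect_null(out)
})

test_that("a single injected mid-band oscillation yields one broad
           ripple-range maximum", {
  amp <- ampForSnrDb(18, 15, c(80, 250))
  cfg <- synthConfig(nChannels = 1, durationS = 30,
                     events = list(list(channel = 1, type = "ripple",
                                        rate_per_min = 4,
                                        carrier_hz = 190,
                                        amp_uvpp = amp)),
                     seed = 8)
  g <- generateRecording(cfg)
  tru <- g$groundTruth$events[1, ]
  sp <- eventSpectrum(g$recording["CH1"], 2000, tru)
  expect_lt(abs(sp$freqs_hz[which.max(sp$power)] - 190), 30)
})

test_that("the cohort summary recovers known class proportions", {
  cls <- function(label) structure(list(label = label,
                                        peak_freqs_hz = 200),
                                   class = "SpectralClass")
  all10 <- replicate(10, cls("bimodal"), simplify = FALSE)
  s <- cohortSpectralSummary(all10)
  expect_equal(unname(s$proportions), c(1, 0, 0))
  expect_error(cohortSpectralSummary(list()), "empty")
  # cohort generated at 45/28/27 recovered within binomial error
  set.seed(16)
  n <- 240
  truth <- sample(c("bimodal", "unimodal", "none"), n, replace = TRUE,
                  prob = c(0.45, 0.28, 0.27))
  spectra <- lapply(truth, function(lb) {
    pw <- switch(lb,
      bimodal = gaussBump(specGrid, 1, runif(1, 120, 150), 25) +
        gaussBump(specGrid, runif(1, .5, .9), runif(1, 300, 360), 35),
      unimodal = gaussBump(specGrid, 1, runif(1, 150, 220), 40),
      none = rep(1, length(specGrid)))
    list(freqs_hz = specGrid,
         power = pw + abs(rnorm(length(specGrid), 0, 0.01)))
  })
  got <- cohortSpectralSummary(lapply(spectra, fitPeakModel))
  se <- sqrt(c(.45, .28, .27) * c(.55, .72, .73) / n)
  expect_true(all(abs(got$proportions - c(.45, .28, .27)) < 4 * se))
})

test_that("the spectral channel is the hottest area channel", {
  rates <- setNames(c(5, 3, 0.1, 0), paste0("C", 1:4))
  area <- delineateArea(rates, q = 50)
  expect_equal(selectSpectralChannel(area), "C1")
  emptyArea <- new("HFOArea", channels = character(),
                   thresholdRate = 1, type = "FRandR",
                   meanRates = rates, degenerate = FALSE)
  expect_true(is.na(selectSpectralChannel(emptyArea)))
})
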