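Package: ieegHFO
Title: Automated Detection and Clinical Validation of High-Frequency
    Oscillations in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated interictal analysis of long-term intracranial
    EEG recordings for epilepsy surgery evaluation. Detects high-frequency
    oscillations (HFOs) in the ripple (80-250 Hz) and fast-ripple
    (250-500 Hz) bands with a two-stage detector (Stockwell-entropy
    baseline identification followed by amplitude thresholding of the
    band-filtered envelope), identifies fast ripples co-occurring with
    ripples (FRandR), delineates the per-patient HFO area by
    95th-percentile rate thresholding, quantifies test-retest
    reproducibility of the spatial HFO rate distribution with a
    channel-permutation statistic, classifies FRandR events as spectrally
    bimodal or unimodal from the instantaneous Stockwell spectrum, and
    validates the HFO area against surgical resection and seizure outcome
    at the individual-patient level. Includes a ground-truthed synthetic
    iEEG generator so the whole pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
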