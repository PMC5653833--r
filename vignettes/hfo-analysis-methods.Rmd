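---
title: "Automated HFO analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated HFO analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegHFO)
```

This vignette explains the science implemented by **ieegHFO**: the
detector model and its assumptions, the parameters that matter and why
they default the way they do, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
method leaves room.

## The problem

High-frequency oscillations (HFOs) — brief (tens of ms) oscillatory
iEEG events at 80–500 Hz that stand out from background — mark
epileptogenic cortex. Ripples occupy 80–250 Hz, fast ripples (FR)
250–500 Hz, and an FR that temporally overlaps a ripple (FRandR) is
treated as a third, more specific event type. The clinical quantity of
interest is spatial: the set of bipolar channels generating HFOs at
high rate (the *HFO area*), compared against the surgically resected
area and the patient's seizure outcome.

## Signal model and the two-stage detector

The detector assumes a recording in microvolts at 2000 Hz (4000 Hz
input is decimated after a zero-phase anti-alias low-pass), re-montaged
to bipolar channels (`anode − cathode` of adjacent contacts, contact 1
deepest). Each channel is treated independently: background activity is
broadband and approximately 1/f, against which an HFO appears as a
transient narrowband excursion.

**Stage 1 — baseline.** An amplitude threshold is only meaningful
relative to the channel's quiet background, so the detector first finds
*baseline* stretches. The signal is cut into contiguous 0.125 s windows
and each window's Stockwell entropy is computed: the S-transform power
in 80–500 Hz is time-averaged over the window, sum-normalised, and its
Shannon entropy taken. A flat (noise-like) spectrum has high entropy; a
window containing an oscillation concentrates power and drops the
entropy. Windows above the 0.90 quantile of the channel's entropy
distribution — the flattest decile — are baseline. On a 5-minute
interval that is 30 s of signal, enough for a stable envelope quantile.
The amplitude threshold for a band is the 0.99 quantile of the
band-filtered envelope restricted to those baseline samples. If no
baseline is found the whole-signal quantile is used and flagged
(`fallback`).

Both quantiles are configuration keys (`hfoConfig()`), not constants of
nature: 0.90/0.99 are sensible defaults for interictal slow-wave-sleep
iEEG, and the entropy window must be long enough to resolve 80 Hz
(≥ 2 cycles = 25 ms) yet short enough that baseline interleaves with
events; 0.125 s satisfies both with an 8 Hz frequency grid.

**Stage 2 — events.** The band filters are linear-phase equiripple FIRs
(ripple: pass 80–240 Hz, stop 70/250 Hz; FR: pass 250–490 Hz, stop
240/500 Hz; ≥ 60 dB stopband, ≤ 1 dB passband ripple; order 800 at
2000 Hz for the 10 Hz transitions), applied with group-delay
compensation so event times are phase-true across bands — essential
because FRandR is defined by cross-band temporal overlap. The envelope
is the analytic-signal magnitude. Maximal supra-threshold runs are
merged across gaps shorter than 10 ms (an envelope dip mid-oscillation
must not split one event), and a merged run is kept when its
*supra-threshold* time reaches 20 ms (ripple) or 10 ms (FR). We count
only supra-threshold samples, not the bridged gaps: the event
definition demands the envelope *exceed* the threshold for the minimum
duration, and on pure noise the distinction matters — counting gap
samples admits tens of spurious FR events per 5 minutes, counting
exceedance time admits essentially none. The event amplitude is the
peak-to-peak excursion of the band-filtered trace within the run.

**FRandR.** Each FR that overlaps any ripple (non-empty intersection of
half-open `[start, end)` spans) yields one FRandR spanning the union;
the FR's own span is kept on the event because the spectral analysis
averages over the FR duration. FRandR count can never exceed FR count.
Overlapping ripples are not merged before the pairing; with the minimum
durations and merge gap in place, double-pairing is not observed in
practice and the convention is the simpler one to reason about.

## The HFO area

Rates are event counts per minute per channel, zero-filled for channels
without events (a channel that is demonstrably quiet is clinical
information). The patient-level area uses the *mean* rate across all
intervals — averaging first stabilises the spatial profile before
thresholding — while per-interval areas remain available for display.
The threshold is the 95th percentile across channels under the
convention that sorted sample *i* of *N* sits at percentile
`100·(i − 0.5)/N`, linearly interpolated and clamped (R's
`quantile(type = 5)`); `ratePercentile()` implements it directly so the
threshold is bit-compatible with the convention stated. Channels
*strictly above* the threshold form the area, so ties fail and an
all-equal rate vector yields an empty, flagged area. One consequence of
clamping worth knowing: for *N* ≤ 10 channels the 95th percentile
equals the maximum and the strict rule gives an empty area — the method
presumes the larger montages of clinical practice. The percentile is
always taken within one patient and HFO type, never pooled.

## Test–retest statistic

Reproducibility of the spatial distribution is the normalized scalar
product (cosine) between two interval rate vectors: 1 for proportional
profiles, 0 for disjoint support, undefined (missing) if either vector
is all-zero. Significance is judged per pair against a null built by
independently permuting both vectors' channel orders 5000 times;
the true value is significant when it strictly exceeds the 97.5th
percentile of that pair's null. The per-pair null matters: the null
distribution depends on the pair's own value multiset. Permuting both
vectors is distributionally identical to permuting one (the relative
permutation is uniform either way); both are permuted as a matter of
symmetry. All unordered interval pairs are pooled, within and between
nights; the night-level analysis repeats the procedure on per-night
mean rate vectors. With fewer than two intervals (or nights) the
summary is missing, mirroring the "—" of the clinical table. Note the
statistic's honest failure mode: a profile that is *exchangeable*
across channels (constant, or a lone hot channel among 20 with
`1/20 > 2.5%` of null mass at the top value) cannot reach significance
under the strict rule — real rate maps are heterogeneous, which is what
the statistic exploits.

## Spectral classification

For each FRandR on the patient's hottest area channel, the S-transform
of a 0.6 s window centred on the event is averaged over the FR duration
and restricted to 80–500 Hz. A sum of four Gaussian bumps is fit by
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm` on the
residual; widths bounded to [10, 200] Hz, centres to the band,
amplitudes non-negative). Initial centres are the four highest local
maxima of the lightly smoothed spectrum, deduplicated to ≥ 40 Hz
spacing and padded with spread-out positions — overlapping initial
components otherwise make the Jacobian near-singular; restarts re-space
the centres deterministically, and persistent non-convergence yields
the label "none" with a flag. Peaks and troughs are read off the fitted
curve on a 1 Hz grid by derivative sign changes; a peak is *prominent*
when it rises by ≥ 20% of the curve's maximum above its flanking
troughs (the prominence floor is a configuration key — "prominent" has
no canonical definition here). The labels, scale-invariant and mutually
exclusive: **bimodal** if a trough in [150, 250] Hz separates prominent
peaks with at least one above 200 Hz; **unimodal** if exactly one
prominent peak > 100 Hz lies in the ripple band; **none** otherwise.
The interpretation of "least-squares fitting maximum likelihood
estimation" is ordinary least squares on the power spectrum.

## Outcome validation

`classifyPatient()` crosses area-resection status with outcome:
positive ⇔ at least one area channel unresected; good outcome ⇔ ILAE 1
(primary) or ILAE 1–3 (Engel-I secondary). "Recurrent seizures" is
ILAE ≥ 2. An empty area is an error, not a silent negative. Metrics
follow the standard formulas; confidence intervals use Clopper–Pearson
below and the normal approximation above n = 10 (the boundary itself
resolves to exact; `ciMethod` overrides), and the association test is
Pearson's chi-squared without continuity correction — the variant that
reproduces the primary table's printed p-value; the secondary table's
printed p matches neither variant exactly and is reported as computed.
For 13/13 the exact interval is [75, 100]% and the asymptotic one
[100, 100]%; a published value of [78, 100]% for that cell matches
neither recipe, so the package reports its own method rather than
forcing agreement. Display rounds to integer percent; full precision is
retained in the objects.

## The synthetic-data generator

`generateRecording()` emulates the regime the detector is designed for:
per channel, Gaussian noise shaped to `1/f^(β/2)` in amplitude (β = 1
by default), flattened below 0.5 Hz to mimic the acquisition passband,
scaled to 15 µV RMS; plus Hann-windowed sinusoidal bursts at
Poisson-drawn onsets with a 200 ms refractory spacing (isolating
duration/threshold logic from overlap logic). Default burst parameters:
ripple 140 Hz carrier, 80 ms, 27.4 µVpp; FR 350 Hz, 30 ms, 9.2 µVpp —
amplitudes at the clinically reported medians, durations in the
physiological range with the ripple long enough that its envelope can
exceed threshold for 20 ms. An FRandR injection superposes both bursts
with the FR centred inside the ripple. Every injected burst is recorded
in a ground-truth table; `burstSnrDb()`/`ampForSnrDb()` convert between
amplitude and in-band SNR (peak envelope over band RMS of the analytic
1/f spectrum) so test conditions can be stated in dB.

What it does *not* emulate: spike-and-wave morphology beyond simple
sharp transients, muscle or line-noise artifacts, non-stationary sleep
architecture, inter-channel correlation, or the filtered edge effects
of real acquisition chains. Passing tests therefore demonstrate
correctness of the algorithmic chain under its stated signal model, not
clinical performance on real recordings; the clinical columns of the
packaged patient table are the bridge to the latter.

`generateCohort()` works at the rate level — per patient a
heterogeneous per-channel base-rate profile (one hot channel plus
exponential background, Poisson counts per interval), a resection set
that does or does not cover the area, and an ILAE class conditioned on
coverage — because every consumer of cohort structure (area,
test–retest, outcome) operates on rates; full waveforms are available
per patient through `generateRecording()`. A uniform background would
make rate vectors exchangeable and the permutation test rightly never
fire, which is why the background is heterogeneous by default.

## Problem sizes in the checks

The packaged test suite and `scripts/acceptance.R` run the detector on
8 bipolar channels × 5 minutes at 2000 Hz with events injected at
16 dB in-band SNR (rates 3/min ripple and FR, 2/min FRandR) — the
clearly supra-threshold regime the detector targets; sensitivity and
precision are ≥ 95%/90% there. Permutation calibration uses 10,000
exchangeable pairs with 1000 permutations each (the package default
stays at 5000; 1000 keeps the per-pair threshold accurate enough that
the empirical type-I error lands at 2.5 ± 1%). Area recovery uses 100
topographies of 20 channels × 6 intervals with the hot rate at 3× the
largest background rate. The spectral mixture check classifies 300
constructed spectra at proportions 45/28/27%. On one CPU the whole
acceptance script completes in under a minute.

## Known limitations

- Thresholds are per channel and per interval; very short intervals
  (< 60 s) give unstable baseline statistics (warned).
- The strict-exceedance area is empty for montages of ≤ 10 channels
  and degenerates under exact rate ties.
- The spectral labels depend on the prominence floor; 20% of curve
  maximum is a reasonable default, not a canonical constant.
- The EDF reader covers plain continuous 16-bit EDF in microvolts; it
  is not a general EDF+ implementation.
- Sleep staging, artifact rejection beyond channel exclusion, and
  electrode localisation are out of scope; intervals are taken as
  given.
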