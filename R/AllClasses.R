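#' @import methods
NULL

#' Multichannel iEEG recording
#'
#' Container for an equally-sampled block of intracranial EEG. Samples are
#' stored channels-by-time in microvolts. Channel labels are contact names
#' for referential recordings ("AR1") or "anode-cathode" pairs after the
#' bipolar transform ("AR1-AR2").
#'
#' @slot samples numeric matrix, `n_channels x n_samples`, in microvolts.
#' @slot rateHz sampling rate in Hz.
#' @slot labels character vector of unique channel labels, one per row.
#' @slot patientId,nightId identifiers carried through to event tables.
#'
#' @examples
#' rec <- Recording(matrix(rnorm(2000), 2, 1000), rateHz = 2000,
#'                  labels = c("A1", "A2"))
#' nChannels(rec)
#' duration(rec)
#' @export
setClass("Recording",
  representation(
    samples   = "matrix",
    rateHz    = "numeric",
    labels    = "character",
    patientId = "character",
    nightId   = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) ||
      object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (nrow(object@samples) != length(object@labels))
    msg <- c(msg, "number of rows of samples must equal length(labels)")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric matrix `n_channels x n_samples` (microvolts).
#' @param rateHz sampling rate in Hz.
#' @param labels unique channel labels, one per row of `samples`.
#' @param patientId,nightId optional identifiers.
#' @return A [Recording-class] object.
#' @export
Recording <- function(samples, rateHz, labels,
                      patientId = "P", nightId = "N1") {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  rownames(samples) <- labels
  new("Recording", samples = samples, rateHz = as.numeric(rateHz),
      labels = as.character(labels), patientId = patientId,
      nightId = nightId)
}

#' Stockwell time-frequency map
#'
#' Power (squared magnitude) of the S-transform on a discrete frequency grid.
#'
#' @slot power non-negative matrix `n_freqs x n_times`.
#' @slot freqsHz ascending frequency grid (Hz).
#' @slot timesS times of the columns, aligned to input samples (s).
#' @export
setClass("TimeFrequencyMap",
  representation(power = "matrix", freqsHz = "numeric", timesS = "numeric")
)

setValidity("TimeFrequencyMap", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@freqsHz))
    msg <- c(msg, "nrow(power) must equal length(freqsHz)")
  if (ncol(object@power) != length(object@timesS))
    msg <- c(msg, "ncol(power) must equal length(timesS)")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (is.unsorted(object@freqsHz, strictly = TRUE))
    msg <- c(msg, "freqsHz must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Baseline model for one channel and band
#'
#' Result of the first detector stage: segments of the signal judged
#' baseline (low oscillatory activity in the HFO range, identified by high
#' Stockwell entropy) and the per-band amplitude threshold derived from the
#' band-filtered envelope on those segments.
#'
#' @slot segments two-column matrix of half-open `[start_s, end_s)` baseline
#'   segments, non-overlapping and sorted.
#' @slot ampThresholdUv positive amplitude threshold (microvolts).
#' @slot fallback TRUE when no baseline could be identified and the
#'   threshold fell back to the whole-signal envelope quantile.
#' @slot entropy entropy value per analysis window (diagnostic).
#' @slot windowStartS start time of each entropy window (s).
#' @export
setClass("BaselineModel",
  representation(
    segments       = "matrix",
    ampThresholdUv = "numeric",
    fallback       = "logical",
    entropy        = "numeric",
    windowStartS   = "numeric"
  )
)

setValidity("BaselineModel", function(object) {
  msg <- character()
  if (length(object@ampThresholdUv) != 1L || object@ampThresholdUv <= 0)
    msg <- c(msg, "ampThresholdUv must be a single positive number")
  seg <- object@segments
  if (nrow(seg)) {
    if (ncol(seg) != 2L) msg <- c(msg, "segments must have two columns")
    else {
      if (any(seg[, 2] <= seg[, 1]))
        msg <- c(msg, "segment ends must exceed starts")
      if (nrow(seg) > 1L && any(seg[-1L, 1] < seg[-nrow(seg), 2]))
        msg <- c(msg, "segments must be sorted and non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HFO area of a patient
#'
#' The set of bipolar channels whose mean event rate strictly exceeds the
#' rate threshold (by default the 95th percentile of the per-patient rate
#' distribution).
#'
#' @slot channels labels of the channels in the area.
#' @slot thresholdRate the rate threshold (events/min).
#' @slot type HFO type: "ripple", "FR" or "FRandR".
#' @slot meanRates named mean rate per channel (events/min).
#' @slot degenerate TRUE when all rates tie (area empty by the strict rule).
#' @export
setClass("HFOArea",
  representation(
    channels      = "character",
    thresholdRate = "numeric",
    type          = "character",
    meanRates     = "numeric",
    degenerate    = "logical"
  )
)

setValidity("HFOArea", function(object) {
  msg <- character()
  if (!object@type %in% c("ripple", "FR", "FRandR"))
    msg <- c(msg, "type must be one of ripple, FR, FRandR")
  if (any(object@meanRates < 0)) msg <- c(msg, "rates must be non-negative")
  if (!all(object@channels %in% names(object@meanRates)))
    msg <- c(msg, "area channels must be a subset of the rate vector labels")
  if (length(msg)) msg else TRUE
})
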