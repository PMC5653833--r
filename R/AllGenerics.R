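#' @rdname Recording-class
#' @param object,x a `Recording`
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname Recording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname Recording-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname Recording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname Recording-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname Recording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname HFOArea-class
#' @param x an `HFOArea`
#' @export
setGeneric("areaChannels", function(x) standardGeneric("areaChannels"))

#' @rdname HFOArea-class
#' @export
setGeneric("thresholdRate", function(x) standardGeneric("thresholdRate"))

#' @rdname HFOArea-class
#' @export
setGeneric("meanRates", function(x) standardGeneric("meanRates"))

#' @describeIn Recording-class number of channels
setMethod("nChannels", "Recording", function(x) nrow(x@samples))

#' @describeIn Recording-class number of samples per channel
setMethod("nSamples", "Recording", function(x) ncol(x@samples))

#' @describeIn Recording-class sampling rate (Hz)
setMethod("sampleRate", "Recording", function(x) x@rateHz)

#' @describeIn Recording-class channel labels
setMethod("channelLabels", "Recording", function(x) x@labels)

#' @describeIn Recording-class the channels-by-samples matrix (microvolts)
setMethod("signalMatrix", "Recording", function(x) x@samples)

#' @describeIn Recording-class duration in seconds
setMethod("duration", "Recording", function(x) ncol(x@samples) / x@rateHz)

#' @describeIn Recording-class extract one channel's trace by label
#' @param i channel label or index
#' @param j,...,drop ignored
#' @export
setMethod("[", c("Recording", "ANY", "missing"), function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@labels)
  if (anyNA(i)) stop("unknown channel label")
  x@samples[i, ]
})

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording '%s' night '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    object@patientId, object@nightId, nChannels(object), nSamples(object),
    object@rateHz, duration(object)))
  lbl <- object@labels
  if (length(lbl) > 8) lbl <- c(lbl[1:8], "...")
  cat("  channels:", paste(lbl, collapse = " "), "\n")
})

#' @describeIn HFOArea-class channels in the area
setMethod("areaChannels", "HFOArea", function(x) x@channels)

#' @describeIn HFOArea-class the rate threshold (events/min)
setMethod("thresholdRate", "HFOArea", function(x) x@thresholdRate)

#' @describeIn HFOArea-class named mean rate per channel (events/min)
setMethod("meanRates", "HFOArea", function(x) x@meanRates)

setMethod("show", "HFOArea", function(object) {
  cat(sprintf("HFOArea (%s): threshold %.3g events/min\n",
              object@type, object@thresholdRate))
  if (length(object@channels))
    cat("  channels:", paste(object@channels, collapse = " "), "\n")
  else
    cat("  channels: (empty", if (object@degenerate) ", degenerate ties", ")\n")
})

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf(
    "BaselineModel: %d baseline segment(s), amplitude threshold %.3g uV%s\n",
    nrow(object@segments), object@ampThresholdUv,
    if (object@fallback) " [whole-signal fallback]" else ""))
})

setMethod("show", "TimeFrequencyMap", function(object) {
  cat(sprintf("TimeFrequencyMap: %d frequencies [%.1f-%.1f Hz] x %d times\n",
              length(object@freqsHz), min(object@freqsHz),
              max(object@freqsHz), length(object@timesS)))
})
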