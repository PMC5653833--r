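## Per-channel HFO rates and delineation of the HFO area by
## 95th-percentile rate thresholding.

#' Per-channel event rate for one interval
#'
#' @param events event data.frame (canonical columns).
#' @param channels full channel universe (fixed order); channels without
#'   events get rate 0. Events on channels outside the universe are an
#'   error.
#' @param durationS interval duration in seconds.
#' @param type HFO type to count: "ripple", "FR" or "FRandR".
#' @return named numeric vector of rates (events/min), one per channel.
#' @export
computeRates <- function(events, channels, durationS,
                         type = c("FRandR", "ripple", "FR")) {
  type <- match.arg(type)
  if (durationS <= 0) stop("durationS must be positive")
  ev <- events[events$type == type, , drop = FALSE]
  unknown <- setdiff(unique(ev$channel), channels)
  if (length(unknown))
    stop("events on unknown channel(s): ", paste(unknown, collapse = ", "))
  counts <- table(factor(ev$channel, levels = channels))
  r <- as.numeric(counts) / (durationS / 60)
  names(r) <- channels
  r
}

#' Rate matrix over intervals
#'
#' @param events event data.frame.
#' @param channels channel universe.
#' @param intervals data.frame with columns `night`, `interval`,
#'   `duration_s` (one row per interval).
#' @param type HFO type.
#' @return matrix channels x intervals (events/min) with `night` attached
#'   as the `"night"` attribute (character per column).
#' @export
computeRateMatrix <- function(events, channels, intervals,
                              type = c("FRandR", "ripple", "FR")) {
  type <- match.arg(type)
  cols <- lapply(seq_len(nrow(intervals)), function(i) {
    sel <- events$night == intervals$night[i] &
      events$interval == as.character(intervals$interval[i])
    computeRates(events[sel, , drop = FALSE], channels,
                 intervals$duration_s[i], type)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste(intervals$night, intervals$interval, sep = ".")
  attr(m, "night") <- as.character(intervals$night)
  m
}

#' Percentile with the reference (MATLAB prctile) convention
#'
#' The sorted sample `x_(i)` (1-based, of `N`) sits at percentile
#' `100 * (i - 0.5) / N`; values between those positions are linearly
#' interpolated and the extremes are clamped to the minimum / maximum.
#' This is the convention of the reference implementation named by the
#' method (equivalently R's `quantile(type = 5)`), reproduced here so rate
#' thresholds are bit-compatible.
#'
#' @param x numeric vector (non-empty).
#' @param q percentile in `[0, 100]`.
#' @return the percentile value.
#' @examples
#' ratePercentile(c(1, 2, 3, 4), 50)  # 2.5
#' @export
ratePercentile <- function(x, q) {
  if (!length(x)) stop("empty vector")
  if (q < 0 || q > 100) stop("q must be in [0, 100]")
  s <- sort(x)
  n <- length(s)
  pos <- 100 * (seq_len(n) - 0.5) / n
  if (q <= pos[1L]) return(s[1L])
  if (q >= pos[n]) return(s[n])
  i <- findInterval(q, pos)
  s[i] + (q - pos[i]) / (pos[i + 1L] - pos[i]) * (s[i + 1L] - s[i])
}

#' Delineate the HFO area
#'
#' The HFO area is the set of channels whose mean rate (across intervals)
#' strictly exceeds the `q`-th percentile of the mean-rate distribution
#' across channels. Ties at the threshold are excluded ("exceeded"); when
#' all channels tie the area is empty and flagged degenerate.
#'
#' @param rates matrix channels x intervals (events/min) or a single rate
#'   vector; rownames / names are the channel labels.
#' @param q percentile (default 95).
#' @param type HFO type label carried on the result.
#' @return An [HFOArea-class].
#' @export
delineateArea <- function(rates, q = 95,
                          type = c("FRandR", "ripple", "FR")) {
  type <- match.arg(type)
  if (is.matrix(rates)) {
    if (!ncol(rates)) stop("no intervals")
    mean_r <- rowMeans(rates)
  } else mean_r <- rates
  if (is.null(names(mean_r))) stop("rates must carry channel labels")
  thr <- ratePercentile(mean_r, q)
  degenerate <- length(unique(mean_r)) == 1L
  inArea <- names(mean_r)[mean_r > thr]
  if (degenerate)
    warning("all channels share the same rate; area is empty (degenerate)")
  new("HFOArea", channels = inArea, thresholdRate = thr, type = type,
      meanRates = mean_r, degenerate = degenerate)
}

#' Per-interval HFO areas
#'
#' Applies [delineateArea()] column-wise, one area per interval (the
#' test-retest display).
#'
#' @inheritParams delineateArea
#' @return list of [HFOArea-class], one per column of `rates`.
#' @export
perIntervalAreas <- function(rates, q = 95,
                             type = c("FRandR", "ripple", "FR")) {
  type <- match.arg(type)
  lapply(seq_len(ncol(rates)), function(i)
    suppressWarnings(delineateArea(rates[, i], q, type)))
}

#' Export an HFO area as JSON
#'
#' @param area an [HFOArea-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAreaJSON <- function(area, path) {
  jsonlite::write_json(
    list(type = area@type, threshold_rate = area@thresholdRate,
         channels = area@channels, mean_rates = as.list(area@meanRates),
         degenerate = area@degenerate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
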