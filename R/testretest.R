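## Test-retest reproducibility of the spatial HFO rate distribution.
##
## For every pair of 5-minute intervals the normalized scalar product
## (cosine similarity) of the two per-channel rate vectors measures how
## well the spatial topography is reproduced (~1 for overlapping
## distributions). Significance is assessed against a channel-permutation
## null built per pair: both vectors' channel orders are independently
## permuted (5000 draws) and the true value is called significant when it
## strictly exceeds the 97.5th percentile of the null.

#' Normalized scalar product of two rate vectors
#'
#' Cosine similarity `<v1, v2> / (||v1|| ||v2||)`, in `[0, 1]` for
#' non-negative rates. Undefined (NA) when either vector is all zero; such
#' pairs are excluded from summaries.
#'
#' @param v1,v2 rate vectors on the same channel order.
#' @return number in `[0, 1]`, or `NA`.
#' @export
normalizedScalarProduct <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must share channel order")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  sum(v1 * v2) / (n1 * n2)
}

#' Channel-permutation null for one interval pair
#'
#' Draws `nPerm` scalar products with both vectors' channel orders
#' independently permuted and returns the null distribution, its 97.5th
#' percentile (the significance threshold), and the significance call for
#' the true (unpermuted) value under strict exceedance.
#'
#' @param v1,v2 rate vectors (length >= 3).
#' @param nPerm number of permutations (default 5000).
#' @param thresholdPct percentile of the null used as threshold
#'   (default 97.5).
#' @return list with `value`, `null`, `threshold`, `significant`.
#' @export
permutationNull <- function(v1, v2, nPerm = 5000, thresholdPct = 97.5) {
  if (length(v1) < 3L) stop("need at least 3 channels")
  true <- normalizedScalarProduct(v1, v2)
  n <- length(v1)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (is.na(true))
    return(list(value = NA_real_, null = rep(NA_real_, nPerm),
                threshold = NA_real_, significant = NA))
  # nPerm independent uniform channel permutations for each vector,
  # generated in bulk: within each block of n uniforms, the ranking is a
  # uniform permutation
  blockPerms <- function() {
    o <- order(rep(seq_len(nPerm), each = n), stats::runif(n * nPerm))
    (o - 1L) %% n + 1L
  }
  null <- colSums(matrix(v1[blockPerms()] * v2[blockPerms()],
                         nrow = n)) / (n1 * n2)
  thr <- ratePercentile(null, thresholdPct)
  list(value = true, null = null, threshold = thr,
       significant = true > thr)
}

#' Test-retest reproducibility summary
#'
#' Computes the normalized scalar product and its permutation threshold
#' for all unordered interval pairs (pooling within- and between-night
#' pairs) and, separately, for all pairs of nights using the mean rate per
#' night. Reports the fraction of pairs whose true scalar product strictly
#' exceeds its own null threshold. With fewer than 2 intervals (or nights)
#' the corresponding percentage is missing (`NA`), mirroring the "-"
#' convention of the clinical table.
#'
#' @param rates matrix channels x intervals (events/min).
#' @param nights character/factor of length `ncol(rates)` assigning each
#'   interval to a night; defaults to the `"night"` attribute of `rates`,
#'   else a single night.
#' @param nPerm permutations per pair.
#' @param thresholdPct null percentile (default 97.5).
#' @return list with `pct_significant_intervals`,
#'   `pct_significant_nights`, `interval_pairs` and `night_pairs`
#'   data.frames (`i`, `j`, `value`, `threshold`, `significant`).
#' @export
reproducibilitySummary <- function(rates, nights = NULL, nPerm = 5000,
                                   thresholdPct = 97.5) {
  if (is.null(nights)) nights <- attr(rates, "night")
  if (is.null(nights)) nights <- rep("N1", ncol(rates))
  stopifnot(length(nights) == ncol(rates))
  pairTable <- function(m) {
    k <- ncol(m)
    if (k < 2L)
      return(data.frame(i = integer(), j = integer(), value = numeric(),
                        threshold = numeric(), significant = logical()))
    pairs <- utils::combn(k, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      pn <- permutationNull(m[, i], m[, j], nPerm, thresholdPct)
      data.frame(i = i, j = j, value = pn$value,
                 threshold = pn$threshold, significant = pn$significant)
    })
    do.call(rbind, rows)
  }
  ivp <- pairTable(rates)
  pctI <- if (!nrow(ivp) || all(is.na(ivp$significant))) NA_real_ else
    mean(ivp$significant, na.rm = TRUE)
  nightLevels <- unique(as.character(nights))
  nm <- vapply(nightLevels, function(nt)
    rowMeans(rates[, nights == nt, drop = FALSE]),
    numeric(nrow(rates)))
  nm <- matrix(nm, nrow = nrow(rates),
               dimnames = list(rownames(rates), nightLevels))
  ntp <- pairTable(nm)
  pctN <- if (!nrow(ntp) || all(is.na(ntp$significant))) NA_real_ else
    mean(ntp$significant, na.rm = TRUE)
  list(pct_significant_intervals = pctI, pct_significant_nights = pctN,
       interval_pairs = ivp, night_pairs = ntp)
}

#' Group medians and lower quartiles of per-patient percentages
#'
#' Summarises per-patient test-retest percentages by stratum (epilepsy
#' type x outcome), excluding missing values; quantiles use the same
#' reference percentile convention as the rate threshold
#' ([ratePercentile()]).
#'
#' @param values per-patient percentages (0-1 or 0-100 scale; returned on
#'   the input scale). `NA` = missing ("-").
#' @param epilepsy optional "TLE"/"ETE" per patient.
#' @param goodOutcome optional logical per patient (TRUE = good outcome).
#' @return data.frame with columns `stratum`, `n`, `median`,
#'   `lower_quartile`; strata are "all" plus every epilepsy-type and
#'   type-x-outcome combination present.
#' @export
groupMedians <- function(values, epilepsy = NULL, goodOutcome = NULL) {
  strata <- list(all = rep(TRUE, length(values)))
  if (!is.null(epilepsy))
    for (e in unique(epilepsy)) strata[[e]] <- epilepsy == e
  if (!is.null(epilepsy) && !is.null(goodOutcome))
    for (e in unique(epilepsy)) {
      strata[[paste0(e, ".good")]] <- epilepsy == e & goodOutcome
      strata[[paste0(e, ".poor")]] <- epilepsy == e & !goodOutcome
    }
  rows <- lapply(names(strata), function(s) {
    v <- values[strata[[s]] & !is.na(values)]
    if (!length(v))
      return(data.frame(stratum = s, n = 0L, median = NA_real_,
                        lower_quartile = NA_real_))
    data.frame(stratum = s, n = length(v),
               median = ratePercentile(v, 50),
               lower_quartile = ratePercentile(v, 25))
  })
  do.call(rbind, rows)
}
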