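## Patient-level clinical validation of the HFO area against the resected
## area (RA) and post-surgical seizure outcome (ILAE classification).
##
## A patient is a *positive* when the HFO area is NOT fully inside the RA
## (at least one area channel unresected: the marker says "more tissue to
## remove") and a *negative* when the area is fully resected. The call is
## true/false according to the seizure outcome: under the primary rule a
## good outcome is complete seizure freedom (ILAE 1); under the secondary
## Engel-I rule good outcome is ILAE 1-3.

#' Decide whether the HFO area was fully resected
#'
#' @param area an [HFOArea-class] (or a character vector of area
#'   channels).
#' @param resectedChannels labels of resected channels.
#' @return TRUE iff every area channel is resected; empty areas are an
#'   error (classification undefined).
#' @export
areaFullyResected <- function(area, resectedChannels) {
  ch <- if (is(area, "HFOArea")) areaChannels(area) else area
  if (!length(ch)) stop("empty HFO area: classification undefined")
  all(ch %in% resectedChannels)
}

#' Classify one patient as TP / FP / TN / FN
#'
#' @param areaResected TRUE iff the HFO area is fully inside the RA (see
#'   [areaFullyResected()]).
#' @param ilae ILAE outcome class (1-6).
#' @param rule `"ILAE-1"` (good = ILAE 1, the primary rule) or
#'   `"Engel-I"` (good = ILAE 1-3).
#' @return one of `"TP"`, `"FP"`, `"TN"`, `"FN"`; positives are patients
#'   whose HFO area was not fully resected.
#' @export
classifyPatient <- function(areaResected, ilae,
                            rule = c("ILAE-1", "Engel-I")) {
  rule <- match.arg(rule)
  if (!ilae %in% 1:6) stop("ilae must be in 1..6")
  good <- if (rule == "ILAE-1") ilae == 1 else ilae <= 3
  positive <- !areaResected
  if (positive && !good) "TP"
  else if (positive && good) "FP"
  else if (!positive && good) "TN"
  else "FN"
}

#' Confusion counts from patient labels
#'
#' @param labels character vector of `"TP"/"FP"/"TN"/"FN"`.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusionCounts <- function(labels) {
  stopifnot(all(labels %in% c("TP", "FP", "TN", "FN")))
  c(tp = sum(labels == "TP"), fp = sum(labels == "FP"),
    tn = sum(labels == "TN"), fn = sum(labels == "FN"))
}

#' Binomial confidence interval (percent)
#'
#' Exact (Clopper-Pearson) interval for small samples, normal-
#' approximation (asymptotic) interval for larger ones. The automatic rule
#' uses the exact method for `n <= 10` and the asymptotic method for
#' `n > 10`.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials (> 0).
#' @param level confidence level (default 0.95).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return numeric `c(lo, hi)` in percent.
#' @examples
#' round(binomialCI(4, 7))   # 18 90
#' @export
binomialCI <- function(k, n, level = 0.95,
                       method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must be in 0..n")
  if (method == "auto") method <- if (n <= 10) "exact" else "asymptotic"
  alpha <- 1 - level
  if (method == "exact") {
    lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    p <- k / n
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half); hi <- min(1, p + half)
  }
  100 * c(lo, hi)
}

#' Predictive metrics from confusion counts
#'
#' Specificity `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, negative and
#' positive predictive values `TN/(TN+FN)`, `TP/(TP+FP)`, and accuracy
#' `(TP+TN)/N`, as percentages with confidence intervals
#' ([binomialCI()], each on its own denominator) and the uncorrected
#' Pearson chi-squared p-value of the 2x2 association. Metrics with a
#' zero denominator are `NA` (missing).
#'
#' @param counts named counts from [confusionCounts()].
#' @param ciMethod passed to [binomialCI()].
#' @return list of class `"MetricSet"`: per metric `value` (percent, full
#'   precision) and `ci`; plus `counts`, `chi2_p`, `n`.
#' @export
computeMetrics <- function(counts, ciMethod = "auto") {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  n <- tp + fp + tn + fn
  if (n == 0) stop("all counts are zero")
  one <- function(k, d) {
    if (d == 0) return(list(value = NA_real_, ci = c(NA_real_, NA_real_)))
    list(value = 100 * k / d, ci = binomialCI(k, d, method = ciMethod))
  }
  structure(list(
    specificity = one(tn, tn + fp),
    sensitivity = one(tp, tp + fn),
    npv = one(tn, tn + fn),
    ppv = one(tp, tp + fp),
    accuracy = one(tp + tn, n),
    counts = counts, n = n,
    chi2_p = tryCatch(chi2AccuracyTest(counts), error = function(e)
      NA_real_)), class = "MetricSet")
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(sprintf("MetricSet (n = %d; TP %d FP %d TN %d FN %d)\n", x$n,
              x$counts[["tp"]], x$counts[["fp"]], x$counts[["tn"]],
              x$counts[["fn"]]))
  for (m in c("specificity", "sensitivity", "npv", "ppv", "accuracy")) {
    v <- x[[m]]
    if (is.na(v$value)) cat(sprintf("  %-12s -\n", m))
    else cat(sprintf("  %-12s %3.0f%%  CI [%.0f-%.0f%%]\n", m, v$value,
                     v$ci[1L], v$ci[2L]))
  }
  if (!is.na(x$chi2_p)) cat(sprintf("  chi2 p = %.3g\n", x$chi2_p))
  invisible(x)
}

#' Pearson chi-squared test of area-resection vs outcome
#'
#' Uncorrected (no continuity correction) chi-squared test with 1 df on
#' the 2x2 table (HFO area fully resected?) x (good outcome?).
#'
#' @param counts named counts from [confusionCounts()].
#' @return the p-value.
#' @export
chi2AccuracyTest <- function(counts) {
  tab <- matrix(c(counts[["tn"]], counts[["fp"]],
                  counts[["fn"]], counts[["tp"]]), nrow = 2L,
                dimnames = list(resected = c("yes", "no"),
                                outcome = c("good", "poor")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)")
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
}

#' Validate a patient cohort
#'
#' Classifies every patient (resected-flag x ILAE under `rule`), counts,
#' and computes the metric set, plus the cohort seizure-free rate
#' (fraction with ILAE 1).
#'
#' @param patients data.frame with one row per patient: logical (or
#'   "Y"/"N") columns `ripple_resected`, `fr_resected`, `frandr_resected`,
#'   and integer `ilae`.
#' @param type HFO type whose area-resection flag is used.
#' @param rule outcome rule, see [classifyPatient()].
#' @param ciMethod passed to [binomialCI()].
#' @return list with `labels`, `counts`, `metrics` (a `"MetricSet"`),
#'   `seizure_free_rate` (percent).
#' @export
validateCohort <- function(patients, type = c("FRandR", "ripple", "FR"),
                           rule = c("ILAE-1", "Engel-I"),
                           ciMethod = "auto") {
  type <- match.arg(type)
  rule <- match.arg(rule)
  if (!nrow(patients)) stop("need at least one patient")
  col <- switch(type, ripple = "ripple_resected", FR = "fr_resected",
                FRandR = "frandr_resected")
  res <- patients[[col]]
  if (is.character(res)) res <- toupper(trimws(res)) == "Y"
  labels <- vapply(seq_len(nrow(patients)), function(i)
    classifyPatient(res[i], patients$ilae[i], rule), "")
  counts <- confusionCounts(labels)
  list(labels = labels, counts = counts,
       metrics = computeMetrics(counts, ciMethod),
       seizure_free_rate = 100 * mean(patients$ilae == 1))
}

#' Load the packaged reference patient table
#'
#' The 20-patient clinical characteristics table shipped with the package
#' (per-type HFO-area resection flags, ILAE outcome, test-retest
#' percentages); the input to the outcome validation and the test-retest
#' group summaries.
#'
#' @param path CSV path (defaults to the packaged copy).
#' @return data.frame, one row per patient; `trt_intervals` /
#'   `trt_nights` are proportions in `[0, 1]` with `NA` for patients with
#'   too few intervals or nights.
#' @export
loadPatientTable <- function(path = system.file("extdata",
                                                "table1_patients.csv",
                                                package = "ieegHFO")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("ripple_resected", "fr_resected", "frandr_resected"))
    df[[cc]] <- toupper(trimws(df[[cc]])) == "Y"
  df
}

#' Follow-up comparison between outcome groups
#'
#' Wilcoxon rank-sum comparison of follow-up durations between good- and
#' poor-outcome patients (a balance check, not a prediction metric).
#'
#' @param patients data.frame with `followup_months` and `ilae`.
#' @param rule outcome rule.
#' @return the Wilcoxon p-value.
#' @export
followupComparison <- function(patients, rule = c("ILAE-1", "Engel-I")) {
  rule <- match.arg(rule)
  good <- if (rule == "ILAE-1") patients$ilae == 1 else patients$ilae <= 3
  stats::wilcox.test(patients$followup_months[good],
                     patients$followup_months[!good],
                     exact = FALSE)$p.value
}
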