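# Integration of per-TR metric traces into per-scan motion scores, with
# optional k-space partition weighting. Scores have units 1/s: the sum of
# the per-TR metric values divided by n * TR, where n is the number of
# outer phase-encoding steps (one per TR in this 3D sequence).

.report_scale <- function(metric_name) if (metric_name == "ccc") 100 else 1

#' Integrated motion score
#'
#' Numerical time-integral of a per-TR motion metric:
#' score = (1 / (n * TR)) * sum_i metric_i over the defined TRs. Metrics
#' start at TR 2, so an n-step acquisition contributes n - 1 terms.
#'
#' @param metric a [MotionMetricSeries-class]
#' @param n total number of phase-encoding steps in the acquisition
#' @param tr_seconds repetition time in seconds
#' @param weighted internal flag recorded on the result
#' @return an [IntegratedScore-class] (value in 1/s; the cross-correlation
#'   metric carries a x100 display scale, as conventional in reports)
#' @export
integrateScore <- function(metric, n, tr_seconds, weighted = FALSE) {
  stopifnot(is(metric, "MotionMetricSeries"))
  vals <- metricValues(metric)
  if (length(vals) == 0L) stop("metric trace is empty")
  if (n < length(vals)) stop("n must be >= the number of defined TRs")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  new("IntegratedScore", value = sum(vals) / (n * tr_seconds),
      metricName = metricName(metric), weighted = weighted,
      reportScale = .report_scale(metricName(metric)))
}

#' k-space partition weights from reference acquisitions
#'
#' The impact of motion at a given phase-encoding step is proportional to
#' the k-space energy encoded there. Weights are computed as the Euclidean
#' norm of each acquired k-space plane (outer phase-encode dimension =
#' first array dimension), averaged across reference subjects, then
#' normalized to unit mean.
#'
#' @param reference_kspace list of 3D arrays (or matrices), one per
#'   reference subject; magnitude or complex k-space with planes along the
#'   first dimension
#' @return a [KspaceWeighting-class]
#' @export
kspaceWeightsFromReference <- function(reference_kspace) {
  if (!is.list(reference_kspace)) reference_kspace <- list(reference_kspace)
  norms <- lapply(reference_kspace, function(k) {
    k <- as.array(k)
    m <- matrix(k, nrow = dim(k)[1])
    sqrt(rowSums(Mod(m)^2))
  })
  n <- unique(vapply(norms, length, integer(1)))
  if (length(n) != 1L)
    stop("reference volumes have mismatched phase-encode plane counts")
  w <- Reduce(`+`, norms) / length(norms)
  KspaceWeighting(w / mean(w),
                  source = sprintf("norm of k-space planes, %d subject(s)",
                                   length(norms)))
}

#' Default synthetic k-space partition weighting
#'
#' Smooth centre-peaked weighting over `n` acquisition steps, emulating the
#' typical k-space plane-norm profile of a structural brain scan acquired
#' with linear Cartesian ordering (centre of k-space reached halfway
#' through). Provided for workflows that only have navigator CSVs and no
#' reference k-space; labelled synthetic in its `source`.
#'
#' @param n number of phase-encoding steps
#' @param width Lorentzian half-width as a fraction of n
#' @param floor baseline weight level at the k-space periphery
#' @return a [KspaceWeighting-class] with unit-mean weights
#' @export
defaultKspaceWeights <- function(n, width = 0.08, floor = 0.15) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  centre <- (n + 1) / 2
  w <- floor + 1 / (1 + ((i - centre) / (width * n))^2)
  KspaceWeighting(w / mean(w), source = "synthetic centre-peaked default")
}

#' Partition-weighted integrated motion score
#'
#' As [integrateScore()] but each per-TR metric value is multiplied by the
#' k-space weight of its acquisition step:
#' score = (1 / (n * TR)) * sum_i w_i * metric_i. Trimmed series stay
#' aligned through the trace's `startStep`.
#'
#' @inheritParams integrateScore
#' @param weighting a [KspaceWeighting-class] or a bare numeric weight
#'   vector of length `n`
#' @return an [IntegratedScore-class]
#' @export
weightedIntegrate <- function(metric, weighting, n, tr_seconds) {
  stopifnot(is(metric, "MotionMetricSeries"))
  w <- if (is(weighting, "KspaceWeighting")) stepWeights(weighting)
       else as.numeric(weighting)
  if (length(w) != n)
    stop(sprintf("weight vector length %d does not match n = %d",
                 length(w), n))
  vals <- metricValues(metric)
  if (length(vals) == 0L) stop("metric trace is empty")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  steps <- seq.int(startStep(metric), length.out = length(vals))
  if (max(steps) > n)
    stop("metric trace extends beyond the n phase-encoding steps")
  new("IntegratedScore", value = sum(w[steps] * vals) / (n * tr_seconds),
      metricName = metricName(metric), weighted = TRUE,
      reportScale = .report_scale(metricName(metric)))
}

#' All eight integrated scores of one navigator series
#'
#' Convenience wrapper computing the four metrics and their raw and
#' partition-weighted integrals.
#'
#' @param series a trimmed [FidnavSeries-class]
#' @param weighting a [KspaceWeighting-class]; default
#'   [defaultKspaceWeights()] over the series' steps
#' @param ... passed to [fidnavMetrics()]
#' @return one-row data.frame with columns `<metric>` and `w_<metric>`
#'   (raw 1/s values, no display scaling)
#' @export
subjectScores <- function(series, weighting = NULL, ...) {
  n <- nSteps(series)
  if (is.null(weighting)) weighting <- defaultKspaceWeights(n)
  mets <- fidnavMetrics(series, ...)
  out <- list(subject_id = subjectId(series))
  for (nm in names(mets)) {
    out[[nm]] <- scoreValue(integrateScore(mets[[nm]], n,
                                           trSeconds(series)))
    out[[paste0("w_", nm)]] <-
      scoreValue(weightedIntegrate(mets[[nm]], weighting, n,
                                   trSeconds(series)))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
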