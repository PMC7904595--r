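# Scan-abort analysis: the running (cumulative) motion score, the abort
# decision against a predefined threshold, the aggregate time savings of
# aborting motion-corrupted scans, and the dollar cost model.

#' Running (cumulative) motion score
#'
#' Cumulative sum of the per-TR metric values scaled by 1/(n * TR), so the
#' final element equals the integrated score of the whole scan. Because all
#' published metrics are non-negative the running score is non-decreasing,
#' making the first threshold crossing unique.
#'
#' @inheritParams integrateScore
#' @return numeric vector of cumulative scores, with attribute `steps`
#'   giving the acquisition step of each element
#' @export
runningScore <- function(metric, n, tr_seconds) {
  stopifnot(is(metric, "MotionMetricSeries"))
  vals <- metricValues(metric)
  if (length(vals) == 0L) stop("metric trace is empty")
  if (any(vals < 0)) stop("metric values must be non-negative")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  out <- cumsum(vals) / (n * tr_seconds)
  attr(out, "steps") <- seq.int(startStep(metric), length.out = length(vals))
  out
}

#' Abort decision for one scan
#'
#' Finds the first TR at which the running motion score reaches the
#' threshold. If crossed at acquisition step i* of n, the fraction of the
#' scan already acquired is FA = i*/n and the fraction remaining (the time
#' that aborting would save) is FR = 1 - FA.
#'
#' @param running output of [runningScore()]
#' @param threshold abort threshold (on the integrated-score scale), > 0
#' @param n total number of acquisition steps
#' @return list with `detected`, `crossing_step` (NA if never crossed),
#'   `fa`, `fr` (NA if never crossed)
#' @export
abortDecision <- function(running, threshold, n) {
  if (threshold <= 0) stop("threshold must be positive")
  steps <- attr(running, "steps")
  if (is.null(steps)) steps <- seq_along(running)
  hit <- which(running >= threshold)
  if (length(hit) == 0L)
    return(list(detected = FALSE, crossing_step = NA_integer_,
                fa = NA_real_, fr = NA_real_))
  i_star <- steps[hit[1]]
  fa <- i_star / n
  list(detected = TRUE, crossing_step = as.integer(i_star),
       fa = fa, fr = 1 - fa)
}

.abort_counts <- function(outcomes) {
  det <- outcomes$detected; pos <- outcomes$positive
  list(tp = sum(det & pos), fn = sum(!det & pos),
       fp = sum(det & !pos), tn = sum(!det & !pos))
}

#' Aggregate time savings of threshold-based scan aborts
#'
#' Non-diagnostic scans are assumed to be reacquired after completion, so
#' without monitoring each costs 2 TA; diagnostic scans cost TA. Aborting a
#' true positive saves FR x TA; aborting a false positive wastes FA x TA
#' (the scan is restarted). The aggregate saving, as a percentage of the
#' no-monitoring baseline, is
#' 100 * (sum FR over TPs - sum FA over FPs) / D, where by default
#' D = 2 (nTP + nFN) + nTN + nFP (every non-diagnostic scan counted at
#' 2 TA). `grouping = "printed"` uses the literal grouping
#' D = 2 nTP + nFN + nTN + nFP instead.
#'
#' @param outcomes data.frame with logical columns `detected`, `positive`
#'   (truth: non-diagnostic) and numeric `fr`, `fa` (NA where undetected),
#'   one row per scan — as built by [cohortAbortOutcomes()]
#' @param grouping denominator convention, `"doubled_positives"` (default)
#'   or `"printed"`
#' @return list with `t_savings_pct`, the confusion counts and the FR/FA
#'   sums
#' @export
timeSavings <- function(outcomes,
                        grouping = c("doubled_positives", "printed")) {
  grouping <- match.arg(grouping)
  if (nrow(outcomes) == 0L) stop("empty cohort")
  cnt <- .abort_counts(outcomes)
  sum_fr <- sum(outcomes$fr[outcomes$detected & outcomes$positive])
  sum_fa <- sum(outcomes$fa[outcomes$detected & !outcomes$positive])
  denom <- if (grouping == "doubled_positives")
    2 * (cnt$tp + cnt$fn) + cnt$tn + cnt$fp
  else
    2 * cnt$tp + cnt$fn + cnt$tn + cnt$fp
  list(t_savings_pct = 100 * (sum_fr - sum_fa) / denom,
       n_tp = cnt$tp, n_fp = cnt$fp, n_tn = cnt$tn, n_fn = cnt$fn,
       sum_fr = sum_fr, sum_fa = sum_fa)
}

#' Abort outcomes for a cohort of metric traces
#'
#' Applies [runningScore()] and [abortDecision()] to every subject.
#'
#' @param metrics list of [MotionMetricSeries-class], one per subject
#' @param positive logical truth labels (non-diagnostic scan)
#' @param threshold abort threshold on the integrated-score scale
#' @param n acquisition steps per scan
#' @param tr_seconds repetition time in seconds
#' @param subject_ids optional identifiers
#' @return data.frame, one row per scan: `subject_id`, `positive`,
#'   `detected`, `crossing_step`, `fa`, `fr`
#' @export
cohortAbortOutcomes <- function(metrics, positive, threshold, n, tr_seconds,
                                subject_ids = seq_along(metrics)) {
  stopifnot(length(metrics) == length(positive))
  rows <- lapply(seq_along(metrics), function(k) {
    dec <- abortDecision(runningScore(metrics[[k]], n, tr_seconds),
                         threshold, n)
    data.frame(subject_id = subject_ids[k], positive = positive[k],
               detected = dec$detected, crossing_step = dec$crossing_step,
               fa = dec$fa, fr = dec$fr)
  })
  do.call(rbind, rows)
}

#' Cohort cost report
#'
#' Combines the abort outcomes with a [CostModel-class]: the baseline cost
#' of repeating every non-diagnostic scan, the minutes saved by aborting
#' true positives, the minutes wasted restarting false positives, and the
#' net cost saving at the scanner's per-minute rate.
#'
#' @param grades radiologist grades 1..5, one per scan
#' @param outcomes abort outcomes as from [cohortAbortOutcomes()]; may be
#'   `NULL` for the baseline-only report
#' @param cost a [CostModel-class]
#' @param grouping passed to [timeSavings()]
#' @return a [SavingsReport-class]
#' @export
costReport <- function(grades, outcomes = NULL, cost = costModel(),
                       grouping = "doubled_positives") {
  stopifnot(is(cost, "CostModel"))
  cpm <- cost@slotCost / cost@slotMinutes
  n_repeat <- sum(grades <= 2)
  repeat_minutes <- n_repeat * cost@taMinutes
  repeat_cost <- repeat_minutes * cpm
  if (is.null(outcomes)) {
    return(new("SavingsReport", tSavingsPct = NA_real_,
               nTP = 0L, nFP = 0L, nTN = 0L, nFN = 0L,
               minutesSaved = 0, minutesWasted = 0,
               repeatCost = repeat_cost, repeatMinutes = repeat_minutes,
               netCostSaving = 0, costPerMinute = cpm))
  }
  ts <- timeSavings(outcomes, grouping = grouping)
  saved <- ts$sum_fr * cost@taMinutes
  wasted <- ts$sum_fa * cost@taMinutes
  new("SavingsReport", tSavingsPct = ts$t_savings_pct,
      nTP = as.integer(ts$n_tp), nFP = as.integer(ts$n_fp),
      nTN = as.integer(ts$n_tn), nFN = as.integer(ts$n_fn),
      minutesSaved = saved, minutesWasted = wasted,
      repeatCost = repeat_cost, repeatMinutes = repeat_minutes,
      netCostSaving = (saved - wasted) * cpm, costPerMinute = cpm)
}

#' Threshold maximizing the aggregate time savings
#'
#' Grid search over the union of all subjects' final integrated scores plus
#' the midpoints between consecutive candidates. Ties are broken toward the
#' larger threshold (fewer false aborts).
#'
#' @inheritParams cohortAbortOutcomes
#' @param grouping passed to [timeSavings()]
#' @return list with `threshold` and `t_savings_pct`
#' @export
optimizeThresholdForSavings <- function(metrics, positive, n, tr_seconds,
                                        grouping = "doubled_positives") {
  stopifnot(length(metrics) == length(positive))
  running <- lapply(metrics, runningScore, n = n, tr_seconds = tr_seconds)
  finals <- vapply(running, function(r) r[length(r)], numeric(1))
  cand <- sort(unique(finals[finals > 0]))
  if (length(cand) == 0L) stop("all integrated scores are zero")
  if (length(cand) > 1L)
    cand <- sort(unique(c(cand, (head(cand, -1) + tail(cand, -1)) / 2)))
  eval_thr <- function(thr) {
    dec <- lapply(running, abortDecision, threshold = thr, n = n)
    outcomes <- data.frame(
      positive = positive,
      detected = vapply(dec, `[[`, logical(1), "detected"),
      fa = vapply(dec, `[[`, numeric(1), "fa"),
      fr = vapply(dec, `[[`, numeric(1), "fr"))
    timeSavings(outcomes, grouping = grouping)$t_savings_pct
  }
  sav <- vapply(cand, eval_thr, numeric(1))
  best <- max(sav)
  thr <- cand[max(which(sav >= best - 1e-12))]   # tie -> larger threshold
  list(threshold = thr, t_savings_pct = best)
}
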