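# Cohort-level analysis and report layout: per-grade score summaries with
# a Spearman row, and the detection table (AUC, J, threshold, SE, SP per
# metric and dichotomization).

.metric_cols <- c("delta_ref", "delta", "delta_max", "ccc")
.all_score_cols <- c(.metric_cols, paste0("w_", .metric_cols))

#' Score every subject of a cohort
#'
#' Runs preprocessing (pre-steady-state trim) and all eight integrated
#' scores over a list of navigator series.
#'
#' @param series list of [FidnavSeries-class]
#' @param grades radiologist (or ground-truth) grades, one per series
#' @param weighting a [KspaceWeighting-class]; default
#'   [defaultKspaceWeights()]
#' @param n_discard pre-steady-state TRs to discard
#' @param n_ref TRs averaged into the fixed reference
#' @return data.frame: `subject_id`, `grade`, eight raw score columns
#'   (1/s, no display scaling)
#' @export
scoreCohort <- function(series, grades, weighting = NULL, n_discard = 3L,
                        n_ref = 3L) {
  stopifnot(length(series) == length(grades))
  rows <- lapply(series, function(s) {
    s <- trimPresteady(s, n_discard)
    subjectScores(s, weighting = weighting, n_ref = n_ref)
  })
  out <- do.call(rbind, rows)
  out$grade <- as.integer(grades)
  out[, c("subject_id", "grade", .all_score_cols)]
}

#' Per-grade score summary (display layout)
#'
#' Mean and SD of each of the eight integrated score variants per grade,
#' with the cross-correlation scores on their x100 display scale, plus a
#' Spearman correlation row (|rho| of score vs grade).
#'
#' @param score_df output of [scoreCohort()]
#' @param path optional CSV output path
#' @return data.frame in display layout
#' @export
gradeSummaryTable <- function(score_df, path = NULL) {
  scale_of <- function(col) if (grepl("ccc$", col)) 100 else 1
  grades <- sort(unique(score_df$grade), decreasing = TRUE)
  rows <- lapply(grades, function(g) {
    sub <- score_df[score_df$grade == g, ]
    vals <- lapply(.all_score_cols, function(col) {
      x <- sub[[col]] * scale_of(col)
      sprintf("%.2f +/- %.2f", mean(x), sd(x))
    })
    c(list(row = sprintf("Grade %d (n = %d)", g, nrow(sub))),
      setNames(vals, .all_score_cols))
  })
  sp <- lapply(.all_score_cols, function(col)
    sprintf("%.2f",
            abs(spearmanScoreGrade(score_df[[col]], score_df$grade)$rho)))
  rows[[length(rows) + 1L]] <- c(list(row = "Spearman correlation"),
                                 setNames(sp, .all_score_cols))
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Detection table: ROC + bootstrap per metric and dichotomization
#'
#' For each integrated metric and each grade dichotomization: full-sample
#' AUC and Youden-optimal threshold, bootstrap mean +/- SD of AUC and J,
#' and the 0.632-estimator sensitivity and specificity. Thresholds for the
#' cross-correlation metric are reported on the raw scale.
#'
#' @param score_df output of [scoreCohort()]
#' @param metrics score columns to analyse (default the four unweighted)
#' @param schemes dichotomizations to analyse
#' @param b bootstrap replicates
#' @param seed RNG seed
#' @param path optional CSV output path
#' @return data.frame: metric, scheme, auc, auc_sd, j, j_sd, threshold,
#'   se, sp
#' @export
detectionTable <- function(score_df, metrics = .metric_cols,
                           schemes = c("12v345", "123v45"), b = 1000L,
                           seed = 1L, path = NULL) {
  rows <- list()
  for (scheme in schemes) {
    positive <- dichotomizeGrades(score_df$grade, scheme)
    for (m in metrics) {
      scores <- score_df[[m]]
      bs <- bootstrap632(scores, positive, b = b, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, scheme = scheme,
        auc = bs@aucMean, auc_sd = bs@aucSd,
        j = bs@jMean, j_sd = bs@jSd,
        threshold = bs@threshold, se = bs@se632, sp = bs@sp632,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' End-to-end abort/savings analysis of a scored cohort
#'
#' Recomputes the chosen metric's running scores, applies the threshold,
#' and produces the time-savings and cost report. The threshold may be a
#' number or `"youden"` (full-sample Youden-optimal for the chosen metric
#' and dichotomization).
#'
#' @param series list of [FidnavSeries-class]
#' @param grades grades, one per series
#' @param metric metric name (default `"ccc"`, the best detector)
#' @param threshold numeric, or `"youden"`
#' @param scheme dichotomization defining the positive (non-diagnostic)
#'   class
#' @param cost a [CostModel-class]
#' @param n_discard pre-steady-state TRs to discard
#' @return list with `report` (a [SavingsReport-class]), `outcomes`,
#'   `threshold`
#' @export
abortAnalysis <- function(series, grades, metric = "ccc",
                          threshold = "youden", scheme = "12v345",
                          cost = costModel(), n_discard = 3L) {
  stopifnot(length(series) == length(grades))
  trimmed <- lapply(series, trimPresteady, n_discard = n_discard)
  traces <- lapply(trimmed, function(s) {
    switch(metric,
           delta_ref = deltaRef(s),
           delta = deltaPrev(s),
           delta_max = deltaMax(s),
           ccc = cccMetric(s),
           stop("unknown metric: ", metric))
  })
  n <- nSteps(series[[1]])
  tr <- trSeconds(series[[1]])
  positive <- dichotomizeGrades(grades, scheme)
  if (identical(threshold, "youden")) {
    scores <- vapply(traces, function(m)
      scoreValue(integrateScore(m, n, tr)), numeric(1))
    threshold <- rocCurve(scores, positive)@optimalThreshold
  }
  outcomes <- cohortAbortOutcomes(traces, positive, threshold, n, tr,
                                  subject_ids = vapply(series, subjectId,
                                                       character(1)))
  report <- costReport(grades, outcomes, cost)
  list(report = report, outcomes = outcomes, threshold = threshold)
}

#' Write a savings report as JSON
#'
#' @param report a [SavingsReport-class]
#' @param path output JSON path
#' @param extra named list merged into the output (e.g. threshold used)
#' @return `path`, invisibly
#' @export
writeSavingsJson <- function(report, path, extra = list()) {
  stopifnot(is(report, "SavingsReport"))
  out <- c(list(
    t_savings_pct = report@tSavingsPct,
    n_tp = report@nTP, n_fp = report@nFP,
    n_tn = report@nTN, n_fn = report@nFN,
    minutes_saved = report@minutesSaved,
    minutes_wasted = report@minutesWasted,
    repeat_minutes = report@repeatMinutes,
    repeat_cost = round(report@repeatCost),
    net_cost_saving = round(report@netCostSaving),
    cost_per_minute = report@costPerMinute), extra)
  out$config_hash <- configHash(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
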