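# Threshold-based detection statistics: confusion counts, empirical ROC
# with trapezoidal AUC, Youden-optimal threshold, the 0.632 bootstrap
# estimator of out-of-sample sensitivity/specificity, Spearman rank
# correlation against image grade, and weighted Cohen's kappa for
# inter-rater agreement.

#' Dichotomize radiologist grades
#'
#' Grades run 1 (severe artifact, non-diagnostic) to 5 (no appreciable
#' artifact). Two dichotomizations are standard: `"12v345"` marks
#' non-diagnostic scans (grades 1-2) positive; `"123v45"` marks scans with
#' impaired diagnostic quality (grades 1-3) positive.
#'
#' @param grades integer vector in 1..5
#' @param scheme `"12v345"` or `"123v45"`
#' @return logical vector, `TRUE` = positive (motion-corrupted)
#' @export
dichotomizeGrades <- function(grades, scheme = c("12v345", "123v45")) {
  scheme <- match.arg(scheme)
  if (any(!grades %in% 1:5)) stop("grades must be integers in 1..5")
  grades <= if (scheme == "12v345") 2L else 3L
}

.check_labels <- function(positive) {
  if (!is.logical(positive) || anyNA(positive))
    stop("labels must be logical without NAs")
  if (!any(positive) || all(positive))
    stop("both a positive and a negative class are required")
}

#' Confusion counts at a detection threshold
#'
#' A scan is called positive (motion-corrupted, to be aborted) when its
#' score is greater than or equal to the threshold. Sensitivity is
#' TP/(TP+FN); specificity is TN/(TN+FP).
#'
#' @param scores numeric motion scores, higher = more motion
#' @param positive logical truth labels (`TRUE` = motion-corrupted)
#' @param threshold decision threshold c
#' @return list with `tp`, `fp`, `tn`, `fn`, `se`, `sp`
#' @export
confusionCounts <- function(scores, positive, threshold) {
  .check_labels(positive)
  if (length(scores) != length(positive))
    stop("scores and labels must have equal length")
  call_pos <- scores >= threshold
  tp <- sum(call_pos & positive); fn <- sum(!call_pos & positive)
  fp <- sum(call_pos & !positive); tn <- sum(!call_pos & !positive)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       se = tp / (tp + fn), sp = tn / (tn + fp))
}

#' Empirical ROC analysis
#'
#' Candidate thresholds are the sorted unique scores plus a +Inf sentinel
#' (at which nothing is called positive). The AUC is the trapezoidal area
#' under the (1 - SP, SE) curve, which equals the tie-corrected
#' Mann-Whitney probability that a positive outscores a negative.
#'
#' @inheritParams confusionCounts
#' @return a [RocResult-class]
#' @export
rocCurve <- function(scores, positive) {
  .check_labels(positive)
  if (length(scores) != length(positive))
    stop("scores and labels must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  thr <- c(sort(unique(scores)), Inf)
  cc <- lapply(thr, function(c) confusionCounts(scores, positive, c))
  se <- vapply(cc, `[[`, numeric(1), "se")
  sp <- vapply(cc, `[[`, numeric(1), "sp")
  # integrate over the curve ordered by increasing false positive rate
  fpr <- rev(1 - sp); tpr <- rev(se)
  fpr <- c(0, fpr); tpr <- c(0, tpr)   # +Inf sentinel gives the (0,0) end
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  j <- se + sp - 1
  jmax <- max(j)
  opt <- thr[which(j >= jmax - 1e-12)[1]]   # ties broken low (higher SE)
  new("RocResult", thresholds = thr, se = se, sp = sp, auc = auc,
      youdenJ = jmax, optimalThreshold = opt)
}

#' Youden-optimal operating point
#'
#' Maximizes J = SE + SP - 1 over the candidate thresholds of a ROC
#' analysis; ties are broken toward the smaller threshold, favouring
#' sensitivity.
#'
#' @param roc a [RocResult-class]
#' @return list with `j` and `threshold`
#' @export
youdenOptimal <- function(roc) {
  stopifnot(is(roc, "RocResult"))
  list(j = roc@youdenJ, threshold = roc@optimalThreshold)
}

# the 0.632 blend of resubstitution and out-of-bag accuracy, with the
# constants as conventionally printed (0.368/0.632, not 1/e)
.blend632 <- function(acc_res, acc_oob) 0.368 * acc_res + 0.632 * acc_oob

.replicate_seed <- function(seed, i) {
  # counter-based stream split: replicate i's stream is independent of
  # execution order (31-bit to stay within R's integer range)
  as.integer((as.double(seed) * 1103515245 + i * 12345) %% 2147483647)
}

#' 0.632 bootstrap of detection accuracy
#'
#' Draws `b` bootstrap samples of the cohort with replacement. On each
#' replicate the ROC analysis and Youden-optimal threshold are recomputed;
#' the replicate's resubstitution sensitivity/specificity (on the bootstrap
#' sample itself) and holdout sensitivity/specificity (on the out-of-bag
#' subjects) are blended by the 0.632 estimator,
#' Acc = mean_i(0.368 * Acc_res,i + 0.632 * Acc_oob,i), which corrects the
#' optimism of resubstitution and the pessimism of out-of-bag estimates.
#' Replicates whose bootstrap sample or out-of-bag set lacks a class are
#' redrawn (counted in `redraws`).
#'
#' @inheritParams confusionCounts
#' @param b number of bootstrap replicates (default 1000)
#' @param seed integer RNG seed; replicate streams are derived from it by
#'   counter-based splitting
#' @return a [BootstrapResult-class]
#' @export
bootstrap632 <- function(scores, positive, b = 1000L, seed = 1L) {
  .check_labels(positive)
  n <- length(scores)
  if (n < 4L) stop("too few subjects to bootstrap")
  full <- rocCurve(scores, positive)
  auc_i <- j_i <- se_i <- sp_i <- numeric(b)
  redraws <- 0L
  for (i in seq_len(b)) {
    attempt <- 0L
    repeat {
      set.seed(.replicate_seed(seed, i * 1000L + attempt))
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      ok <- any(positive[idx]) && !all(positive[idx]) &&
        length(oob) > 0L && any(positive[oob]) && !all(positive[oob])
      if (ok) break
      redraws <- redraws + 1L
      attempt <- attempt + 1L
      if (attempt > 1000L) stop("could not draw a usable bootstrap sample")
    }
    rep_roc <- rocCurve(scores[idx], positive[idx])
    auc_i[i] <- rep_roc@auc
    j_i[i] <- rep_roc@youdenJ
    thr <- rep_roc@optimalThreshold
    res <- confusionCounts(scores[idx], positive[idx], thr)
    hold <- confusionCounts(scores[oob], positive[oob], thr)
    se_i[i] <- .blend632(res$se, hold$se)
    sp_i[i] <- .blend632(res$sp, hold$sp)
  }
  new("BootstrapResult", b = as.integer(b), seed = as.integer(seed),
      aucMean = mean(auc_i), aucSd = if (b > 1) sd(auc_i) else 0,
      jMean = mean(j_i), jSd = if (b > 1) sd(j_i) else 0,
      threshold = full@optimalThreshold,
      se632 = mean(se_i), sp632 = mean(sp_i), redraws = redraws)
}

#' Spearman rank correlation of motion score and image grade
#'
#' Average-rank Spearman correlation with a two-sided p-value from the t
#' approximation. Motion scores decrease with grade, so a working metric is
#' expected to show a negative rho against grade (or, equivalently,
#' positive against artifact severity).
#'
#' @param scores numeric motion scores
#' @param grades numeric grades (or any ordinal covariate)
#' @return list with `rho` and `p`
#' @export
spearmanScoreGrade <- function(scores, grades) {
  if (length(scores) != length(grades))
    stop("scores and grades must have equal length")
  if (length(scores) < 3L) stop("need at least 3 observations")
  if (sd(scores) == 0 || sd(grades) == 0) {
    warning("constant input; Spearman correlation undefined, returning 0")
    return(list(rho = 0, p = NA_real_))
  }
  ct <- suppressWarnings(
    cor.test(scores, grades, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Weighted Cohen's kappa between two raters
#'
#' Chance-corrected agreement on an ordinal scale with linear (default) or
#' quadratic disagreement weights:
#' kappa = 1 - sum(v * O) / sum(v * E), where O and E are the observed and
#' expected (product of margins) contingency proportions and
#' v_kl = |k - l| (linear) or (k - l)^2 (quadratic). The 95% CI is a
#' percentile bootstrap over subjects.
#'
#' @param grades_a,grades_b paired ratings on the same scale
#' @param weighting `"linear"` or `"quadratic"`
#' @param levels rating levels; default the sorted union of both raters
#' @param ci_b bootstrap replicates for the CI (default 2000); 0 skips it
#' @param seed RNG seed for the CI bootstrap
#' @return list with `kappa`, `ci` (length-2 or NULL), `weighting`
#' @export
weightedKappa <- function(grades_a, grades_b,
                          weighting = c("linear", "quadratic"),
                          levels = sort(union(grades_a, grades_b)),
                          ci_b = 2000L, seed = 1L) {
  weighting <- match.arg(weighting)
  if (length(grades_a) != length(grades_b))
    stop("the two rating vectors must have equal length")
  k <- length(levels)
  if (k < 2L) stop("need at least two rating levels")
  d <- abs(outer(seq_len(k), seq_len(k), `-`))
  v <- if (weighting == "linear") d else d^2
  kap <- function(a, b) {
    o <- table(factor(a, levels), factor(b, levels)) / length(a)
    e <- outer(rowSums(o), colSums(o))
    den <- sum(v * e)
    if (den == 0) return(1)   # all mass on one cell: trivially perfect
    1 - sum(v * o) / den
  }
  est <- kap(grades_a, grades_b)
  ci <- NULL
  if (ci_b > 0L) {
    n <- length(grades_a)
    reps <- vapply(seq_len(ci_b), function(i) {
      set.seed(.replicate_seed(seed, i))
      idx <- sample.int(n, n, replace = TRUE)
      kap(grades_a[idx], grades_b[idx])
    }, numeric(1))
    ci <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }
  list(kappa = est, ci = ci, weighting = weighting)
}
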