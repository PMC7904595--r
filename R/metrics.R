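# The four multi-channel coil-combination motion metrics. Each compresses
# the per-channel complex navigator signal at TR i into one real number,
# defined for i >= 2 (comparison against the previous TR or a fixed
# reference), yielding n - 1 values for an n-step acquisition.

.check_denominator <- function(denom, max_mag, floor_rel, what) {
  floor <- floor_rel * max_mag
  bad <- which(denom < floor)
  if (length(bad))
    stop(sprintf("degenerate %s: channel(s) %s have magnitude below %g",
                 what, paste(bad, collapse = ", "), floor))
}

#' Reference-change motion metric
#'
#' Normalized mean absolute change of the complex navigator signal over all
#' channels, relative to a fixed per-channel reference: at TR i,
#' mean_j |s_j(i) - s_j(ref)| / |s_j(ref)|. Sensitive to any departure from
#' the initial head position.
#'
#' @param series a [FidnavSeries-class]
#' @param ref per-channel complex reference; defaults to
#'   [referenceSignal()] of `series`
#' @param floor_rel denominator guard: error if any reference magnitude is
#'   below `floor_rel * max(|signal|)`
#' @return a [MotionMetricSeries-class] starting at the series' second TR
#' @export
deltaRef <- function(series, ref = referenceSignal(series),
                     floor_rel = 1e-12) {
  stopifnot(is(series, "FidnavSeries"))
  s <- fidSignal(series)
  if (length(ref) != nrow(s))
    stop("reference length must equal the number of channels")
  .check_denominator(Mod(ref), max(Mod(s)), floor_rel, "reference")
  vals <- colMeans(Mod(s[, -1L, drop = FALSE] - ref) / Mod(ref))
  MotionMetricSeries(vals, firstStep(series) + 1L, "delta_ref")
}

#' Previous-TR change motion metric
#'
#' As [deltaRef()] but relative to the immediately preceding TR:
#' mean_j |s_j(i) - s_j(i-1)| / |s_j(i-1)|. Chosen because subjects rarely
#' return to their initial position after a motion event, so a fixed
#' reference accumulates offset while this metric isolates events.
#'
#' @inheritParams deltaRef
#' @return a [MotionMetricSeries-class]
#' @export
deltaPrev <- function(series, floor_rel = 1e-12) {
  stopifnot(is(series, "FidnavSeries"))
  s <- fidSignal(series)
  if (ncol(s) < 2L) stop("need at least 2 TRs")
  prev <- s[, -ncol(s), drop = FALSE]
  cur <- s[, -1L, drop = FALSE]
  .check_denominator(apply(Mod(prev), 1L, min), max(Mod(s)), floor_rel,
                     "previous-TR denominator")
  vals <- colMeans(Mod(cur - prev) / Mod(prev))
  MotionMetricSeries(vals, firstStep(series) + 1L, "delta")
}

#' Maximally-changing-channels motion metric
#'
#' Normalized mean change in the navigator magnitude over the `top_k`
#' channels with the largest relative magnitude change at each TR:
#' r_j = | |s_j(i)| - |s_j(i-1)| | / |s_j(i-1)|, averaged over the `top_k`
#' largest r_j (channel set re-selected every TR). Averaging only the
#' maximally changing channels suppresses random fluctuations while
#' retaining sensitivity to fast motion.
#'
#' @inheritParams deltaRef
#' @param top_k number of channels to average (default 3); if the array has
#'   fewer channels, all are used with a warning
#' @return a [MotionMetricSeries-class]
#' @export
deltaMax <- function(series, top_k = 3L, floor_rel = 1e-12) {
  stopifnot(is(series, "FidnavSeries"))
  s <- Mod(fidSignal(series))
  if (ncol(s) < 2L) stop("need at least 2 TRs")
  if (nrow(s) < top_k) {
    warning(sprintf(
      "only %d channels available; averaging all instead of top %d",
      nrow(s), top_k))
    top_k <- nrow(s)
  }
  prev <- s[, -ncol(s), drop = FALSE]
  cur <- s[, -1L, drop = FALSE]
  .check_denominator(apply(prev, 1L, min), max(s), floor_rel,
                     "previous-TR denominator")
  r <- abs(cur - prev) / prev
  vals <- apply(r, 2L, function(col)
    mean(sort(col, decreasing = TRUE)[seq_len(top_k)]))
  MotionMetricSeries(vals, firstStep(series) + 1L, "delta_max")
}

#' Cross-correlation motion metric
#'
#' One minus the Pearson correlation, across channels, between the
#' navigator magnitude vectors of consecutive TRs:
#' 1 - cor(|s(i)|, |s(i-1)|). A drop in the correlation means the load
#' distribution over the coil elements has changed, indicating motion.
#' Values lie in [0, 2]; 0 means identical load distribution, 2 perfect
#' anti-correlation.
#'
#' @inheritParams deltaRef
#' @return a [MotionMetricSeries-class]
#' @export
cccMetric <- function(series) {
  stopifnot(is(series, "FidnavSeries"))
  s <- Mod(fidSignal(series))
  if (nrow(s) < 2L)
    stop("cross-correlation metric requires at least 2 channels")
  if (ncol(s) < 2L) stop("need at least 2 TRs")
  n <- ncol(s)
  vals <- vapply(seq.int(2L, n), function(i) {
    a <- s[, i]; b <- s[, i - 1L]
    if (sd(a) == 0 || sd(b) == 0) {
      warning(sprintf(
        "zero channel-wise variance at TR %d; correlation undefined, using 0",
        i))
      return(0)
    }
    val <- 1 - cor(a, b)
    # clamp float round-off outside [0, 2]
    min(max(val, 0), 2)
  }, numeric(1))
  MotionMetricSeries(vals, firstStep(series) + 1L, "ccc")
}

#' Compute all four motion metrics of a navigator series
#'
#' @inheritParams deltaRef
#' @inheritParams deltaMax
#' @param n_ref TRs averaged for the fixed reference of [deltaRef()]
#' @return named list of [MotionMetricSeries-class]:
#'   `delta_ref`, `delta`, `delta_max`, `ccc`
#' @export
fidnavMetrics <- function(series, n_ref = 3L, top_k = 3L,
                          floor_rel = 1e-12) {
  list(
    delta_ref = deltaRef(series, referenceSignal(series, n_ref),
                         floor_rel = floor_rel),
    delta = deltaPrev(series, floor_rel = floor_rel),
    delta_max = deltaMax(series, top_k = top_k, floor_rel = floor_rel),
    ccc = cccMetric(series)
  )
}

#' Write per-TR metric traces to CSV
#'
#' One row per TR (acquisition step), columns `tr_index` then one per
#' metric; steps where a metric is undefined are left blank.
#'
#' @param metrics named list of [MotionMetricSeries-class]
#' @param path output CSV path
#' @param n_steps total acquisition steps (rows); default spans the traces
#' @export
writeMetricsCsv <- function(metrics, path, n_steps = NULL) {
  stopifnot(length(metrics) >= 1L)
  last <- max(vapply(metrics, function(m)
    startStep(m) + length(metricValues(m)) - 1L, integer(1)))
  if (is.null(n_steps)) n_steps <- last
  df <- data.frame(tr_index = seq_len(n_steps))
  for (nm in names(metrics)) {
    m <- metrics[[nm]]
    col <- rep(NA_real_, n_steps)
    idx <- seq.int(startStep(m), length.out = length(metricValues(m)))
    col[idx] <- metricValues(m)
    df[[nm]] <- col
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}
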