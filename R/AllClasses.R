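#' @import methods
#' @importFrom stats cor cor.test quantile rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' FidnavSeries: per-TR, per-channel complex navigator signal
#'
#' Container for the assembled FID navigator signal of one scan: one complex
#' value per receive channel per repetition time (TR). Rows are channels,
#' columns are TRs. `nSteps` is the total number of outer phase-encoding
#' steps of the acquisition (one per TR before any trimming) and `firstStep`
#' records which acquisition step the first retained column corresponds to,
#' so that trimmed series stay aligned with k-space partition weights.
#'
#' @slot signal complex matrix, channels x TRs
#' @slot trSeconds repetition time in seconds
#' @slot nSteps total outer phase-encoding steps in the acquisition
#' @slot firstStep acquisition step index of the first retained column
#' @slot channelLabels character vector, one label per channel
#' @slot subjectId subject/scan identifier
#' @exportClass FidnavSeries
setClass("FidnavSeries",
  representation(
    signal = "matrix",
    trSeconds = "numeric",
    nSteps = "integer",
    firstStep = "integer",
    channelLabels = "character",
    subjectId = "character"
  )
)

setValidity("FidnavSeries", function(object) {
  sig <- object@signal
  msgs <- character()
  if (!is.complex(sig)) msgs <- c(msgs, "signal must be a complex matrix")
  if (nrow(sig) < 1L) msgs <- c(msgs, "at least one channel is required")
  if (any(!is.finite(Re(sig))) || any(!is.finite(Im(sig))))
    msgs <- c(msgs, "signal contains non-finite values")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msgs <- c(msgs, "trSeconds must be a single positive number")
  if (object@nSteps < 1L) msgs <- c(msgs, "nSteps must be positive")
  if (object@firstStep < 1L) msgs <- c(msgs, "firstStep must be >= 1")
  if (ncol(sig) != object@nSteps - object@firstStep + 1L)
    msgs <- c(msgs, sprintf(
      "ncol(signal) = %d does not equal nSteps - firstStep + 1 = %d",
      ncol(sig), object@nSteps - object@firstStep + 1L))
  if (length(object@channelLabels) != nrow(sig))
    msgs <- c(msgs, "channelLabels length must equal the number of channels")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FidnavSeries
#'
#' @param signal complex (or numeric, promoted to complex) matrix,
#'   channels x TRs
#' @param tr_seconds repetition time in seconds
#' @param n_steps total outer phase-encoding steps; defaults to
#'   `ncol(signal)` for an untrimmed series
#' @param first_step acquisition step of the first column (1 at assembly)
#' @param channel_labels optional channel labels
#' @param subject_id optional subject identifier
#' @return a [FidnavSeries-class] object
#' @examples
#' s <- FidnavSeries(matrix(complex(real = 1:6, imaginary = 0), 2, 3),
#'                   tr_seconds = 1.54)
#' nChannels(s); nTR(s)
#' @export
FidnavSeries <- function(signal, tr_seconds, n_steps = ncol(signal),
                         first_step = 1L,
                         channel_labels = paste0("ch", seq_len(nrow(signal))),
                         subject_id = NA_character_) {
  signal <- as.matrix(signal)
  if (!is.complex(signal)) storage.mode(signal) <- "complex"
  new("FidnavSeries", signal = signal, trSeconds = as.numeric(tr_seconds),
      nSteps = as.integer(n_steps), firstStep = as.integer(first_step),
      channelLabels = as.character(channel_labels),
      subjectId = as.character(subject_id))
}

#' MotionMetricSeries: per-TR motion metric trace
#'
#' Real-valued trace of one coil-combination motion metric. The trace is
#' stored without padding; `startStep` gives the acquisition step of the
#' first defined value (step 2 for all four published metrics, which compare
#' TR i against TR i-1 or a reference).
#'
#' @slot values numeric per-TR metric values
#' @slot startStep acquisition step index of values[1]
#' @slot metricName one of "delta_ref", "delta", "delta_max", "ccc"
#' @exportClass MotionMetricSeries
setClass("MotionMetricSeries",
  representation(values = "numeric", startStep = "integer",
                 metricName = "character"))

.metric_names <- c("delta_ref", "delta", "delta_max", "ccc")

setValidity("MotionMetricSeries", function(object) {
  msgs <- character()
  if (any(!is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (!object@metricName %in% .metric_names)
    msgs <- c(msgs, sprintf("metricName must be one of: %s",
                            paste(.metric_names, collapse = ", ")))
  if (object@metricName %in% c("delta_ref", "delta", "delta_max") &&
      any(object@values < 0))
    msgs <- c(msgs, "difference metrics must be non-negative")
  if (object@metricName == "ccc" &&
      any(object@values < -1e-12 | object@values > 2 + 1e-12))
    msgs <- c(msgs, "ccc values must lie in [0, 2]")
  if (object@startStep < 1L) msgs <- c(msgs, "startStep must be >= 1")
  if (length(msgs)) msgs else TRUE
})

MotionMetricSeries <- function(values, start_step, metric_name) {
  new("MotionMetricSeries", values = as.numeric(values),
      startStep = as.integer(start_step), metricName = metric_name)
}

#' KspaceWeighting: per-phase-encode-step weights
#'
#' Non-negative weight per outer phase-encoding step, normalized to unit
#' mean so that weighted and unweighted integrated scores are directly
#' comparable. Steps are in acquisition order (the k-space centre is
#' acquired halfway through the scan).
#'
#' @slot w numeric weights, length = number of steps
#' @slot source short description of how the weights were derived
#' @exportClass KspaceWeighting
setClass("KspaceWeighting",
  representation(w = "numeric", source = "character"))

setValidity("KspaceWeighting", function(object) {
  msgs <- character()
  if (any(!is.finite(object@w)) || any(object@w < 0))
    msgs <- c(msgs, "weights must be finite and non-negative")
  if (length(object@w) < 1L) msgs <- c(msgs, "at least one weight required")
  if (abs(mean(object@w) - 1) > 1e-8)
    msgs <- c(msgs, "weights must be normalized to unit mean")
  if (length(msgs)) msgs else TRUE
})

KspaceWeighting <- function(w, source = "unspecified") {
  new("KspaceWeighting", w = as.numeric(w), source = source)
}

#' IntegratedScore: per-scan integrated motion score
#'
#' The time-integral of a per-TR motion metric, in 1/s. `reportScale` is a
#' display multiplier only (100 for the cross-correlation metric, whose raw
#' values are small); `value` is always on the raw scale.
#'
#' @slot value integrated score in 1/s
#' @slot metricName metric identifier
#' @slot weighted whether k-space partition weighting was applied
#' @slot reportScale display multiplier (1 or 100)
#' @exportClass IntegratedScore
setClass("IntegratedScore",
  representation(value = "numeric", metricName = "character",
                 weighted = "logical", reportScale = "numeric"))

setValidity("IntegratedScore", function(object) {
  if (!is.finite(object@value)) return("value must be finite")
  TRUE
})

#' RocResult: empirical ROC analysis
#'
#' @slot thresholds candidate thresholds (sorted unique scores plus an
#'   +Inf sentinel at which nothing is called positive)
#' @slot se sensitivity at each threshold
#' @slot sp specificity at each threshold
#' @slot auc trapezoidal area under the ROC curve
#' @slot youdenJ maximal Youden's index J = SE + SP - 1
#' @slot optimalThreshold threshold attaining youdenJ (ties broken low)
#' @exportClass RocResult
setClass("RocResult",
  representation(thresholds = "numeric", se = "numeric", sp = "numeric",
                 auc = "numeric", youdenJ = "numeric",
                 optimalThreshold = "numeric"))

setValidity("RocResult", function(object) {
  msgs <- character()
  n <- length(object@thresholds)
  if (length(object@se) != n || length(object@sp) != n)
    msgs <- c(msgs, "thresholds, se and sp must have equal length")
  if (any(object@se < -1e-12 | object@se > 1 + 1e-12) ||
      any(object@sp < -1e-12 | object@sp > 1 + 1e-12))
    msgs <- c(msgs, "se and sp must lie in [0, 1]")
  if (is.unsorted(object@thresholds))
    msgs <- c(msgs, "thresholds must be sorted increasing")
  if (any(diff(object@se) > 1e-12))
    msgs <- c(msgs, "se must be non-increasing in the threshold")
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    msgs <- c(msgs, "auc must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' BootstrapResult: 0.632 bootstrap of threshold detection accuracy
#'
#' @slot b number of bootstrap replicates
#' @slot seed RNG seed used
#' @slot aucMean,aucSd mean and SD of the replicate AUCs
#' @slot jMean,jSd mean and SD of the replicate Youden indices
#' @slot threshold full-sample Youden-optimal threshold
#' @slot se632,sp632 0.632-blended sensitivity and specificity
#' @slot redraws replicates redrawn because an out-of-bag class was empty
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(b = "integer", seed = "integer",
                 aucMean = "numeric", aucSd = "numeric",
                 jMean = "numeric", jSd = "numeric",
                 threshold = "numeric", se632 = "numeric", sp632 = "numeric",
                 redraws = "integer"))

setValidity("BootstrapResult", function(object) {
  msgs <- character()
  if (object@b < 1L) msgs <- c(msgs, "b must be >= 1")
  if (object@se632 < 0 || object@se632 > 1 ||
      object@sp632 < 0 || object@sp632 > 1)
    msgs <- c(msgs, "se632 and sp632 must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' CostModel: scanner-time economics of a repeat scan
#'
#' Defaults reflect a standard unenhanced brain MRI billed at $2828 for a
#' 45-minute slot, with a 4.2-minute structural acquisition.
#'
#' @slot slotCost cost of one scanner slot (currency units)
#' @slot slotMinutes slot duration in minutes
#' @slot taMinutes acquisition time of the monitored scan in minutes
#' @exportClass CostModel
setClass("CostModel",
  representation(slotCost = "numeric", slotMinutes = "numeric",
                 taMinutes = "numeric"))

setValidity("CostModel", function(object) {
  if (object@slotCost <= 0 || object@slotMinutes <= 0 ||
      object@taMinutes < 0)
    return("slotCost and slotMinutes must be positive, taMinutes >= 0")
  TRUE
})

#' @rdname CostModel-class
#' @param slot_cost cost of one scanner slot
#' @param slot_minutes slot duration in minutes
#' @param ta_minutes acquisition time in minutes
#' @export
costModel <- function(slot_cost = 2828, slot_minutes = 45,
                      ta_minutes = 4.2) {
  new("CostModel", slotCost = slot_cost, slotMinutes = slot_minutes,
      taMinutes = ta_minutes)
}

#' SavingsReport: cohort-level scan-abort analysis
#'
#' @slot tSavingsPct aggregate time savings as % of baseline scan time
#' @slot nTP,nFP,nTN,nFN confusion counts of the abort decisions
#' @slot minutesSaved minutes saved aborting true positives
#' @slot minutesWasted minutes wasted re-starting false positives
#' @slot repeatCost cost of repeating all non-diagnostic scans (baseline)
#' @slot repeatMinutes scan time of those repeats in minutes
#' @slot netCostSaving (minutesSaved - minutesWasted) x cost per minute
#' @slot costPerMinute slot cost / slot minutes
#' @exportClass SavingsReport
setClass("SavingsReport",
  representation(tSavingsPct = "numeric",
                 nTP = "integer", nFP = "integer",
                 nTN = "integer", nFN = "integer",
                 minutesSaved = "numeric", minutesWasted = "numeric",
                 repeatCost = "numeric", repeatMinutes = "numeric",
                 netCostSaving = "numeric", costPerMinute = "numeric"))

setValidity("SavingsReport", function(object) {
  msgs <- character()
  if (is.finite(object@tSavingsPct) && object@tSavingsPct > 100)
    msgs <- c(msgs, "time savings cannot exceed 100%")
  if (any(c(object@nTP, object@nFP, object@nTN, object@nFN) < 0L))
    msgs <- c(msgs, "confusion counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})
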