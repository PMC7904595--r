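#' @name accessors
#' @title Accessors for fidnavQC classes
#' @param object an object of the documented class
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("fidSignal", function(object) standardGeneric("fidSignal"))
#' @rdname accessors
#' @export
setMethod("fidSignal", "FidnavSeries", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "FidnavSeries", function(object) nrow(object@signal))

#' @rdname accessors
#' @export
setGeneric("nTR", function(object) standardGeneric("nTR"))
#' @rdname accessors
#' @export
setMethod("nTR", "FidnavSeries", function(object) ncol(object@signal))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setMethod("trSeconds", "FidnavSeries", function(object) object@trSeconds)

#' @rdname accessors
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))
#' @rdname accessors
#' @export
setMethod("nSteps", "FidnavSeries", function(object) object@nSteps)

#' @rdname accessors
#' @export
setGeneric("firstStep", function(object) standardGeneric("firstStep"))
#' @rdname accessors
#' @export
setMethod("firstStep", "FidnavSeries", function(object) object@firstStep)

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "FidnavSeries",
          function(object) object@channelLabels)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "FidnavSeries", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setMethod("metricValues", "MotionMetricSeries",
          function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("startStep", function(object) standardGeneric("startStep"))
#' @rdname accessors
#' @export
setMethod("startStep", "MotionMetricSeries", function(object) object@startStep)

#' @rdname accessors
#' @export
setGeneric("metricName", function(object) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setMethod("metricName", "MotionMetricSeries",
          function(object) object@metricName)
#' @rdname accessors
#' @export
setMethod("metricName", "IntegratedScore", function(object) object@metricName)

#' @rdname accessors
#' @export
setGeneric("scoreValue", function(object) standardGeneric("scoreValue"))
#' @rdname accessors
#' @export
setMethod("scoreValue", "IntegratedScore", function(object) object@value)

#' Display value of an integrated score (raw value x report scale)
#' @rdname accessors
#' @export
setGeneric("displayValue", function(object) standardGeneric("displayValue"))
#' @rdname accessors
#' @export
setMethod("displayValue", "IntegratedScore",
          function(object) object@value * object@reportScale)

#' @rdname accessors
#' @export
setGeneric("stepWeights", function(object) standardGeneric("stepWeights"))
#' @rdname accessors
#' @export
setMethod("stepWeights", "KspaceWeighting", function(object) object@w)

#' @rdname accessors
#' @export
setGeneric("rocThresholds", function(object) standardGeneric("rocThresholds"))
#' @rdname accessors
#' @export
setMethod("rocThresholds", "RocResult", function(object) object@thresholds)

#' @rdname accessors
#' @export
setGeneric("rocAuc", function(object) standardGeneric("rocAuc"))
#' @rdname accessors
#' @export
setMethod("rocAuc", "RocResult", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("youdenJ", function(object) standardGeneric("youdenJ"))
#' @rdname accessors
#' @export
setMethod("youdenJ", "RocResult", function(object) object@youdenJ)

#' @rdname accessors
#' @export
setGeneric("optimalThreshold", function(object)
  standardGeneric("optimalThreshold"))
#' @rdname accessors
#' @export
setMethod("optimalThreshold", "RocResult",
          function(object) object@optimalThreshold)

setMethod("show", "FidnavSeries", function(object) {
  cat("FidnavSeries:", nChannels(object), "channels x", nTR(object),
      "TRs (TR =", object@trSeconds, "s)\n")
  cat("  acquisition steps", object@firstStep, "-", object@nSteps,
      "of", object@nSteps, "\n")
  if (!is.na(object@subjectId)) cat("  subject:", object@subjectId, "\n")
})

setMethod("show", "MotionMetricSeries", function(object) {
  cat("MotionMetricSeries <", object@metricName, ">: ",
      length(object@values), " values from step ", object@startStep,
      "\n", sep = "")
})

setMethod("show", "IntegratedScore", function(object) {
  lab <- if (object@weighted) "weighted integrated" else "integrated"
  cat(sprintf("%s %s score: %.6g 1/s", lab, object@metricName,
              object@value))
  if (object@reportScale != 1)
    cat(sprintf(" (reported as %.4g, x%g)", displayValue(object),
                object@reportScale))
  cat("\n")
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "RocResult: AUC = %.3f, J = %.3f at threshold %.4g (%d thresholds)\n",
    object@auc, object@youdenJ, object@optimalThreshold,
    length(object@thresholds)))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult (b = %d):\n", object@b))
  cat(sprintf("  AUC %.3f +/- %.3f, J %.3f +/- %.3f\n",
              object@aucMean, object@aucSd, object@jMean, object@jSd))
  cat(sprintf("  0.632 estimator: SE %.3f, SP %.3f at threshold %.4g\n",
              object@se632, object@sp632, object@threshold))
})

setMethod("show", "SavingsReport", function(object) {
  cat(sprintf("SavingsReport: time savings %.2f%%\n", object@tSavingsPct))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              object@nTP, object@nFP, object@nTN, object@nFN))
  cat(sprintf("  saved %.1f min, wasted %.1f min, net %.0f at %.2f/min\n",
              object@minutesSaved, object@minutesWasted,
              object@netCostSaving, object@costPerMinute))
})
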