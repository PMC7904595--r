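# Assembly of raw per-excitation navigator readouts into the per-TR,
# per-channel complex FIDnav signal used by all downstream metrics.

#' Average the ADC samples of one navigator readout
#'
#' Each navigator readout consists of `S` complex samples per channel
#' acquired in 0.2 ms. The leading and trailing samples are affected by
#' ADC electronic adjustments, so only a central window (by default the
#' middle `S/2` samples, i.e. samples 17-48 of 64) is averaged.
#'
#' @param readout complex matrix, channels x samples, for one excitation
#' @param window inclusive 1-based sample range `c(lo, hi)`; `NULL` selects
#'   the central half `S/4 + 1 ... 3S/4`
#' @return complex vector, one averaged value per channel
#' @examples
#' ro <- matrix(complex(real = rep(1:64, each = 2)), nrow = 2)
#' averageAdcSamples(ro)   # mean of samples 17..48 per channel
#' @export
averageAdcSamples <- function(readout, window = NULL) {
  readout <- as.matrix(readout)
  if (!is.complex(readout)) storage.mode(readout) <- "complex"
  S <- ncol(readout)
  if (S < 2L) stop("readout must contain at least 2 samples")
  if (any(!is.finite(Re(readout))) || any(!is.finite(Im(readout))))
    stop("readout contains non-finite samples")
  if (is.null(window)) window <- c(floor(S / 4) + 1L, floor(3 * S / 4))
  if (length(window) != 2L || window[1] > window[2] ||
      window[1] < 1L || window[2] > S)
    stop(sprintf("invalid sample window [%s] for %d samples",
                 paste(window, collapse = ", "), S))
  idx <- seq.int(window[1], window[2])
  rowMeans(readout[, idx, drop = FALSE])
}

#' Collapse the per-excitation navigator means of one echo train
#'
#' Within each TR the sequence plays an echo train of excitations, each
#' yielding one averaged navigator value per channel. These are averaged
#' again to a single complex navigator signal per channel per TR.
#'
#' @param readout_means complex matrix, channels x excitations (or a list of
#'   per-excitation channel vectors)
#' @return complex vector, one value per channel
#' @export
collapseEchoTrain <- function(readout_means) {
  if (length(readout_means) == 0L)
    stop("echo train contains no excitations")
  if (is.list(readout_means))
    readout_means <- do.call(cbind, readout_means)
  readout_means <- as.matrix(readout_means)
  if (!is.complex(readout_means)) storage.mode(readout_means) <- "complex"
  rowMeans(readout_means)
}

#' Assemble a FidnavSeries from raw readouts
#'
#' Applies [averageAdcSamples()] to every excitation and
#' [collapseEchoTrain()] within every TR.
#'
#' @param readouts list over TRs; each element a list (over excitations) of
#'   channels x samples complex matrices
#' @param tr_seconds repetition time in seconds
#' @param window ADC sample window passed to [averageAdcSamples()]
#' @param ... further arguments passed to [FidnavSeries()]
#' @return a [FidnavSeries-class] with one column per TR
#' @export
assembleFidnav <- function(readouts, tr_seconds, window = NULL, ...) {
  if (length(readouts) < 1L) stop("no TRs supplied")
  cols <- lapply(readouts, function(train) {
    means <- lapply(train, averageAdcSamples, window = window)
    collapseEchoTrain(do.call(cbind, means))
  })
  FidnavSeries(do.call(cbind, cols), tr_seconds = tr_seconds, ...)
}

#' Discard pre-steady-state TRs
#'
#' The first few navigator time points are acquired before the longitudinal
#' magnetization reaches steady state and are discarded (default 3).
#' Acquisition-step alignment is preserved via `firstStep`.
#'
#' @param series a [FidnavSeries-class]
#' @param n_discard number of leading TRs to drop
#' @return the trimmed [FidnavSeries-class]
#' @export
trimPresteady <- function(series, n_discard = 3L) {
  stopifnot(is(series, "FidnavSeries"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("n_discard must be >= 0")
  if (n_discard == 0L) return(series)
  if (nTR(series) <= n_discard)
    stop(sprintf("series has %d TRs; cannot discard %d",
                 nTR(series), n_discard))
  FidnavSeries(fidSignal(series)[, -seq_len(n_discard), drop = FALSE],
               tr_seconds = trSeconds(series), n_steps = nSteps(series),
               first_step = firstStep(series) + n_discard,
               channel_labels = channelLabels(series),
               subject_id = subjectId(series))
}

#' Per-channel reference navigator signal
#'
#' Complex mean of the first `n_ref` retained TRs, used as the fixed
#' reference by the reference-change metric. Apply after
#' [trimPresteady()] so the reference is not contaminated by the
#' pre-steady-state transient.
#'
#' @param series a [FidnavSeries-class]
#' @param n_ref number of leading TRs to average (default 3)
#' @return complex vector, one reference value per channel
#' @export
referenceSignal <- function(series, n_ref = 3L) {
  stopifnot(is(series, "FidnavSeries"))
  n_ref <- as.integer(n_ref)
  if (n_ref < 1L) stop("n_ref must be >= 1")
  if (n_ref > nTR(series))
    stop(sprintf("n_ref = %d exceeds the %d available TRs",
                 n_ref, nTR(series)))
  rowMeans(fidSignal(series)[, seq_len(n_ref), drop = FALSE])
}
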