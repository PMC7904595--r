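# File formats. The navigator-series interchange format is a CSV with one
# row per TR (tr_index, then ch{j}_re / ch{j}_im per channel) plus a JSON
# sidecar carrying acquisition metadata; values round-trip at full double
# precision. A delimited-text raw-readout backend (one record per TR x
# excitation) feeds the assembly stage.

.sidecar_path <- function(path) paste0(path, ".json")

.fmt_full <- function(x) sprintf("%.17g", x)

#' Write a navigator series to CSV (+ JSON sidecar)
#'
#' Columns: `tr_index`, then `ch{j}_re`, `ch{j}_im` per channel, written at
#' full double precision so a read-back is bit-exact. The sidecar records
#' `tr_seconds`, `n_steps`, `first_step`, `subject_id`, `channel_labels`
#' and a provenance hash.
#'
#' @param series a [FidnavSeries-class]
#' @param path output CSV path; the sidecar is written at `<path>.json`
#' @return `path`, invisibly
#' @export
writeNavigatorCsv <- function(series, path) {
  stopifnot(is(series, "FidnavSeries"))
  s <- fidSignal(series)
  df <- data.frame(tr_index = seq.int(firstStep(series),
                                      length.out = ncol(s)))
  for (j in seq_len(nrow(s))) {
    df[[paste0("ch", j, "_re")]] <- .fmt_full(Re(s[j, ]))
    df[[paste0("ch", j, "_im")]] <- .fmt_full(Im(s[j, ]))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(tr_seconds = trSeconds(series), n_steps = nSteps(series),
               first_step = firstStep(series),
               subject_id = subjectId(series),
               channel_labels = channelLabels(series))
  meta$config_hash <- configHash(meta)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a navigator series from CSV
#'
#' Validates the header (a `tr_index` column and paired `ch{j}_re` /
#' `ch{j}_im` columns), rejects ragged or non-finite rows, and restores
#' acquisition metadata from the JSON sidecar (or from the explicit
#' arguments, which take precedence).
#'
#' @param path CSV path written by [writeNavigatorCsv()]
#' @param tr_seconds,n_steps,first_step,subject_id optional metadata
#'   overrides; required if no sidecar exists
#' @return a [FidnavSeries-class]
#' @export
readNavigatorCsv <- function(path, tr_seconds = NULL, n_steps = NULL,
                             first_step = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("malformed navigator CSV ", path, ": ",
                        conditionMessage(e)))
  if (nrow(df) == 0L) stop("navigator CSV is empty: ", path)
  if (!"tr_index" %in% names(df))
    stop("navigator CSV is missing the tr_index column")
  re_cols <- grep("^ch[0-9]+_re$", names(df), value = TRUE)
  nc <- length(re_cols)
  if (nc == 0L) stop("navigator CSV has no channel columns")
  for (j in seq_len(nc)) {
    for (part in c("_re", "_im")) {
      col <- paste0("ch", j, part)
      if (!col %in% names(df))
        stop("navigator CSV is missing column ", col)
      bad <- which(!is.finite(df[[col]]))
      if (length(bad))
        stop(sprintf("non-finite value in column %s at data line %d",
                     col, bad[1]))
    }
  }
  meta <- list()
  if (file.exists(.sidecar_path(path)))
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  tr_seconds <- tr_seconds %||% meta$tr_seconds
  if (is.null(tr_seconds))
    stop("tr_seconds not given and no sidecar found for ", path)
  first_step <- first_step %||% meta$first_step %||% df$tr_index[1]
  n_steps <- n_steps %||% meta$n_steps %||%
    (nrow(df) + first_step - 1L)
  subject_id <- subject_id %||% meta$subject_id %||% NA_character_
  sig <- t(as.matrix(vapply(seq_len(nc), function(j)
    complex(real = df[[paste0("ch", j, "_re")]],
            imaginary = df[[paste0("ch", j, "_im")]]),
    complex(nrow(df)))))
  labels <- meta$channel_labels %||% paste0("ch", seq_len(nc))
  FidnavSeries(sig, tr_seconds = tr_seconds, n_steps = n_steps,
               first_step = first_step, channel_labels = labels,
               subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write raw per-excitation readouts as delimited text
#'
#' One record (row) per TR x excitation: `tr_index`, `excitation`, then
#' interleaved `ch{j}_s{k}_re` / `ch{j}_s{k}_im` columns. A JSON sidecar
#' carries `n_channels`, `n_samples`, `echo_train_length`, `tr_seconds`.
#'
#' @param readouts list over TRs of lists (over excitations) of channels x
#'   samples complex matrices
#' @param path output CSV path
#' @param tr_seconds repetition time in seconds
#' @return `path`, invisibly
#' @export
writeRawReadoutCsv <- function(readouts, path, tr_seconds) {
  stopifnot(length(readouts) >= 1L)
  first <- readouts[[1]][[1]]
  nc <- nrow(first); S <- ncol(first)
  header <- c("tr_index", "excitation",
              unlist(lapply(seq_len(nc), function(j)
                paste0("ch", j, "_s", rep(seq_len(S), each = 2),
                       c("_re", "_im")))))
  mat <- do.call(rbind, lapply(seq_along(readouts), function(i) {
    do.call(rbind, lapply(seq_along(readouts[[i]]), function(k) {
      m <- readouts[[i]][[k]]
      if (!all(dim(m) == c(nc, S)))
        stop("ragged readout at TR ", i, ", excitation ", k)
      # per channel j, per sample: re, im
      v <- unlist(lapply(seq_len(nc), function(j)
        as.vector(rbind(Re(m[j, ]), Im(m[j, ])))))
      c(i, k, v)
    }))
  }))
  df <- as.data.frame(mat)
  names(df) <- header
  for (col in setdiff(header, c("tr_index", "excitation")))
    df[[col]] <- .fmt_full(df[[col]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(n_channels = nc, n_samples = S,
               echo_train_length = length(readouts[[1]]),
               tr_seconds = tr_seconds)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read raw readouts written by [writeRawReadoutCsv()]
#'
#' @param path CSV path
#' @return list with `readouts` (list over TRs of lists of channels x
#'   samples complex matrices) and `tr_seconds`
#' @export
readRawReadoutCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  nc <- meta$n_channels; S <- meta$n_samples
  readouts <- lapply(sort(unique(df$tr_index)), function(i) {
    sub <- df[df$tr_index == i, , drop = FALSE]
    lapply(sort(unique(sub$excitation)), function(k) {
      r <- sub[sub$excitation == k, , drop = FALSE]
      m <- matrix(0i, nc, S)
      for (j in seq_len(nc))
        m[j, ] <- complex(
          real = as.numeric(r[paste0("ch", j, "_s", seq_len(S), "_re")]),
          imaginary = as.numeric(r[paste0("ch", j, "_s", seq_len(S),
                                          "_im")]))
      m
    })
  })
  list(readouts = readouts, tr_seconds = meta$tr_seconds)
}

#' Pipeline configuration
#'
#' Bundles and validates the acquisition, preprocessing, detection and
#' cost-model parameters used across the pipeline.
#'
#' @param tr_seconds repetition time (s)
#' @param n_steps outer phase-encoding steps per scan
#' @param n_channels receive channels
#' @param ta_minutes scan duration in minutes
#' @param n_discard pre-steady-state TRs discarded
#' @param n_ref TRs averaged into the fixed reference
#' @param window ADC sample window (`NULL` = central half)
#' @param dichotomization `"12v345"` or `"123v45"`
#' @param b bootstrap replicates
#' @param seed RNG seed
#' @param cost a [CostModel-class]
#' @return validated named list with class `"fidnavConfig"`
#' @export
pipelineConfig <- function(tr_seconds = 1.54, n_steps = 160L,
                           n_channels = 32L, ta_minutes = 4.2,
                           n_discard = 3L, n_ref = 3L, window = NULL,
                           dichotomization = "12v345", b = 1000L,
                           seed = 1L, cost = costModel()) {
  stopifnot(tr_seconds > 0, n_steps >= 1, n_channels >= 1,
            ta_minutes > 0, n_discard >= 0, n_ref >= 1, b >= 1)
  if (!dichotomization %in% c("12v345", "123v45"))
    stop('dichotomization must be "12v345" or "123v45"')
  structure(list(tr_seconds = tr_seconds, n_steps = as.integer(n_steps),
                 n_channels = as.integer(n_channels),
                 ta_minutes = ta_minutes, n_discard = as.integer(n_discard),
                 n_ref = as.integer(n_ref), window = window,
                 dichotomization = dichotomization, b = as.integer(b),
                 seed = as.integer(seed), cost = cost),
            class = "fidnavConfig")
}

#' Provenance hash of a configuration
#'
#' 32-bit polynomial rolling hash over the serialized object, reported as 8 hex
#' digits; stamped into output files so results can be traced to the
#' configuration that produced them.
#'
#' @param x any R object
#' @return character scalar, e.g. `"a1b2c3d4"`
#' @export
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the serialization header (holds the writing R version)
  bytes <- bytes[-seq_len(14)]
  h <- 0
  for (byte in bytes) h <- (h * 31 + byte) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
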