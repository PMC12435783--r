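# Plain-text containers: EEG as a CSV matrix plus JSON sidecar, TRFs and
# accuracy tables as TSV with a JSON metadata header file.

#' Write an EEG trial set as CSV + JSON sidecar
#'
#' All trials are stacked sample-wise into one samples x channels CSV; the
#' sidecar records `fs`, `channel_labels`, and the per-trial row boundaries.
#'
#' @param eeg An `eeg_trials` object.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths.
#' @export
write_eeg_container <- function(eeg, prefix) {
  stopifnot(inherits(eeg, "eeg_trials"))
  mats <- lapply(eeg$trials, t) # samples x channels
  ns <- vapply(mats, nrow, integer(1))
  big <- do.call(rbind, mats)
  colnames(big) <- eeg$channel_labels
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.csv(big, csv, row.names = FALSE)
  meta <- list(fs = eeg$fs, channel_labels = eeg$channel_labels,
               n_trials = length(eeg$trials),
               trial_start_row = cumsum(c(1, ns[-length(ns)])),
               trial_n_samples = ns,
               normalized = isTRUE(eeg$normalized))
  if (!is.null(eeg$layout)) meta$layout <- eeg$layout
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Read an EEG trial set written by [write_eeg_container()]
#'
#' @param prefix Path prefix used at write time.
#' @return An `eeg_trials` object.
#' @export
read_eeg_container <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  big <- as.matrix(utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE))
  starts <- meta$trial_start_row
  ns <- meta$trial_n_samples
  trials <- lapply(seq_len(meta$n_trials), function(i) {
    t(big[seq(starts[i], length.out = ns[i]), , drop = FALSE])
  })
  layout <- if (!is.null(meta$layout)) as.data.frame(meta$layout) else NULL
  out <- eeg_trials(trials, meta$fs, meta$channel_labels, layout)
  out$normalized <- isTRUE(meta$normalized)
  out
}

#' Export a TRF model as TSV + JSON header
#'
#' One row per (feature, lag, channel) weight; the JSON header records the
#' lambda, lag grid and feature names.
#'
#' @param model A `trf_model`.
#' @param prefix Output path prefix.
#' @param fs Sampling rate used to express lags in ms.
#' @return Invisibly, the TSV path.
#' @export
write_trf_tsv <- function(model, prefix, fs) {
  d <- dim(model$weights)
  tab <- expand.grid(feature = model$feature_names,
                     lag = model$lags,
                     channel = model$channel_labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$lag_ms <- 1000 * tab$lag / fs
  tab$weight <- as.vector(model$weights)
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(lambda = model$lambda, fs = fs, lags = model$lags,
         feature_names = model$feature_names,
         channel_labels = model$channel_labels),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".tsv"))
}

#' Export an accuracy table as TSV
#'
#' @param accuracy Trial x channel matrix of correlations.
#' @param path Output TSV path.
#' @param meta Optional metadata list written as `<path minus .tsv>.json`.
#' @export
write_accuracy_tsv <- function(accuracy, path, meta = NULL) {
  tab <- data.frame(trial = rep(seq_len(nrow(accuracy)), ncol(accuracy)),
                    channel = rep(colnames(accuracy) %||%
                                    paste0("ch", seq_len(ncol(accuracy))),
                                  each = nrow(accuracy)),
                    r = as.vector(accuracy))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
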