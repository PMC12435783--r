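# Forward-model specifications and per-subject fitting: the bridge between
# the simulated (or imported) subject data and the TRF core.

#' Specify a forward model
#'
#' The analysis fits three onset-model structures — word, phoneme, and
#' word+phoneme — each with or without the speech envelope as an additional
#' regressor, separately for the attended and the ignored stream.
#'
#' @param onsets Character subset of `c("word", "phoneme")` (nonempty).
#' @param envelope Include the envelope regressor?
#' @return Object of class `model_spec` with an `id` like
#'   `"word+phoneme+env"`.
#' @export
model_spec <- function(onsets = c("word", "phoneme"), envelope = FALSE) {
  onsets <- match.arg(onsets, c("word", "phoneme"), several.ok = TRUE)
  id <- paste(onsets, collapse = "+")
  if (envelope) id <- paste0(id, "+env")
  structure(list(onsets = onsets, envelope = envelope, id = id),
            class = "model_spec")
}

model_feature_names <- function(spec) {
  c(paste0(spec$onsets, "_onset"), if (spec$envelope) "envelope")
}

#' Default model set
#'
#' Word, phoneme and word+phoneme structures, each with and without the
#' envelope.
#' @return Named list of `model_spec`s.
#' @export
default_model_set <- function() {
  specs <- list(
    model_spec("word", FALSE), model_spec("phoneme", FALSE),
    model_spec(c("word", "phoneme"), FALSE),
    model_spec("word", TRUE), model_spec("phoneme", TRUE),
    model_spec(c("word", "phoneme"), TRUE))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "id"))
}

# Regressors for one stream of one subject under a model spec, per trial.
# tiers_override supplies permuted tiers (list[stream][[trial]]$word/phoneme).
subject_stream_features <- function(subject, stream, spec,
                                    tiers_override = NULL) {
  cfg <- subject$config
  n <- round(cfg$trial_duration_s * cfg$fs)
  lapply(seq_along(subject$streams[[stream]]$trials), function(tr) {
    tt <- subject$streams[[stream]]$trials[[tr]]
    word <- tt$word
    phoneme <- tt$phoneme
    if (!is.null(tiers_override)) {
      word <- tiers_override[[stream]][[tr]]$word
      phoneme <- tiers_override[[stream]][[tr]]$phoneme
    }
    build_feature_set(word, phoneme, tt$envelope,
                      fs = cfg$fs, n_samples = n,
                      include = c(spec$onsets, if (spec$envelope) "envelope"),
                      stream_id = stream, trial_id = tr,
                      clip = !is.null(tiers_override))
  })
}

#' Fit one model for one subject and condition
#'
#' Builds the condition's regressors (attended or ignored stream), runs the
#' leave-one-trial-out cross-validation at the frozen lambda, and returns
#' the `crossval_trf` result.
#'
#' @param subject A subject object (see [simulate_subject()]).
#' @param condition `"attend"` or `"ignore"`.
#' @param spec A [model_spec()].
#' @param lambda Ridge parameter.
#' @param lspec A `lag_spec`.
#' @param eeg Preprocessed `eeg_trials`; defaults to preprocessing the
#'   subject's raw EEG.
#' @param tiers_override Optional permuted tiers (as produced inside
#'   [build_chance_distribution()]).
#' @return The [crossval_trf()] result list.
#' @export
fit_subject_model <- function(subject, condition = c("attend", "ignore"),
                              spec, lambda, lspec, eeg = NULL,
                              tiers_override = NULL) {
  condition <- match.arg(condition)
  stream <- if (condition == "attend") subject$attended else
    (3 - subject$attended)
  if (is.null(eeg)) eeg <- preprocess_eeg(subject$eeg)
  feats <- subject_stream_features(subject, stream, spec, tiers_override)
  crossval_trf(feats, eeg, lambda, lspec)
}

#' Tune the ridge parameter for a subject
#'
#' Follows the convention of tuning once per subject on a combined model
#' containing the word and phoneme onset regressors of both the attended
#' and the ignored stream, minimizing any attention bias; the selected
#' lambda is then reused in every later analysis step.
#'
#' @inheritParams fit_subject_model
#' @param grid Lambda grid (default 1e-6..1e6 in decades).
#' @return The [tune_lambda()] result list.
#' @export
tune_subject_lambda <- function(subject, lspec, grid = default_lambda_grid(),
                                eeg = NULL) {
  if (is.null(eeg)) eeg <- preprocess_eeg(subject$eeg)
  att <- subject$attended
  spec <- model_spec(c("word", "phoneme"), FALSE)
  fa <- subject_stream_features(subject, att, spec)
  fi <- subject_stream_features(subject, 3 - att, spec)
  feats <- lapply(seq_along(fa), function(tr) {
    combine_feature_sets(list(att = fa[[tr]], ign = fi[[tr]]))
  })
  tune_lambda(feats, eeg, lspec, grid)
}
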