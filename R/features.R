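# Stimulus feature sets: onset impulse trains and the speech envelope,
# sampled at the EEG rate.

#' Construct a stimulus feature set
#'
#' Named regressor channels sampled at the EEG rate. Feature names ending in
#' `_onset` are treated as impulse trains and contribute to the valid-sample
#' mask; other features (e.g. `envelope`) do not.
#'
#' @param features Named list of numeric vectors of equal length.
#' @param fs Sampling rate in Hz.
#' @param stream_id,trial_id Optional identifiers carried along for bookkeeping.
#' @return Object of class `stim_features`.
#' @export
stim_features <- function(features, fs, stream_id = NA, trial_id = NA) {
  stopifnot(is.list(features), length(features) >= 1,
            !is.null(names(features)), all(nzchar(names(features))))
  n <- unique(vapply(features, length, integer(1)))
  if (length(n) != 1) stop("all features must have the same length")
  for (nm in names(features)) {
    if (!all(is.finite(features[[nm]]))) stop("feature '", nm, "' is not finite")
  }
  structure(list(features = features, fs = fs, n_samples = n,
                 stream_id = stream_id, trial_id = trial_id),
            class = "stim_features")
}

#' @export
print.stim_features <- function(x, ...) {
  cat(sprintf("<stim_features> %d samples @ %g Hz; features: %s\n",
              x$n_samples, x$fs, paste(names(x$features), collapse = ", ")))
  invisible(x)
}

onset_feature_names <- function(x) {
  grep("_onset$", names(x$features), value = TRUE)
}

#' Build a binary onset impulse train from a tier
#'
#' Places a unit impulse at `round(onset * fs)` (0-based sample index,
#' round-half-up) for every event. Two events falling on the same sample
#' keep a value of 1: the regressor codes event presence, not event count.
#'
#' @param tier An `annotation_tier`.
#' @param fs Sampling rate in Hz.
#' @param n_samples Length of the output array.
#' @param clip If `TRUE`, onsets mapping beyond the trial end are silently
#'   dropped instead of raising an error (used for permuted tiers, where a
#'   long word assigned to the last onset slot can extend past the trial).
#' @return Numeric 0/1 vector of length `n_samples`.
#' @export
build_onset_regressor <- function(tier, fs, n_samples, clip = FALSE) {
  x <- numeric(n_samples)
  if (nrow(tier) == 0) return(x)
  idx <- onset_sample_index(tier$onset, fs)
  if (any(idx >= n_samples)) {
    if (clip) {
      idx <- idx[idx < n_samples]
      if (!length(idx)) return(x)
    } else {
      bad <- which(idx >= n_samples)[1]
      stop(sprintf("onset at %.4f s maps beyond the trial end (%d samples @ %g Hz)",
                   tier$onset[bad], n_samples, fs))
    }
  }
  x[idx + 1L] <- 1
  x
}

# round-half-up of onset * fs, 0-based; trial time starts at 0 s
onset_sample_index <- function(onset_s, fs) {
  as.integer(floor(onset_s * fs + 0.5))
}

#' Extract the broadband speech envelope
#'
#' Magnitude of the analytic signal, low-pass filtered at 8 Hz with a
#' zero-phase order-4 Butterworth filter at the audio rate, then resampled
#' to the EEG rate. Small negative excursions from filter ripple are
#' possible and left in place.
#'
#' @param audio Numeric waveform.
#' @param audio_fs Audio sampling rate in Hz (must exceed 16 Hz).
#' @param target_fs Output sampling rate in Hz.
#' @param lowpass_hz Envelope cutoff, default 8 Hz.
#' @return Envelope vector at `target_fs`.
#' @export
extract_envelope <- function(audio, audio_fs, target_fs, lowpass_hz = 8) {
  stopifnot(all(is.finite(audio)), audio_fs > 2 * lowpass_hz, target_fs > 0)
  if (all(audio == 0)) {
    return(numeric(floor(length(audio) * target_fs / audio_fs)))
  }
  env <- hilbert_magnitude(audio)
  ba <- butter_lowpass(4, lowpass_hz, audio_fs)
  env <- filtfilt(ba$b, ba$a, env)
  resample_signal(env, audio_fs, target_fs)
}

#' Assemble regressors for one trial of one stream
#'
#' @param word,phoneme `annotation_tier` objects for the trial.
#' @param envelope Optional envelope vector at `fs` (length `n_samples`).
#' @param fs Sampling rate in Hz.
#' @param n_samples Trial length in samples.
#' @param include Character vector choosing among `"word"`, `"phoneme"`,
#'   `"envelope"`.
#' @inheritParams stim_features
#' @return A `stim_features` object with the requested features.
#' @export
build_feature_set <- function(word, phoneme, envelope = NULL, fs, n_samples,
                              include = c("word", "phoneme", "envelope"),
                              stream_id = NA, trial_id = NA, clip = FALSE) {
  feats <- list()
  if ("word" %in% include) {
    feats$word_onset <- build_onset_regressor(word, fs, n_samples, clip = clip)
  }
  if ("phoneme" %in% include) {
    feats$phoneme_onset <- build_onset_regressor(phoneme, fs, n_samples, clip = clip)
  }
  if ("envelope" %in% include) {
    if (is.null(envelope)) stop("envelope requested but not supplied")
    stopifnot(length(envelope) == n_samples)
    feats$envelope <- envelope
  }
  stim_features(feats, fs, stream_id = stream_id, trial_id = trial_id)
}

#' Merge feature sets from several streams into one design's features
#'
#' Prefixes feature names with the stream tag so that, e.g., attended and
#' ignored regressors can enter a single model (used for ridge-parameter
#' tuning).
#'
#' @param sets Named list of `stim_features` (names become prefixes).
#' @return A single `stim_features` object.
#' @export
combine_feature_sets <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  fs <- unique(vapply(sets, function(s) s$fs, numeric(1)))
  n <- unique(vapply(sets, function(s) s$n_samples, numeric(1)))
  if (length(fs) != 1 || length(n) != 1) {
    stop("feature sets differ in fs or length")
  }
  feats <- list()
  for (tag in names(sets)) {
    f <- sets[[tag]]$features
    names(f) <- paste0(tag, ".", names(f))
    feats <- c(feats, f)
  }
  stim_features(feats, fs, trial_id = sets[[1]]$trial_id)
}
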