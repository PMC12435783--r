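# Synthetic competing-speaker world: two concurrent speech streams with
# word/phoneme annotation tiers, a smoothed-impulse speech envelope, and
# multichannel EEG formed by convolving each regressor with ground-truth
# kernels (attended kernels scaled up relative to ignored) plus 1/f noise.

#' Simulation configuration
#'
#' Defaults describe the desk-scale analogue of the recorded paradigm:
#' six trials per subject, two competing streams whose word-duration medians
#' are 290 ms and 270 ms, about four phonemes per word (median phoneme
#' durations near 70 ms and 60 ms), 16 channels in bilateral pairs, and
#' kernel-driven EEG at 0 dB SNR over 1/f noise.
#'
#' @param n_trials Trials per subject (default 6).
#' @param trial_duration_s Trial length in seconds (default 60).
#' @param fs Sampling rate in Hz (default 500; tests use lower rates to
#'   keep runtimes small).
#' @param n_channels Channel count, must be even (bilateral pairs).
#' @param word_median_s Per-stream median word duration in seconds.
#' @param word_sdlog Per-stream log-normal dispersion of word durations.
#' @param phonemes_per_word List of two named probability vectors over
#'   phoneme counts per word.
#' @param phoneme_alpha Dirichlet concentration for stick-breaking phoneme
#'   durations within a word (larger = more even).
#' @param gap_prob Probability of a silent gap before a word.
#' @param gap_max_s Maximum silent gap in seconds (0.5: longer gaps are
#'   reduced in the stimulus material this emulates).
#' @param snr_db Pooled variance ratio of kernel-driven signal to noise in
#'   dB; `Inf` disables noise.
#' @param noise_exponent Spectral slope beta of the 1/f^beta channel noise.
#' @param attend_gain,ignore_gain Multipliers on the attended / ignored
#'   stream's kernels.
#' @param seed Master seed; identical config + seed reproduces all outputs
#'   bit-identically.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 6, trial_duration_s = 60, fs = 500,
                       n_channels = 16,
                       word_median_s = c(0.29, 0.27),
                       word_sdlog = c(0.45, 0.45),
                       phonemes_per_word = default_phoneme_counts(),
                       phoneme_alpha = 5,
                       gap_prob = 0.3, gap_max_s = 0.5,
                       snr_db = 0, noise_exponent = 1,
                       attend_gain = 1, ignore_gain = 0.5,
                       seed = 1L) {
  stopifnot(n_trials >= 1, trial_duration_s > 0, fs > 0, n_channels >= 1,
            all(word_median_s > 0), all(word_sdlog > 0),
            gap_prob >= 0, gap_prob <= 1, gap_max_s >= 0,
            attend_gain >= 0, ignore_gain >= 0)
  if (length(word_median_s) == 1) word_median_s <- rep(word_median_s, 2)
  if (length(word_sdlog) == 1) word_sdlog <- rep(word_sdlog, 2)
  structure(list(n_trials = n_trials, trial_duration_s = trial_duration_s,
                 fs = fs, n_channels = n_channels,
                 word_median_s = word_median_s, word_sdlog = word_sdlog,
                 phonemes_per_word = phonemes_per_word,
                 phoneme_alpha = phoneme_alpha,
                 gap_prob = gap_prob, gap_max_s = gap_max_s,
                 snr_db = snr_db, noise_exponent = noise_exponent,
                 attend_gain = attend_gain, ignore_gain = ignore_gain,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default phoneme-count distributions per stream
#'
#' Stream 2's speaker articulates slightly faster (more, shorter phonemes
#' per word), matching the reported 70 ms vs 60 ms phoneme-duration medians.
#' @return List of two named probability vectors (names = counts).
#' @export
default_phoneme_counts <- function() {
  list(
    stats::setNames(c(0.18, 0.30, 0.27, 0.15, 0.07, 0.03), 2:7),
    stats::setNames(c(0.12, 0.27, 0.28, 0.19, 0.10, 0.04), 2:7)
  )
}

# Evaluate code with a derived RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

#' Generate word and phoneme tiers for one stream and trial
#'
#' Words tile the trial left to right: log-normal durations, optional
#' uniform silent gaps capped at `gap_max_s`, at least one phoneme per word.
#' Phoneme durations stick-break each word interval (Dirichlet weights), so
#' the first phoneme onset equals the word onset exactly and phonemes
#' partition the word.
#'
#' @param config A `sim_config`.
#' @param stream_id 1 or 2.
#' @param trial Trial index (used only for seed derivation).
#' @return List with `word` and `phoneme` annotation tiers.
#' @export
simulate_annotations <- function(config, stream_id, trial = 1) {
  stopifnot(inherits(config, "sim_config"), stream_id %in% c(1, 2))
  med <- config$word_median_s[stream_id]
  sdlog <- config$word_sdlog[stream_id]
  pn <- config$phonemes_per_word[[stream_id]]
  counts <- as.integer(names(pn))
  with_seed(derive_seed(config$seed, 11, stream_id, trial), {
    T_end <- config$trial_duration_s
    onsets <- offsets <- numeric(0)
    cur <- 0
    repeat {
      gap <- if (stats::runif(1) < config$gap_prob) {
        stats::runif(1, 0, config$gap_max_s)
      } else 0
      on <- cur + gap
      dur <- stats::rlnorm(1, meanlog = log(med), sdlog = sdlog)
      if (on + dur > T_end) break
      onsets <- c(onsets, on)
      offsets <- c(offsets, on + dur)
      cur <- on + dur
    }
    if (!length(onsets)) {
      stop("trial too short to hold a single word at this duration setting")
    }
    nw <- length(onsets)
    word <- annotation_tier(onsets, offsets,
                            sprintf("w%04d", seq_len(nw)), "word")
    ph_on <- ph_off <- vector("list", nw)
    for (i in seq_len(nw)) {
      k <- sample(counts, 1, prob = pn)
      w <- stats::rgamma(k, shape = config$phoneme_alpha, rate = 1)
      bounds <- onsets[i] + (offsets[i] - onsets[i]) * cumsum(w) / sum(w)
      bounds[k] <- offsets[i] # exact partition
      ph_on[[i]] <- c(onsets[i], bounds[-k])
      ph_off[[i]] <- bounds
    }
    ph_on <- unlist(ph_on)
    ph_off <- unlist(ph_off)
    phoneme <- annotation_tier(ph_on, ph_off,
                               sprintf("p%05d", seq_along(ph_on)), "phoneme")
    list(word = word, phoneme = phoneme)
  })
}

#' Synthesize a speech-like envelope from an annotation tier pair
#'
#' Each phoneme contributes a Hann-windowed burst with an independent random
#' amplitude; bursts are summed and a small positive floor added. The random
#' amplitudes make the envelope carry information not linearly predictable
#' from the onset impulse trains.
#'
#' @param tiers List with `word`/`phoneme` tiers (from
#'   [simulate_annotations()]).
#' @param config A `sim_config`.
#' @param stream_id,trial Indices used for seed derivation.
#' @return Nonnegative envelope vector of the trial length at `config$fs`.
#' @export
simulate_envelope <- function(tiers, config, stream_id = 1, trial = 1) {
  fs <- config$fs
  n <- round(config$trial_duration_s * fs)
  with_seed(derive_seed(config$seed, 23, stream_id, trial), {
    idx <- onset_sample_index(tiers$phoneme$onset, fs) + 1L
    amp <- stats::rgamma(length(idx), shape = 3, rate = 3)
    train <- numeric(n)
    train[idx] <- train[idx] + amp
    wlen <- max(3L, round(0.12 * fs))
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
    env <- stats::convolve(train, rev(win), type = "open")
    env <- env[seq_len(n) + floor(wlen / 2)]
    env + 0.02 * max(env)
  })
}

#' Ground-truth TRF kernels
#'
#' Each feature's kernel is a sum of three Gaussian-windowed lobes over lags
#' 0-500 ms: early positive (~60 ms), mid positive (~220 ms), late negative
#' (~350 ms), echoing the P1/P2/N2 morphology of auditory responses. A
#' smooth frontotemporal channel profile scales the kernels per channel.
#'
#' @param config A `sim_config`.
#' @param lag_max_ms Kernel support in ms (default 500).
#' @param amplitudes Named list of per-feature lobe amplitudes
#'   `c(p1, p2, n2)`.
#' @return Object of class `gt_kernels`: array feature x lag x channel plus
#'   gains and fs.
#' @export
default_kernels <- function(config, lag_max_ms = 500,
                            amplitudes = list(
                              word_onset = c(1.0, 0.8, 0.6),
                              phoneme_onset = c(0.8, 0.5, 0.3),
                              envelope = c(0.6, 0.4, 0.3))) {
  fs <- config$fs
  lags_ms <- 1000 * seq(0, round(lag_max_ms * fs / 1000)) / fs
  lobe <- function(a, mu, sg) a * exp(-((lags_ms - mu)^2) / (2 * sg^2))
  layout <- default_channel_layout(config$n_channels)
  chs <- 0.25 + 0.75 * exp(-((layout$y - 0.2) / 0.45)^2)
  fnames <- names(amplitudes)
  K <- array(0, dim = c(length(fnames), length(lags_ms), config$n_channels),
             dimnames = list(fnames, NULL, NULL))
  for (f in seq_along(fnames)) {
    a <- amplitudes[[f]]
    base <- lobe(a[1], 60, 20) + lobe(a[2], 220, 35) - lobe(a[3], 350, 45)
    for (ch in seq_len(config$n_channels)) K[f, , ch] <- base * chs[ch]
  }
  structure(list(kernels = K, fs = fs, lags_ms = lags_ms,
                 attend_gain = config$attend_gain,
                 ignore_gain = config$ignore_gain,
                 feature_names = fnames, channel_profile = chs),
            class = "gt_kernels")
}

#' Bilaterally symmetric channel layout
#'
#' `n/2` mirror pairs at x = +/- 0.5 with y spread front to back; used for
#' symmetric channel selection and for the kernel channel profile.
#'
#' @param n_channels Even channel count.
#' @return data.frame with columns `x`, `y`.
#' @export
default_channel_layout <- function(n_channels) {
  stopifnot(n_channels %% 2 == 0)
  npair <- n_channels / 2
  y <- seq(-0.8, 0.8, length.out = npair)
  data.frame(x = rep(c(-0.5, 0.5), each = npair), y = rep(y, 2))
}

# 1/f^beta Gaussian noise via FFT spectral shaping, unit variance.
one_over_f_noise <- function(n, beta) {
  w <- stats::rnorm(n)
  if (beta == 0) return(w)
  W <- stats::fft(w)
  fr <- c(1, seq_len(n - 1))
  fr <- pmin(fr, n - fr + 1) # symmetric frequency index
  shape <- fr^(-beta / 2)
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Simulate one EEG trial from regressors and ground-truth kernels
#'
#' `EEG(ch, t) = sum_streams gain(stream) * sum_f (kernel_f_ch * x_f_stream)(t)
#' + noise`, where `*` is causal discrete convolution and the noise is
#' spatially independent 1/f^beta scaled so the realized pooled
#' signal-to-noise variance ratio equals `snr_db` exactly.
#'
#' @param features_by_stream List of two `stim_features` (each with
#'   `word_onset`, `phoneme_onset`, `envelope`).
#' @param kernels A `gt_kernels` object sharing `fs` with the features.
#' @param config A `sim_config`.
#' @param attended_stream 1 or 2.
#' @param trial Trial index for seed derivation.
#' @return List with `eeg` (channels x samples), `signal`, and the
#'   per-stream signal components `signal_by_stream`.
#' @export
simulate_eeg <- function(features_by_stream, kernels, config,
                         attended_stream = 1, trial = 1) {
  stopifnot(inherits(kernels, "gt_kernels"), attended_stream %in% c(1, 2))
  fs <- config$fs
  for (s in features_by_stream) {
    if (s$fs != fs) stop("regressor fs does not match the configuration")
    if (s$n_samples != round(config$trial_duration_s * fs)) {
      stop("regressor duration does not match the configuration")
    }
  }
  n <- features_by_stream[[1]]$n_samples
  C <- config$n_channels
  gains <- rep(kernels$ignore_gain, 2)
  gains[attended_stream] <- kernels$attend_gain
  sig_stream <- lapply(1:2, function(s) matrix(0, C, n))
  for (s in 1:2) {
    for (f in seq_along(kernels$feature_names)) {
      nm <- kernels$feature_names[f]
      x <- features_by_stream[[s]]$features[[nm]]
      if (is.null(x)) stop("feature '", nm, "' missing from stream ", s)
      for (ch in seq_len(C)) {
        k <- kernels$kernels[f, , ch]
        y <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
        sig_stream[[s]][ch, ] <- sig_stream[[s]][ch, ] + gains[s] * y
      }
    }
  }
  signal <- sig_stream[[1]] + sig_stream[[2]]
  if (is.finite(config$snr_db)) {
    noise <- with_seed(derive_seed(config$seed, 37, trial), {
      t(vapply(seq_len(C), function(ch) {
        one_over_f_noise(n, config$noise_exponent)
      }, numeric(n)))
    })
    vs <- stats::var(as.vector(signal))
    vn <- stats::var(as.vector(noise))
    if (vs > 0) {
      noise <- noise * sqrt(vs / (vn * 10^(config$snr_db / 10)))
    }
    # all-zero kernels leave pure unit-variance noise: no SNR to satisfy
    eeg <- signal + noise
  } else {
    eeg <- signal
  }
  list(eeg = eeg, signal = signal, signal_by_stream = sig_stream)
}

#' Simulate a complete synthetic subject
#'
#' Generates both streams' tiers, envelopes and regressors for every trial,
#' convolves them with the ground-truth kernels, and adds noise. The result
#' carries the ground truth alongside the data; downstream analysis stages
#' never read it.
#'
#' @param config A `sim_config`.
#' @param subject Subject index, folded into the seed so subjects differ.
#' @param attended_stream Stream index (1 or 2) the virtual listener attends.
#' @param kernels Optional `gt_kernels`; defaults to [default_kernels()].
#' @return Object of class `sim_subject`: `eeg` (`eeg_trials`), `streams`
#'   (per stream, per trial: tiers, envelope, `stim_features`), `attended`,
#'   `kernels`, `config`.
#' @export
simulate_subject <- function(config, subject = 1, attended_stream = 1,
                             kernels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$seed <- derive_seed(config$seed, 101, subject)
  if (is.null(kernels)) kernels <- default_kernels(cfg)
  n <- round(cfg$trial_duration_s * cfg$fs)
  streams <- lapply(1:2, function(s) list(trials = vector("list", cfg$n_trials)))
  trials <- vector("list", cfg$n_trials)
  for (tr in seq_len(cfg$n_trials)) {
    fsets <- vector("list", 2)
    for (s in 1:2) {
      tiers <- simulate_annotations(cfg, s, trial = tr)
      env <- simulate_envelope(tiers, cfg, stream_id = s, trial = tr)
      fset <- build_feature_set(tiers$word, tiers$phoneme, env,
                                fs = cfg$fs, n_samples = n,
                                stream_id = s, trial_id = tr)
      streams[[s]]$trials[[tr]] <- list(word = tiers$word,
                                        phoneme = tiers$phoneme,
                                        envelope = env, features = fset)
      fsets[[s]] <- fset
    }
    sim <- simulate_eeg(fsets, kernels, cfg, attended_stream, trial = tr)
    trials[[tr]] <- sim$eeg
  }
  eeg <- eeg_trials(trials, cfg$fs, layout = default_channel_layout(cfg$n_channels))
  structure(list(eeg = eeg, streams = streams, attended = attended_stream,
                 kernels = kernels, config = cfg, subject = subject),
            class = "sim_subject")
}

#' @export
print.sim_subject <- function(x, ...) {
  cat(sprintf("<sim_subject> #%d: %d trials x %.0f s @ %g Hz, %d channels, attends stream %d\n",
              x$subject, x$config$n_trials, x$config$trial_duration_s,
              x$config$fs, x$config$n_channels, x$attended))
  invisible(x)
}
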