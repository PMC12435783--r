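test_that("annotation generation is deterministic and respects construction rules", {
  cfg <- sim_config(trial_duration_s = 30, fs = 125, seed = 11)
  a <- simulate_annotations(cfg, 1)
  b <- simulate_annotations(cfg, 1)
  expect_identical(a, b) # bit-identical under the same config + seed
  expect_false(identical(a, simulate_annotations(cfg, 2)))

  validate_annotation_tiers(a$word, a$phoneme)
  # first phoneme onset of every word equals the word onset, exactly
  first_ph <- vapply(seq_len(nrow(a$word)), function(i) {
    min(a$phoneme$onset[a$phoneme$onset >= a$word$onset[i] - 1e-12 &
                          a$phoneme$offset <= a$word$offset[i] + 1e-12])
  }, numeric(1))
  expect_identical(first_ph, a$word$onset)
  # phonemes partition each word: durations sum to the word duration
  for (i in seq_len(nrow(a$word))) {
    sel <- a$phoneme$onset >= a$word$onset[i] - 1e-12 &
      a$phoneme$offset <= a$word$offset[i] + 1e-12
    expect_equal(sum(a$phoneme$offset[sel] - a$phoneme$onset[sel]),
                 a$word$offset[i] - a$word$onset[i], tolerance = 1e-9)
    # contiguity: each phoneme starts where the previous one ends
    expect_equal(a$phoneme$onset[sel][-1], utils::head(a$phoneme$offset[sel], -1),
                 tolerance = 1e-12)
  }
  # silent gaps never exceed 500 ms
  gaps <- a$word$onset[-1] - a$word$offset[-nrow(a$word)]
  expect_true(all(gaps >= 0 & gaps <= 0.5 + 1e-9))
})

test_that("a trial too short for one word errors", {
  cfg <- sim_config(trial_duration_s = 0.01, fs = 500, seed = 1)
  expect_error(simulate_annotations(cfg, 1), "too short")
})

test_that("generated duration medians match the configured stream statistics", {
  cfg <- sim_config(trial_duration_s = 600, fs = 500, seed = 3)
  t1 <- simulate_annotations(cfg, 1)
  st <- stimulus_statistics(t1$word, t1$phoneme)
  expect_equal(unname(st$word["median"]), 0.29, tolerance = 0.1)
  expect_equal(unname(st$phoneme["median"]), 0.07, tolerance = 0.1)
  t2 <- simulate_annotations(cfg, 2)
  st2 <- stimulus_statistics(t2$word, t2$phoneme)
  expect_equal(unname(st2$word["median"]), 0.27, tolerance = 0.1)
  expect_equal(unname(st2$phoneme["median"]), 0.06, tolerance = 0.12)
})

test_that("onset rates match the duration distributions' implied rates within 5%", {
  cfg <- sim_config(trial_duration_s = 600, fs = 500, seed = 13)
  t1 <- simulate_annotations(cfg, 1)
  span <- max(t1$word$offset)
  word_rate <- nrow(t1$word) / span
  # implied: 1 / (E[lognormal duration] + E[gap])
  e_dur <- cfg$word_median_s[1] * exp(cfg$word_sdlog[1]^2 / 2)
  e_gap <- cfg$gap_prob * cfg$gap_max_s / 2
  expect_equal(word_rate, 1 / (e_dur + e_gap), tolerance = 0.05)
  ph_per_word <- nrow(t1$phoneme) / nrow(t1$word)
  pn <- cfg$phonemes_per_word[[1]]
  expect_equal(ph_per_word, sum(as.numeric(names(pn)) * pn), tolerance = 0.05)
})

test_that("noiseless single-feature EEG equals a brute-force convolution loop", {
  cfg <- sim_config(n_trials = 1, trial_duration_s = 4, fs = 100,
                    n_channels = 2, snr_db = Inf, seed = 21,
                    attend_gain = 1, ignore_gain = 0)
  kern <- default_kernels(cfg)
  n <- 400
  tiers <- lapply(1:2, function(s) simulate_annotations(cfg, s))
  fsets <- lapply(1:2, function(s) {
    env <- simulate_envelope(tiers[[s]], cfg, stream_id = s)
    build_feature_set(tiers[[s]]$word, tiers[[s]]$phoneme, env,
                      fs = cfg$fs, n_samples = n)
  })
  sim <- simulate_eeg(fsets, kern, cfg, attended_stream = 1)
  # O(N*L) oracle: sum over features of direct convolution sums
  L <- dim(kern$kernels)[2]
  oracle <- matrix(0, 2, n)
  for (f in 1:3) {
    x <- fsets[[1]]$features[[kern$feature_names[f]]]
    for (ch in 1:2) {
      for (t in seq_len(n)) {
        tau <- 0:min(L - 1, t - 1)
        oracle[ch, t] <- oracle[ch, t] +
          sum(kern$kernels[f, tau + 1, ch] * x[t - tau])
      }
    }
  }
  expect_equal(sim$eeg, oracle, tolerance = 1e-10)
})

test_that("equal gains give equal-variance stream contributions; SNR is exact", {
  cfg <- sim_config(n_trials = 1, trial_duration_s = 60, fs = 125,
                    n_channels = 4, snr_db = 0, seed = 33,
                    attend_gain = 0.8, ignore_gain = 0.8)
  su <- simulate_subject(cfg, 1, attended_stream = 1)
  # rebuild the trial to inspect components
  fsets <- lapply(1:2, function(s) su$streams[[s]]$trials[[1]]$features)
  sim <- simulate_eeg(fsets, su$kernels, cfg, attended_stream = 1, trial = 1)
  v1 <- stats::var(as.vector(sim$signal_by_stream[[1]]))
  v2 <- stats::var(as.vector(sim$signal_by_stream[[2]]))
  expect_equal(v1 / v2, 1, tolerance = 0.25) # same gain, same generative law
  # exact symmetry: with equal gains the attended-stream label is irrelevant
  sim2 <- simulate_eeg(fsets, su$kernels, cfg, attended_stream = 2, trial = 1)
  expect_identical(sim$eeg, sim2$eeg)
  noise <- sim$eeg - sim$signal
  snr_db <- 10 * log10(stats::var(as.vector(sim$signal)) /
                         stats::var(as.vector(noise)))
  expect_equal(snr_db, 0, tolerance = 0.05)
})

test_that("simulate_eeg validates regressor compatibility", {
  cfg <- sim_config(n_trials = 1, trial_duration_s = 2, fs = 100,
                    n_channels = 2, seed = 2)
  kern <- default_kernels(cfg)
  f_bad <- stim_features(list(word_onset = numeric(150),
                              phoneme_onset = numeric(150),
                              envelope = numeric(150)), 100)
  f_ok <- stim_features(list(word_onset = numeric(200),
                             phoneme_onset = numeric(200),
                             envelope = numeric(200)), 100)
  expect_error(simulate_eeg(list(f_bad, f_bad), kern, cfg, 1), "duration")
  f_wrong_fs <- stim_features(list(word_onset = numeric(200),
                                   phoneme_onset = numeric(200),
                                   envelope = numeric(200)), 50)
  expect_error(simulate_eeg(list(f_wrong_fs, f_ok), kern, cfg, 1), "fs")
})

test_that("whole-subject simulation is reproducible bit for bit", {
  cfg <- sim_config(n_trials = 2, trial_duration_s = 10, fs = 100,
                    n_channels = 4, seed = 8)
  a <- simulate_subject(cfg, 3, attended_stream = 2)
  b <- simulate_subject(cfg, 3, attended_stream = 2)
  expect_identical(a$eeg$trials, b$eeg$trials)
  expect_identical(a$streams, b$streams)
})
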