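# Duration-preserving permutation null for onset regressors: word units —
# each carrying its duration, its internal phoneme timing, and the silent
# gap that follows it — are reordered and the timeline rebuilt, so word and
# phoneme rate statistics and all inter-onset-interval multisets are
# exactly preserved while the onset times themselves move.

#' Shuffle word units, rebuilding the onset timeline
#'
#' Each word unit consists of the word's duration, its label, its
#' within-word phoneme onsets/durations, and the silent gap up to the next
#' word onset. The movable units (all but the trial-final word, which keeps
#' its position so the inter-onset-interval multiset stays exact) are
#' reordered by a uniform random permutation and the onset timeline is
#' rebuilt by cumulative summation from the original first onset. Because
#' units travel with their gaps, the multisets of word durations, word
#' inter-onset intervals, and within-word phoneme onset offsets are all
#' preserved exactly, the total span is unchanged, and the permuted tiers
#' remain non-overlapping — but the onset times themselves are rearranged,
#' which is what makes the null informative. The identity ordering returns
#' the input unchanged.
#'
#' @param word,phoneme `annotation_tier` objects satisfying the tier
#'   invariants.
#' @param seed Integer seed used to draw the permutation (ignored when
#'   `ordering` is given).
#' @param ordering Optional explicit permutation of the movable units,
#'   i.e. of `seq_len(nrow(word) - 1)`.
#' @return List with permuted `word` and `phoneme` tiers plus the `ordering`
#'   used.
#' @export
shuffle_onsets <- function(word, phoneme, seed = NULL, ordering = NULL) {
  nw <- nrow(word)
  if (nw < 2) stop("need at least 2 words to permute")
  if (is.null(ordering)) {
    if (is.null(seed)) stop("provide either a seed or an explicit ordering")
    ordering <- with_seed(seed, sample.int(nw - 1))
  }
  stopifnot(length(ordering) == nw - 1,
            all(sort(ordering) == seq_len(nw - 1)))
  if (all(ordering == seq_len(nw - 1))) {
    return(list(word = word, phoneme = phoneme, ordering = ordering))
  }
  units <- decompose_word_units(word, phoneme)
  reassemble_word_units(units, word$onset[1], c(ordering, nw))
}

decompose_word_units <- function(word, phoneme) {
  nw <- nrow(word)
  lapply(seq_len(nw), function(i) {
    sel <- phoneme$onset >= word$onset[i] - 1e-9 &
      phoneme$offset <= word$offset[i] + 1e-9
    list(duration = word$offset[i] - word$onset[i],
         gap = if (i < nw) word$onset[i + 1] - word$offset[i] else 0,
         label = word$label[i],
         ph_onset_rel = phoneme$onset[sel] - word$onset[i],
         ph_offset_rel = phoneme$offset[sel] - word$onset[i],
         ph_label = phoneme$label[sel])
  })
}

reassemble_word_units <- function(units, first_onset, ordering) {
  nw <- length(ordering)
  w_on <- w_off <- numeric(nw)
  w_lab <- character(nw)
  ph <- vector("list", nw)
  cur <- first_onset
  for (j in seq_len(nw)) {
    u <- units[[ordering[j]]]
    w_on[j] <- cur
    w_off[j] <- cur + u$duration
    w_lab[j] <- u$label
    ph[[j]] <- data.frame(onset = cur + u$ph_onset_rel,
                          offset = cur + u$ph_offset_rel,
                          label = u$ph_label)
    cur <- w_off[j] + u$gap
  }
  phall <- do.call(rbind, ph)
  list(word = annotation_tier(w_on, w_off, w_lab, "word"),
       phoneme = annotation_tier(phall$onset, phall$offset, phall$label,
                                 "phoneme"),
       ordering = ordering[-length(ordering)])
}

#' Generate unique word-order permutations
#'
#' Rejection-samples orderings until `n_perm` distinct ones are found
#' (hash-set over the ordered index sequence). Errors when more orderings
#' are requested than exist.
#'
#' @param n_words Number of word units.
#' @param n_perm Number of unique orderings (default 100).
#' @param seed Integer seed.
#' @return List of `n_perm` integer permutations of `seq_len(n_words)`.
#' @export
generate_unique_orderings <- function(n_words, n_perm = 100, seed = 1) {
  stopifnot(n_words >= 1, n_perm >= 1)
  if (n_words <= 20 && n_perm > factorial(n_words)) {
    stop(sprintf("requested %d permutations but only %.0f orderings exist",
                 n_perm, factorial(n_words)))
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- vector("list", n_perm)
    got <- 0
    while (got < n_perm) {
      o <- sample.int(n_words)
      key <- paste(o, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1
        out[[got]] <- o
      }
    }
    out
  })
}

#' Chance-level distribution of TRFs and accuracies
#'
#' For each of `n_perm` permutations, every subject's onset tiers are
#' shuffled with [shuffle_onsets()] (the envelope, when present in the
#' model, is left intact), the forward model is refit with the frozen lambda
#' and scored, and results are averaged across subjects: one grand-average
#' accuracy (over trials and the selected channels) and one grand-average
#' channel-averaged TRF per permutation, per condition.
#'
#' The permutation pipeline is deterministic given `seed`; orderings are
#' unique per (subject, stream, trial) tier.
#'
#' @param subjects List of subject objects (see [simulate_subject()] for the
#'   structure: `$eeg`, `$streams[[s]]$trials[[t]]$word/phoneme/envelope`,
#'   `$attended`).
#' @param eeg_list Optional list of preprocessed `eeg_trials`, one per
#'   subject (defaults to `preprocess_eeg` of each subject's raw EEG).
#' @param spec A [model_spec()].
#' @param conditions Subset of `c("attend", "ignore")`.
#' @param lambda Frozen ridge parameter (scalar, or vector per subject).
#' @param lspec A `lag_spec`.
#' @param channels Integer indices of the selected channels to average over.
#' @param n_perm Number of permutations (default 100).
#' @param seed Master seed.
#' @return Object of class `chance_distribution`: `accuracy` (n_perm x
#'   condition matrix) and `trf` (list per condition of arrays
#'   n_perm x feature x lag), plus metadata.
#' @export
build_chance_distribution <- function(subjects, spec, lambda, lspec, channels,
                                      conditions = c("attend", "ignore"),
                                      n_perm = 100, seed = 1,
                                      eeg_list = NULL) {
  stopifnot(length(subjects) >= 1, n_perm >= 1)
  if (is.null(eeg_list)) {
    eeg_list <- lapply(subjects, function(su) preprocess_eeg(su$eeg))
  }
  lambdas <- rep_len(lambda, length(subjects))
  n_words_min <- Inf
  # pregenerate unique orderings per (subject, stream, trial)
  orderings <- lapply(seq_along(subjects), function(si) {
    su <- subjects[[si]]
    lapply(1:2, function(s) {
      lapply(seq_along(su$streams[[s]]$trials), function(tr) {
        nw <- nrow(su$streams[[s]]$trials[[tr]]$word)
        n_words_min <<- min(n_words_min, nw)
        generate_unique_orderings(nw - 1, n_perm,
                                  seed = derive_seed(seed, si, s, tr))
      })
    })
  })
  fnames <- model_feature_names(spec)
  acc <- matrix(NA_real_, n_perm, length(conditions),
                dimnames = list(NULL, conditions))
  trf <- lapply(conditions, function(cc) {
    array(NA_real_, dim = c(n_perm, length(fnames), lspec$n_lags),
          dimnames = list(NULL, fnames, NULL))
  })
  names(trf) <- conditions
  for (p in seq_len(n_perm)) {
    acc_s <- matrix(0, length(subjects), length(conditions))
    trf_s <- lapply(conditions, function(cc) {
      array(0, dim = c(length(fnames), lspec$n_lags))
    })
    for (si in seq_along(subjects)) {
      su <- subjects[[si]]
      perm_tiers <- lapply(1:2, function(s) {
        lapply(seq_along(su$streams[[s]]$trials), function(tr) {
          tt <- su$streams[[s]]$trials[[tr]]
          shuffle_onsets(tt$word, tt$phoneme,
                         ordering = orderings[[si]][[s]][[tr]][[p]])
        })
      })
      for (ci in seq_along(conditions)) {
        cv <- fit_subject_model(su, conditions[ci], spec, lambdas[si], lspec,
                                eeg = eeg_list[[si]],
                                tiers_override = perm_tiers)
        acc_s[si, ci] <- mean(cv$accuracy[, channels], na.rm = TRUE)
        trf_s[[ci]] <- trf_s[[ci]] +
          apply(cv$model$weights[, , channels, drop = FALSE], c(1, 2), mean)
      }
    }
    acc[p, ] <- colMeans(acc_s)
    for (ci in seq_along(conditions)) {
      trf[[ci]][p, , ] <- trf_s[[ci]] / length(subjects)
    }
  }
  structure(list(accuracy = acc, trf = trf, n_perm = n_perm, seed = seed,
                 model = spec$id, channels = channels,
                 envelope_permuted = FALSE),
            class = "chance_distribution")
}

#' @export
print.chance_distribution <- function(x, ...) {
  cat(sprintf("<chance_distribution> model %s, %d permutations; mean accuracy: %s\n",
              x$model, x$n_perm,
              paste(sprintf("%s=%.4f", colnames(x$accuracy),
                            colMeans(x$accuracy)), collapse = ", ")))
  invisible(x)
}
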