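# End-to-end orchestration: preprocess -> lambda tuning -> channel
# selection -> model fits per condition -> permutation null -> statistics,
# with seeded, logged, file-backed stages.

#' Pipeline run configuration
#'
#' Every default matches the analysis convention where one exists: lags
#' 0-500 ms, lambda grid 1e-6..1e6, 100 regressor permutations, cluster
#' alphas 0.001. Scale parameters (subjects, trial length, permutation
#' counts) default to desk scale.
#'
#' @param mode `"synthetic"` (generate subjects) or `"real"` (caller
#'   supplies `subjects`).
#' @param sim A [sim_config()] for synthetic mode.
#' @param n_subjects Number of subjects to simulate.
#' @param models Named list of [model_spec()]s.
#' @param n_perm Regressor permutations for the chance distribution.
#' @param n_perm_cluster Relabelings for the cluster test.
#' @param cluster_alpha,corrected_alpha Cluster-forming and cluster-level
#'   alphas.
#' @param k_channels Channels to select (default 12: six bilateral pairs).
#' @param symmetric_channels Require mirror-pair selection?
#' @param lambda Fixed ridge parameter; `NULL` tunes per subject on the
#'   combined attended+ignored word+phoneme model.
#' @param lag_min_ms,lag_max_ms Lag window.
#' @param seed Master seed; stage sub-seeds are derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       sim = sim_config(),
                       n_subjects = 20,
                       models = default_model_set(),
                       n_perm = 100,
                       n_perm_cluster = 2000,
                       cluster_alpha = 0.001,
                       corrected_alpha = 0.001,
                       k_channels = 12,
                       symmetric_channels = TRUE,
                       lambda = NULL,
                       lag_min_ms = 0, lag_max_ms = 500,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(models) >= 1, n_subjects >= 1)
  structure(list(mode = mode, sim = sim, n_subjects = n_subjects,
                 models = models, n_perm = n_perm,
                 n_perm_cluster = n_perm_cluster,
                 cluster_alpha = cluster_alpha,
                 corrected_alpha = corrected_alpha,
                 k_channels = k_channels,
                 symmetric_channels = symmetric_channels,
                 lambda = lambda, lag_min_ms = lag_min_ms,
                 lag_max_ms = lag_max_ms, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Synthetic mode generates `n_subjects` subjects with a known attention
#' gain, then runs: EEG preprocessing, per-subject ridge-parameter tuning
#' (on the combined attended+ignored word+phoneme model), accuracy-ranked
#' channel selection, every model x condition fit, the duration-preserving
#' permutation null, rank-sum tests against chance, the attend-vs-ignore
#' cluster permutation test per feature, and pairwise model comparisons
#' with Benjamini-Yekutieli correction. Statistics never see the
#' generator's ground truth. When `out_dir` is given, stage outputs are
#' written as TSV/JSON and a manifest is saved.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param subjects Pre-built subject list for `mode = "real"` (or to reuse
#'   simulations).
#' @return Object of class `pipeline_result` with `accuracy` (per model x
#'   condition, subject-level), `trf` (grand-average per model x condition),
#'   `chance`, `vs_chance`, `clusters`, `model_comparison`, `channels`,
#'   `lambda`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, subjects = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  lspec <- lag_spec(config$sim$fs, config$lag_min_ms, config$lag_max_ms)

  if (is.null(subjects)) {
    if (config$mode != "synthetic") stop("real mode requires `subjects`")
    pipeline_log("simulate", "generating %d synthetic subjects", config$n_subjects)
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, 1)
    subjects <- lapply(seq_len(config$n_subjects), function(si) {
      simulate_subject(cfg, subject = si,
                       attended_stream = 1 + (si %% 2))
    })
  }
  n_sub <- length(subjects)

  pipeline_log("preprocess", "low-pass + joint z-score, %d subjects", n_sub)
  eeg_list <- lapply(subjects, function(su) preprocess_eeg(su$eeg))

  if (is.null(config$lambda)) {
    pipeline_log("tune", "per-subject lambda on combined word+phoneme model")
    lambdas <- vapply(seq_len(n_sub), function(si) {
      tune_subject_lambda(subjects[[si]], lspec,
                          eeg = eeg_list[[si]])$lambda_opt
    }, numeric(1))
  } else {
    lambdas <- rep(config$lambda, n_sub)
  }
  pipeline_log("tune", "lambda(s): %s", paste(unique(lambdas), collapse = ", "))

  pipeline_log("channels", "accuracy-ranked selection (k = %d)", config$k_channels)
  sel_spec <- model_spec(c("word", "phoneme"), FALSE)
  chan_acc <- Reduce(`+`, lapply(seq_len(n_sub), function(si) {
    su <- subjects[[si]]
    fa <- subject_stream_features(su, su$attended, sel_spec)
    fi <- subject_stream_features(su, 3 - su$attended, sel_spec)
    feats <- lapply(seq_along(fa), function(tr) {
      combine_feature_sets(list(att = fa[[tr]], ign = fi[[tr]]))
    })
    cv <- crossval_trf(feats, eeg_list[[si]], lambdas[si], lspec)
    colMeans(cv$accuracy)
  })) / n_sub
  layout <- subjects[[1]]$eeg$layout
  selection <- select_channels(chan_acc, config$k_channels,
                               symmetry_required = config$symmetric_channels,
                               layout = layout)
  channels <- selection$selected

  conditions <- c("attend", "ignore")
  pipeline_log("fit", "%d models x %d conditions x %d subjects",
               length(config$models), length(conditions), n_sub)
  fits <- list()
  for (mid in names(config$models)) {
    for (cond in conditions) {
      per_sub <- lapply(seq_len(n_sub), function(si) {
        fit_subject_model(subjects[[si]], cond, config$models[[mid]],
                          lambdas[si], lspec, eeg = eeg_list[[si]])
      })
      acc_sub <- vapply(per_sub, function(cv) {
        mean(cv$accuracy[, channels], na.rm = TRUE)
      }, numeric(1))
      trf_sub <- lapply(per_sub, function(cv) {
        apply(cv$model$weights[, , channels, drop = FALSE], c(1, 2), mean)
      })
      fits[[mid]][[cond]] <- list(accuracy = acc_sub, trf_by_subject = trf_sub)
    }
  }

  pipeline_log("permute", "chance distributions (%d permutations)", config$n_perm)
  chance <- list()
  for (mid in names(config$models)) {
    chance[[mid]] <- build_chance_distribution(
      subjects, config$models[[mid]], lambdas, lspec, channels,
      conditions = conditions, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 2), eeg_list = eeg_list)
  }

  pipeline_log("stats", "rank-sum vs chance, cluster test, model comparisons")
  vs_chance <- list()
  for (mid in names(config$models)) {
    for (cond in conditions) {
      vs_chance[[paste(mid, cond, sep = ".")]] <-
        test_vs_chance(fits[[mid]][[cond]]$accuracy,
                       chance[[mid]]$accuracy[, cond])
    }
  }

  lag_ms <- 1000 * lspec$lags / lspec$fs
  clusters <- list()
  for (mid in names(config$models)) {
    fnames <- model_feature_names(config$models[[mid]])
    for (f in seq_along(fnames)) {
      if (fnames[f] == "envelope") next
      diff_sub <- t(vapply(seq_len(n_sub), function(si) {
        fits[[mid]]$attend$trf_by_subject[[si]][f, ] -
          fits[[mid]]$ignore$trf_by_subject[[si]][f, ]
      }, numeric(lspec$n_lags)))
      diff_chance <- chance[[mid]]$trf$attend[, f, ] -
        chance[[mid]]$trf$ignore[, f, ]
      clusters[[paste(mid, fnames[f], sep = ".")]] <-
        cluster_permutation_test(diff_sub, diff_chance,
                                 cluster_alpha = config$cluster_alpha,
                                 corrected_alpha = config$corrected_alpha,
                                 n_perm = config$n_perm_cluster,
                                 seed = derive_seed(config$seed, 3),
                                 lag_ms = lag_ms)
    }
  }

  comparisons <- list()
  onset_ids <- intersect(c("word", "phoneme", "word+phoneme"),
                         names(config$models))
  if (length(onset_ids) == 3 && n_sub >= 5) {
    pairs <- list(c("word", "phoneme"), c("phoneme", "word+phoneme"),
                  c("word", "word+phoneme"))
    for (cond in conditions) {
      accs <- lapply(onset_ids, function(mid) fits[[mid]][[cond]]$accuracy)
      names(accs) <- onset_ids
      comparisons[[cond]] <- compare_models(accs, pairs)
    }
  }

  grand_trf <- lapply(fits, function(bycond) {
    lapply(bycond, function(x) Reduce(`+`, x$trf_by_subject) / n_sub)
  })

  manifest <- list(
    seed = config$seed, n_subjects = n_sub,
    lambda = lambdas, channels = channels,
    models = names(config$models),
    n_perm = config$n_perm, n_perm_cluster = config$n_perm_cluster,
    fs = config$sim$fs, lag_ms = range(lag_ms),
    envelope_permuted = FALSE,
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    version = as.character(utils::packageVersion("speechtrf")))

  result <- structure(list(accuracy = fits, trf = grand_trf, chance = chance,
                           vs_chance = vs_chance, clusters = clusters,
                           model_comparison = comparisons,
                           channels = channels, channel_accuracy = chan_acc,
                           lambda = lambdas, lag_ms = lag_ms,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # subject-level accuracies
  acc_rows <- list()
  for (mid in names(result$accuracy)) {
    for (cond in names(result$accuracy[[mid]])) {
      a <- result$accuracy[[mid]][[cond]]$accuracy
      acc_rows[[paste(mid, cond)]] <-
        data.frame(model = mid, condition = cond,
                   subject = seq_along(a), accuracy = a)
    }
  }
  utils::write.table(do.call(rbind, acc_rows),
                     file.path(out_dir, "accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chance_rows <- list()
  for (mid in names(result$chance)) {
    ch <- result$chance[[mid]]$accuracy
    for (cond in colnames(ch)) {
      chance_rows[[paste(mid, cond)]] <-
        data.frame(model = mid, condition = cond,
                   perm = seq_len(nrow(ch)), accuracy = ch[, cond])
    }
  }
  utils::write.table(do.call(rbind, chance_rows),
                     file.path(out_dir, "chance_accuracy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl_rows <- list()
  for (key in names(result$clusters)) {
    cl <- result$clusters[[key]]$clusters
    if (nrow(cl)) cl_rows[[key]] <- cbind(test = key, cl)
  }
  if (length(cl_rows)) {
    utils::write.table(do.call(rbind, cl_rows),
                       file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(result$model_comparison)) {
    cmp <- do.call(rbind, lapply(names(result$model_comparison), function(cond) {
      cbind(condition = cond,
            as.data.frame(result$model_comparison[[cond]]))
    }))
    utils::write.table(cmp, file.path(out_dir, "model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize pipeline result files
#'
#' Reads the TSV outputs of [run_pipeline()] back from disk and prints one
#' table of accuracies by model/condition with chance percentiles and one
#' table of significant cluster windows. Missing stage outputs produce a
#' partial report with explicit gaps.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return List with `accuracy_table`, `cluster_table`, `complete`
#'   (logical), invisibly printed.
#' @export
report_summary <- function(out_dir) {
  paths <- list(accuracy = file.path(out_dir, "accuracy.tsv"),
                chance = file.path(out_dir, "chance_accuracy.tsv"),
                clusters = file.path(out_dir, "clusters.tsv"))
  have <- vapply(paths, file.exists, logical(1))
  acc_tab <- NULL
  if (have["accuracy"]) {
    acc <- utils::read.table(paths$accuracy, header = TRUE, sep = "\t")
    acc_tab <- stats::aggregate(accuracy ~ model + condition, acc, mean)
    names(acc_tab)[3] <- "mean_accuracy"
    if (have["chance"]) {
      ch <- utils::read.table(paths$chance, header = TRUE, sep = "\t")
      q95 <- stats::aggregate(accuracy ~ model + condition, ch,
                              stats::quantile, probs = 0.95)
      names(q95)[3] <- "chance_q95"
      acc_tab <- merge(acc_tab, q95, by = c("model", "condition"))
      acc_tab$exceeds_chance_q95 <- acc_tab$mean_accuracy > acc_tab$chance_q95
    } else {
      acc_tab$chance_q95 <- NA_real_
    }
  }
  cl_tab <- NULL
  if (have["clusters"]) {
    cl <- utils::read.table(paths$clusters, header = TRUE, sep = "\t")
    cl_tab <- cl[cl$significant,
                 c("test", "lag_start_ms", "lag_end_ms", "t_sum", "p_value")]
  }
  complete <- all(have[c("accuracy", "chance")])
  if (!is.null(acc_tab)) {
    cat("Prediction accuracy by model and condition:\n")
    print(acc_tab, row.names = FALSE)
  } else {
    cat("[missing] accuracy.tsv\n")
  }
  if (!is.null(cl_tab) && nrow(cl_tab)) {
    cat("\nSignificant attend-vs-ignore cluster windows (ms):\n")
    print(cl_tab, row.names = FALSE)
  } else {
    cat("\nNo significant clusters on record",
        if (!have["clusters"]) " (clusters.tsv missing)" else "", "\n", sep = "")
  }
  invisible(list(accuracy_table = acc_tab, cluster_table = cl_tab,
                 complete = complete))
}
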