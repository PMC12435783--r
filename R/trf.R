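# Forward TRF estimation: lagged ridge regression, leave-one-trial-out
# cross-validation, and prediction accuracy on valid post-onset samples.

#' Lag specification for the forward model
#'
#' @param fs Sampling rate in Hz.
#' @param lag_min_ms,lag_max_ms Lag window in milliseconds (default 0-500 ms,
#'   the range used for higher-order speech tracking).
#' @return Object of class `lag_spec` with the integer sample lags.
#' @export
lag_spec <- function(fs, lag_min_ms = 0, lag_max_ms = 500) {
  stopifnot(fs > 0, lag_min_ms <= lag_max_ms)
  lags <- seq.int(round(lag_min_ms * fs / 1000), round(lag_max_ms * fs / 1000))
  structure(list(fs = fs, lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms,
                 lags = lags, n_lags = length(lags)),
            class = "lag_spec")
}

#' Multichannel EEG trial container
#'
#' @param trials List of channels x samples numeric matrices (equal channel
#'   counts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Optional channel names.
#' @param layout Optional data.frame with columns `x`, `y`: 2-D channel
#'   coordinates used for symmetric channel selection.
#' @return Object of class `eeg_trials`.
#' @export
eeg_trials <- function(trials, fs, channel_labels = NULL, layout = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1)
  nch <- unique(vapply(trials, nrow, integer(1)))
  if (length(nch) != 1) stop("all trials must share the channel count")
  for (tr in trials) if (!all(is.finite(tr))) stop("EEG contains non-finite values")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  structure(list(trials = trials, fs = fs, n_channels = nch,
                 channel_labels = channel_labels, layout = layout,
                 normalized = FALSE),
            class = "eeg_trials")
}

#' @export
print.eeg_trials <- function(x, ...) {
  ns <- vapply(x$trials, ncol, integer(1))
  cat(sprintf("<eeg_trials> %d trials, %d channels @ %g Hz, %s samples/trial%s\n",
              length(x$trials), x$n_channels, x$fs,
              paste(unique(ns), collapse = "/"),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Preprocess EEG: zero-phase low-pass and joint z-scoring
#'
#' Applies a zero-phase windowed-sinc FIR low-pass (order 100, Hann window)
#' per channel, then z-scores all channels and trials *jointly* with one
#' pooled mean and standard deviation, preserving the relative power across
#' channels.
#'
#' @param eeg An `eeg_trials` object.
#' @param lowpass_hz Low-pass cutoff in Hz (default 15).
#' @param fir_order FIR filter order (default 100).
#' @return A new `eeg_trials` with `normalized = TRUE`.
#' @export
preprocess_eeg <- function(eeg, lowpass_hz = 15, fir_order = 100) {
  stopifnot(inherits(eeg, "eeg_trials"), eeg$fs > 2 * lowpass_hz)
  h <- fir_lowpass(fir_order, lowpass_hz, eeg$fs)
  trials <- lapply(eeg$trials, function(tr) {
    t(apply(tr, 1, function(x) filtfilt(h, 1, x)))
  })
  all_vals <- unlist(trials, use.names = FALSE)
  mu <- mean(all_vals)
  sigma <- stats::sd(all_vals)
  if (sigma == 0) stop("EEG has zero pooled variance; cannot z-score")
  trials <- lapply(trials, function(tr) (tr - mu) / sigma)
  out <- eeg_trials(trials, eeg$fs, eeg$channel_labels, eeg$layout)
  out$normalized <- TRUE
  out
}

#' Build the lagged (time-expanded) design matrix
#'
#' Column `(f, tau)` at row `t` holds feature `f` at time `t - tau`; rows
#' with `t - tau < 0` are zero (pre-trial stimulus history is zero-padded).
#' A bias column of ones is appended last. The matrix is sparse, which makes
#' impulse-train designs cheap.
#'
#' @param features A `stim_features` object.
#' @param lspec A `lag_spec` with matching `fs`.
#' @return A `Matrix::dgCMatrix` of size samples x (features x lags + 1) with
#'   attributes `feature_names`, `lags`, `n_lags`.
#' @export
build_lagged_design <- function(features, lspec) {
  stopifnot(inherits(features, "stim_features"), inherits(lspec, "lag_spec"))
  if (features$fs != lspec$fs) stop("features and lag spec disagree on fs")
  n <- features$n_samples
  L <- lspec$n_lags
  if (L > n) stop("lag window is longer than the trial")
  fnames <- names(features$features)
  ii <- vector("list", length(fnames) + 1)
  jj <- vector("list", length(fnames) + 1)
  xx <- vector("list", length(fnames) + 1)
  for (f in seq_along(fnames)) {
    x <- features$features[[f]]
    nz <- which(x != 0)
    m <- length(nz)
    if (m == 0) next
    rows <- rep.int(nz, L) + rep(lspec$lags, each = m)
    cols <- (f - 1L) * L + rep(seq_len(L), each = m)
    vals <- rep.int(x[nz], L)
    keep <- rows <= n
    ii[[f]] <- rows[keep]
    jj[[f]] <- cols[keep]
    xx[[f]] <- vals[keep]
  }
  nf <- length(fnames)
  ii[[nf + 1]] <- seq_len(n)
  jj[[nf + 1]] <- rep.int(nf * L + 1L, n)
  xx[[nf + 1]] <- rep.int(1, n)
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, nf * L + 1L))
  attr(X, "feature_names") <- fnames
  attr(X, "lags") <- lspec$lags
  attr(X, "n_lags") <- L
  X
}

# Sufficient statistics for ridge fitting of one trial. Dense designs
# (envelope-heavy models) go through BLAS, sparse impulse designs through
# Matrix; both give identical results.
design_suffstats <- function(X, eeg_trial) {
  Y <- t(eeg_trial) # samples x channels
  stopifnot(nrow(X) == nrow(Y))
  dens <- if (methods::is(X, "sparseMatrix")) {
    length(X@x) / prod(dim(X))
  } else 1
  if (dens > 0.1) {
    Xd <- as.matrix(X)
    list(XtX = crossprod(Xd), XtY = crossprod(Xd, Y), n = nrow(X))
  } else {
    list(XtX = as.matrix(Matrix::crossprod(X)),
         XtY = as.matrix(Matrix::crossprod(X, Y)),
         n = nrow(X))
  }
}

ridge_solve <- function(XtX, XtY, lambda) {
  p <- nrow(XtX)
  pen <- rep(lambda, p)
  pen[p] <- 0 # bias column unpenalized
  A <- XtX + diag(pen, p)
  W <- tryCatch(solve(A, XtY), error = function(e) {
    stop("ridge system is singular; use a positive lambda from the grid ",
         "(10^-6 .. 10^6)", call. = FALSE)
  })
  W
}

#' Fit a forward TRF by ridge regression
#'
#' Solves `(X'X + lambda I') w = X'y` per channel, where `I'` is the identity
#' zeroed at the bias column, on a lagged design from
#' [build_lagged_design()].
#'
#' @param X Lagged design matrix (from [build_lagged_design()]).
#' @param eeg_trial Channels x samples matrix aligned with `X`'s rows.
#' @param lambda Ridge parameter, must be > 0.
#' @param channel_labels Optional channel names.
#' @return Object of class `trf_model` with the feature x lag x channel
#'   weight array, per-channel bias, and the lambda used.
#' @export
ridge_fit <- function(X, eeg_trial, lambda, channel_labels = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("lambda must be a single positive number; lambda = 0 is not ",
         "supported (the normal equations may be singular) - use the grid")
  }
  ss <- design_suffstats(X, eeg_trial)
  W <- ridge_solve(ss$XtX, ss$XtY, lambda)
  weights_to_model(W, X, lambda, channel_labels)
}

weights_to_model <- function(W, X, lambda, channel_labels = NULL,
                             lag_info = NULL) {
  fnames <- if (is.null(lag_info)) attr(X, "feature_names") else lag_info$feature_names
  L <- if (is.null(lag_info)) attr(X, "n_lags") else lag_info$n_lags
  lags <- if (is.null(lag_info)) attr(X, "lags") else lag_info$lags
  C <- ncol(W)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(C))
  w <- array(W[seq_len(length(fnames) * L), , drop = FALSE],
             dim = c(L, length(fnames), C))
  w <- aperm(w, c(2, 1, 3)) # feature x lag x channel
  dimnames(w) <- list(fnames, NULL, channel_labels)
  structure(list(weights = w, bias = W[nrow(W), ], lambda = lambda,
                 lags = lags, feature_names = fnames,
                 channel_labels = channel_labels),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %d features x %d lags x %d channels (lambda = %g)\n",
              d[1], d[2], d[3], x$lambda))
  invisible(x)
}

#' Predict EEG from a fitted TRF
#'
#' @param model A `trf_model`.
#' @param features A `stim_features` with the model's feature names.
#' @param lspec The `lag_spec` used at fit time.
#' @return Predicted channels x samples matrix.
#' @export
predict_eeg <- function(model, features, lspec) {
  stopifnot(inherits(model, "trf_model"))
  if (features$fs != lspec$fs) stop("features and lag spec disagree on fs")
  if (!identical(names(features$features), model$feature_names)) {
    stop("feature names do not match the fitted model")
  }
  X <- build_lagged_design(features, lspec)
  W <- model_to_weight_matrix(model)
  t(as.matrix(X %*% W))
}

model_to_weight_matrix <- function(model) {
  w <- aperm(model$weights, c(2, 1, 3)) # lag x feature x channel
  d <- dim(w)
  W <- matrix(w, nrow = d[1] * d[2], ncol = d[3])
  rbind(W, model$bias)
}

#' Valid-sample mask: 0-500 ms after any onset
#'
#' Marks samples within the lag window after any impulse of any onset-type
#' feature (names ending `_onset`). The envelope contributes no mask. A
#' feature set without onset features yields an all-true mask (the whole
#' trial is scored).
#'
#' @param features A `stim_features`.
#' @param lspec A `lag_spec`; the window length is `lspec$n_lags` samples.
#' @return Logical vector of length `n_samples`.
#' @export
valid_sample_mask <- function(features, lspec) {
  n <- features$n_samples
  onames <- onset_feature_names(features)
  if (!length(onames)) return(rep(TRUE, n))
  L <- lspec$n_lags
  cover <- numeric(n + L)
  any_onset <- FALSE
  for (nm in onames) {
    idx <- which(features$features[[nm]] != 0)
    if (!length(idx)) next
    any_onset <- TRUE
    cover[idx] <- cover[idx] + 1
    cover[idx + L] <- cover[idx + L] - 1
  }
  if (!any_onset) stop("no onsets present in any onset feature")
  cumsum(cover)[seq_len(n)] > 0
}

#' Pearson correlation on valid samples only
#'
#' @param pred,actual Channels x samples matrices.
#' @param mask Logical vector over samples with at least 3 TRUE entries.
#' @return Per-channel correlation vector; `NA` where a masked segment is
#'   constant (correlation undefined).
#' @export
valid_sample_correlation <- function(pred, actual, mask) {
  stopifnot(ncol(pred) == length(mask), dim(pred) == dim(actual))
  if (sum(mask) < 3) stop("mask must retain at least 3 samples")
  p <- pred[, mask, drop = FALSE]
  a <- actual[, mask, drop = FALSE]
  vapply(seq_len(nrow(p)), function(ch) {
    if (stats::sd(p[ch, ]) == 0 || stats::sd(a[ch, ]) == 0) return(NA_real_)
    stats::cor(p[ch, ], a[ch, ])
  }, numeric(1))
}

#' Leave-one-trial-out cross-validated TRF
#'
#' For each fold, fits on all other trials (by accumulating per-trial
#' covariance), predicts the held-out trial, and scores the prediction with
#' [valid_sample_correlation()] on that trial's valid-sample mask. Returns
#' the fold-averaged TRF (in original stimulus units) and the trial x
#' channel accuracy table.
#'
#' @param features_list List of `stim_features`, one per trial, with
#'   identical feature names.
#' @param eeg An `eeg_trials` object with the same number of trials.
#' @param lambda Ridge parameter (> 0).
#' @param lspec A `lag_spec`.
#' @param standardize If `TRUE` (default), each feature is scaled to unit
#'   pooled variance across trials before fitting so a single lambda is
#'   meaningful across impulse and envelope regressors; returned weights are
#'   rescaled back to stimulus units.
#' @return List with `model` (fold-averaged `trf_model`), `accuracy`
#'   (trial x channel r), `mse` (trial x channel), `valid_fraction` (per
#'   trial), `lambda`, and `fold_models`.
#' @export
crossval_trf <- function(features_list, eeg, lambda, lspec,
                         standardize = TRUE) {
  pc <- cv_precompute(features_list, eeg, lspec, standardize)
  cv_run(pc, eeg, lambda)
}

# One-time work shared across lambda values: scaling, lagged designs,
# per-trial covariance, valid-sample masks.
cv_precompute <- function(features_list, eeg, lspec, standardize = TRUE) {
  stopifnot(length(features_list) == length(eeg$trials),
            length(features_list) >= 2)
  fnames <- names(features_list[[1]]$features)
  for (f in features_list) {
    if (!identical(names(f$features), fnames)) {
      stop("trials have mismatched feature names")
    }
  }
  scales <- feature_scales(features_list, standardize)
  features_list <- lapply(features_list, scale_features, scales = scales)
  K <- length(features_list)
  designs <- lapply(features_list, build_lagged_design, lspec = lspec)
  stats_list <- lapply(seq_len(K), function(i) {
    design_suffstats(designs[[i]], eeg$trials[[i]])
  })
  masks <- lapply(features_list, valid_sample_mask, lspec = lspec)
  list(designs = designs, stats_list = stats_list, masks = masks,
       scales = scales, lspec = lspec,
       lag_info = list(feature_names = fnames, n_lags = lspec$n_lags,
                       lags = lspec$lags))
}

cv_run <- function(pc, eeg, lambda) {
  K <- length(pc$designs)
  fnames <- pc$lag_info$feature_names
  XtX_tot <- Reduce(`+`, lapply(pc$stats_list, `[[`, "XtX"))
  XtY_tot <- Reduce(`+`, lapply(pc$stats_list, `[[`, "XtY"))
  C <- eeg$n_channels
  acc <- matrix(NA_real_, K, C, dimnames = list(NULL, eeg$channel_labels))
  mse <- matrix(NA_real_, K, C, dimnames = list(NULL, eeg$channel_labels))
  valid_fraction <- numeric(K)
  fold_models <- vector("list", K)
  for (k in seq_len(K)) {
    W <- ridge_solve(XtX_tot - pc$stats_list[[k]]$XtX,
                     XtY_tot - pc$stats_list[[k]]$XtY, lambda)
    pred <- t(as.matrix(pc$designs[[k]] %*% W))
    actual <- eeg$trials[[k]]
    mask <- pc$masks[[k]]
    valid_fraction[k] <- mean(mask)
    acc[k, ] <- valid_sample_correlation(pred, actual, mask)
    dif <- (pred - actual)[, mask, drop = FALSE]
    mse[k, ] <- rowMeans(dif^2)
    fold_models[[k]] <- weights_to_model(W, NULL, lambda, eeg$channel_labels,
                                         lag_info = pc$lag_info)
  }
  wbar <- Reduce(`+`, lapply(fold_models, `[[`, "weights")) / K
  bbar <- Reduce(`+`, lapply(fold_models, `[[`, "bias")) / K
  # back to original stimulus units
  for (f in seq_along(fnames)) wbar[f, , ] <- wbar[f, , ] / pc$scales[f]
  model <- structure(list(weights = wbar, bias = bbar, lambda = lambda,
                          lags = pc$lspec$lags, feature_names = fnames,
                          channel_labels = eeg$channel_labels),
                     class = "trf_model")
  list(model = model, accuracy = acc, mse = mse,
       valid_fraction = valid_fraction, lambda = lambda,
       fold_models = fold_models, feature_scales = pc$scales)
}

feature_scales <- function(features_list, standardize) {
  fnames <- names(features_list[[1]]$features)
  scales <- rep(1, length(fnames))
  names(scales) <- fnames
  if (!standardize) return(scales)
  for (f in seq_along(fnames)) {
    v <- unlist(lapply(features_list, function(s) s$features[[f]]),
                use.names = FALSE)
    s <- stats::sd(v)
    if (s > 0) scales[f] <- s
  }
  scales
}

scale_features <- function(set, scales) {
  for (f in seq_along(scales)) {
    set$features[[f]] <- set$features[[f]] / scales[f]
  }
  set
}

#' Default ridge parameter grid
#'
#' Thirteen decade steps from 1e-6 to 1e6.
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-6, 6)

#' Tune the ridge parameter by cross-validated MSE
#'
#' Runs the leave-one-trial-out cross-validation at every grid value and
#' selects the lambda minimizing the mean squared error between predicted
#' and actual EEG, averaged across test trials and channels (MSE is computed
#' on the same valid-sample mask as the accuracy). Ties go to the smaller
#' lambda.
#'
#' @inheritParams crossval_trf
#' @param grid Strictly increasing positive lambda values.
#' @return List with `lambda_opt` and `mse_by_lambda`.
#' @export
tune_lambda <- function(features_list, eeg, lspec,
                        grid = default_lambda_grid(), standardize = TRUE) {
  stopifnot(length(grid) >= 1, all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  pc <- cv_precompute(features_list, eeg, lspec, standardize)
  mse <- vapply(grid, function(lam) mean(cv_run(pc, eeg, lam)$mse), numeric(1))
  list(lambda_opt = grid[which.min(mse)], mse_by_lambda = stats::setNames(mse, grid))
}
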