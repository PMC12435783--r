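make_fset <- function(feats, fs) stim_features(feats, fs)

test_that("EEG preprocessing z-scores jointly and preserves relative channel power", {
  set.seed(1)
  trials <- lapply(1:2, function(i) {
    rbind(stats::rnorm(2000, sd = 3), stats::rnorm(2000, sd = 1))
  })
  eeg <- eeg_trials(trials, fs = 200)
  out <- preprocess_eeg(eeg)
  vals <- unlist(out$trials)
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  expect_equal(stats::sd(vals), 1, tolerance = 1e-12)
  sds <- sapply(out$trials, function(tr) apply(tr, 1, stats::sd))
  expect_equal(mean(sds[1, ] / sds[2, ]), 3, tolerance = 0.1)
  expect_true(out$normalized)
  # 20 Hz content is attenuated below 1% variance at a 15 Hz cutoff
  # (checked as spectral power relative to a passband tone, since the joint
  # z-score rescales total variance afterwards)
  t <- (0:2499) / 500
  mix <- matrix(sin(2 * pi * 5 * t) + sin(2 * pi * 20 * t), 1)
  eeg2 <- eeg_trials(list(mix, mix), fs = 500)
  out2 <- preprocess_eeg(eeg2)
  pw <- function(x, f) Mod(sum(x * exp(-2i * pi * f * t)))^2
  y <- out2$trials[[1]][1, ]
  expect_lt(pw(y, 20) / pw(y, 5), 0.01)
  expect_error(eeg_trials(list(matrix(c(1, NA), 1)), 100), "non-finite")
})

test_that("lagged design places shifted copies with zero-padded history", {
  fs <- 100
  x <- numeric(50)
  x[11] <- 1 # 0-based sample 10
  ls <- lag_spec(fs, 0, 20) # lags 0..2 samples
  X <- build_lagged_design(make_fset(list(a_onset = x), fs), ls)
  expect_equal(dim(X), c(50, 4)) # 3 lags + bias
  M <- as.matrix(X)
  expect_equal(which(M[, 1] != 0), 11)
  expect_equal(which(M[, 2] != 0), 12)
  expect_equal(which(M[, 3] != 0), 13)
  expect_true(all(M[, 4] == 1))
  expect_equal(lag_spec(500)$n_lags, 251) # 0-500 ms at 500 Hz
})

test_that("lagged design columns equal an index-loop shift oracle", {
  set.seed(5)
  fs <- 100
  n <- 200
  x <- stats::rnorm(n)
  ls <- lag_spec(fs, 0, 70)
  X <- as.matrix(build_lagged_design(make_fset(list(env = x), fs), ls))
  for (li in seq_along(ls$lags)) {
    tau <- ls$lags[li]
    col <- numeric(n)
    for (t in seq_len(n)) if (t - tau >= 1) col[t] <- x[t - tau]
    expect_equal(X[, li], col)
  }
  expect_error(build_lagged_design(make_fset(list(a = numeric(10)), fs),
                                   lag_spec(fs, 0, 500)),
               "longer than the trial")
})

test_that("ridge_fit solves the penalized normal equations", {
  set.seed(9)
  fs <- 100
  n <- 300
  # noiseless recovery
  k <- exp(-((0:30) - 10)^2 / 20)
  x <- numeric(n)
  x[sample(n - 40, 30)] <- 1
  y <- stats::convolve(x, rev(k), type = "open")[1:n]
  ls <- lag_spec(fs, 0, 300)
  X <- build_lagged_design(make_fset(list(a_onset = x), fs), ls)
  m <- ridge_fit(X, matrix(y, 1), 1e-6)
  expect_lt(max(abs(m$weights[1, , 1] - k)), 1e-6)
  expect_error(ridge_fit(X, matrix(y, 1), 0), "lambda")
  # strong shrinkage collapses the weight norm
  m_big <- ridge_fit(X, matrix(y, 1), 1e6)
  expect_lt(sqrt(sum(m_big$weights^2)), 1e-3 * sqrt(sum(m$weights^2)))
})

test_that("ridge_fit matches a direct normal-equations oracle on random instances", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 120
    nf <- sample(1:3, 1)
    fs <- 50
    feats <- stats::setNames(lapply(seq_len(nf), function(i) stats::rnorm(n)),
                             paste0("f", seq_len(nf)))
    ls <- lag_spec(fs, 0, sample(c(100, 200), 1))
    X <- build_lagged_design(make_fset(feats, fs), ls)
    Y <- matrix(stats::rnorm(3 * n), 3)
    lam <- 10^stats::runif(1, -3, 2)
    m <- ridge_fit(X, Y, lam)
    Xd <- as.matrix(X)
    p <- ncol(Xd)
    Ip <- diag(c(rep(lam, p - 1), 0))
    W_oracle <- solve(t(Xd) %*% Xd + Ip, t(Xd) %*% t(Y))
    W_fit <- speechtrf:::model_to_weight_matrix(m)
    expect_lt(max(abs(W_fit - W_oracle)), 1e-8)
  }
})

test_that("prediction reproduces training data and reduces to convolution", {
  set.seed(3)
  fs <- 100
  n <- 400
  x <- numeric(n)
  x[sample(n - 60, 40)] <- 1
  k <- sin(seq(0, pi, length.out = 51))
  y <- stats::convolve(x, rev(k), type = "open")[1:n]
  ls <- lag_spec(fs, 0, 500)
  fset <- make_fset(list(a_onset = x), fs)
  X <- build_lagged_design(fset, ls)
  m <- ridge_fit(X, matrix(y, 1), 1e-8)
  pred <- predict_eeg(m, fset, ls)
  expect_equal(as.vector(pred), y, tolerance = 1e-6)
  # zero features predict the bias everywhere
  zero <- make_fset(list(a_onset = numeric(n)), fs)
  m$bias <- 0.7
  expect_equal(as.vector(predict_eeg(m, zero, ls)), rep(0.7, n))
  expect_error(predict_eeg(m, make_fset(list(b_onset = x), fs), ls),
               "feature names")
})

test_that("valid-sample mask covers 0-500 ms after onsets, union over features", {
  fs <- 500
  ls <- lag_spec(fs)
  one <- make_fset(list(w_onset = c(1, numeric(999))), fs)
  expect_equal(sum(valid_sample_mask(one, ls)), 251)
  # onsets every 100 ms: all-true from the first onset on
  x <- numeric(1000)
  x[seq(1, 1000, by = 50)] <- 1
  dense <- make_fset(list(w_onset = x), fs)
  expect_true(all(valid_sample_mask(dense, ls)))
  # envelope-only models score every sample
  env_only <- make_fset(list(envelope = stats::rnorm(100)), fs)
  expect_true(all(valid_sample_mask(env_only, ls)))
})

test_that("valid-sample mask equals a brute-force interval union on random onsets", {
  set.seed(23)
  fs <- 100
  ls <- lag_spec(fs) # 51-sample window
  for (rep in 1:5) {
    n <- 500
    x1 <- as.numeric(stats::runif(n) < 0.02)
    x2 <- as.numeric(stats::runif(n) < 0.01)
    fset <- make_fset(list(a_onset = x1, b_onset = x2), fs)
    mask <- valid_sample_mask(fset, ls)
    oracle <- rep(FALSE, n)
    for (i in c(which(x1 != 0), which(x2 != 0))) {
      oracle[i:min(n, i + ls$n_lags - 1)] <- TRUE
    }
    expect_equal(mask, oracle)
  }
})

test_that("valid-sample correlation behaves at the extremes and matches Pearson", {
  set.seed(31)
  a <- matrix(stats::rnorm(2 * 200), 2)
  mask <- rep(TRUE, 200)
  expect_equal(valid_sample_correlation(a, a, mask), c(1, 1))
  expect_equal(valid_sample_correlation(a, -a, mask), c(-1, -1))
  b <- matrix(stats::rnorm(2 * 200), 2)
  # textbook formula oracle
  r_oracle <- sapply(1:2, function(ch) {
    x <- a[ch, ]; y <- b[ch, ]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  })
  expect_equal(valid_sample_correlation(a, b, mask), r_oracle,
               tolerance = 1e-12)
  # constant masked segment is missing, not zero
  cst <- matrix(1, 1, 200)
  expect_true(is.na(valid_sample_correlation(cst, a[1, , drop = FALSE], mask)))
  expect_error(valid_sample_correlation(a, b, c(TRUE, TRUE, rep(FALSE, 198))),
               "at least 3")
})

test_that("masking monotonicity: growing the mask approaches plain Pearson", {
  set.seed(13)
  a <- matrix(stats::rnorm(300), 1)
  b <- a + matrix(stats::rnorm(300, sd = 0.5), 1)
  full_r <- stats::cor(a[1, ], b[1, ])
  sizes <- c(50, 100, 200, 300)
  rs <- sapply(sizes, function(k) {
    valid_sample_correlation(a, b, c(rep(TRUE, k), rep(FALSE, 300 - k)))
  })
  expect_equal(rs[length(rs)], full_r, tolerance = 1e-12)
  expect_lt(abs(rs[3] - full_r), abs(rs[1] - full_r) + 0.1)
})

test_that("cross-validation folds match brute-force refits and score perfectly on clean data", {
  set.seed(19)
  fs <- 100
  n <- 500
  ls <- lag_spec(fs, 0, 200)
  k <- cos(seq(0, 2 * pi, length.out = ls$n_lags))
  feats <- lapply(1:3, function(tr) {
    x <- numeric(n)
    x[sample(n - 30, 40)] <- 1
    make_fset(list(a_onset = x), fs)
  })
  trials <- lapply(feats, function(f) {
    matrix(stats::convolve(f$features[[1]], rev(k), type = "open")[1:n], 1)
  })
  eeg <- eeg_trials(trials, fs)
  cv <- crossval_trf(feats, eeg, 1e-6, ls)
  expect_equal(nrow(cv$accuracy), 3) # one row per held-out trial
  expect_true(all(cv$accuracy > 0.999))
  # fold oracle: refit manually on the two training trials of fold 1
  sc <- cv$feature_scales
  Xs <- lapply(feats, function(f) {
    f$features[[1]] <- f$features[[1]] / sc
    build_lagged_design(f, ls)
  })
  XtX <- Reduce(`+`, lapply(2:3, function(i) as.matrix(Matrix::crossprod(Xs[[i]]))))
  XtY <- Reduce(`+`, lapply(2:3, function(i) {
    as.matrix(Matrix::crossprod(Xs[[i]], t(trials[[i]])))
  }))
  p <- ncol(XtX)
  W <- solve(XtX + diag(c(rep(1e-6, p - 1), 0)), XtY)
  expect_equal(as.vector(cv$fold_models[[1]]$weights[1, , 1]),
               as.vector(W[-p, 1]), tolerance = 1e-10)
  expect_error(crossval_trf(feats[1:2], eeg, 1e-6, ls), "length")
  bad <- feats
  names(bad[[2]]$features) <- "b_onset"
  expect_error(crossval_trf(bad, eeg, 1e-6, ls), "mismatched")
})

test_that("lambda tuning minimizes cross-validated MSE with ties to the smaller value", {
  set.seed(29)
  fs <- 100
  n <- 400
  ls <- lag_spec(fs, 0, 150)
  k <- exp(-((seq_len(ls$n_lags)) - 6)^2 / 18)
  feats <- lapply(1:3, function(tr) {
    x <- numeric(n)
    x[sample(n - 20, 35)] <- 1
    make_fset(list(a_onset = x), fs)
  })
  trials <- lapply(feats, function(f) {
    matrix(stats::convolve(f$features[[1]], rev(k), type = "open")[1:n], 1)
  })
  eeg <- eeg_trials(trials, fs)
  grid <- 10^seq(-6, 6)
  expect_equal(default_lambda_grid(), grid)
  tl <- tune_lambda(feats, eeg, ls, grid)
  # exhaustive oracle
  mse_oracle <- sapply(grid, function(lam) {
    mean(crossval_trf(feats, eeg, lam, ls)$mse)
  })
  expect_equal(unname(tl$mse_by_lambda), mse_oracle, tolerance = 1e-12)
  expect_equal(tl$lambda_opt, grid[which.min(mse_oracle)])
  # noiseless, well-conditioned: bias-only MSE grows with lambda
  expect_equal(tl$lambda_opt, grid[1])
})
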