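test_that("channel selection ranks by accuracy with deterministic ties", {
  sel <- select_channels(c(0.1, 0.9, 0.5, 0.8), k = 2)
  expect_equal(sel$selected, c(2, 4))
  # all equal: first k, deterministic
  expect_equal(select_channels(rep(0.3, 6), k = 3)$selected, 1:3)
  # invariance to reordering up to label mapping
  acc <- c(0.4, 0.1, 0.8, 0.6, 0.2, 0.9)
  perm <- c(3, 1, 6, 2, 5, 4)
  sel_a <- select_channels(acc, k = 2)$selected
  sel_b <- select_channels(acc[perm], k = 2)$selected
  expect_equal(sort(perm[sel_b]), sort(sel_a))
})

test_that("symmetric selection picks the best mirror pairs", {
  layout <- data.frame(x = c(-1, -1, 1, 1), y = c(0, 1, 0, 1))
  # pair (2,4) clearly best by pair mean
  acc <- c(0.2, 0.8, 0.3, 0.7)
  sel <- select_channels(acc, k = 2, symmetry_required = TRUE, layout = layout)
  expect_equal(sel$selected, c(2, 4))
  expect_error(select_channels(acc, k = 3, symmetry_required = TRUE,
                               layout = layout), "even")
  expect_error(select_channels(acc, k = 2, symmetry_required = TRUE), "layout")
  # exhaustive pair-scan oracle on a random symmetric layout
  set.seed(2)
  lay <- default_channel_layout(8)
  a8 <- stats::runif(8)
  sel8 <- select_channels(a8, k = 2, symmetry_required = TRUE, layout = lay)
  pairs <- cbind(1:4, 5:8)
  best <- pairs[which.max((a8[pairs[, 1]] + a8[pairs[, 2]]) / 2), ]
  expect_equal(sel8$selected, sort(best))
})

test_that("cluster test finds no clusters in identical groups and is label-symmetric", {
  set.seed(11)
  a <- matrix(stats::rnorm(10 * 40), 10)
  res <- cluster_permutation_test(a, a, n_perm = 100, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  # relabeling both groups identically leaves results unchanged
  perm_rows <- sample.int(10)
  b <- matrix(stats::rnorm(10 * 40), 10)
  r1 <- cluster_permutation_test(a, b, cluster_alpha = 0.05, n_perm = 200,
                                 seed = 5)
  r2 <- cluster_permutation_test(a[perm_rows, ], b[perm_rows, ],
                                 cluster_alpha = 0.05, n_perm = 200, seed = 5)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$clusters$t_sum, r2$clusters$t_sum, tolerance = 1e-12)
})

test_that("cluster test recovers an injected difference window with valid p bounds", {
  set.seed(21)
  L <- 64
  lag_ms <- seq(0, 500, length.out = L)
  win <- lag_ms >= 180 & lag_ms <= 260
  a <- matrix(stats::rnorm(20 * L, sd = 1), 20)
  a[, win] <- a[, win] + 1.5
  b <- matrix(stats::rnorm(60 * L, sd = 1), 60)
  res <- cluster_permutation_test(a, b, cluster_alpha = 0.001,
                                  corrected_alpha = 0.05, n_perm = 500,
                                  seed = 3, lag_ms = lag_ms)
  sig <- res$clusters[res$clusters$significant & res$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$lag_start_ms <= 260 & sig$lag_end_ms >= 180))
  expect_true(all(res$clusters$p_value >= 1 / (res$n_perm + 1)))
  expect_true(all(res$clusters$p_value <= 1))
  # per-lag t equals a textbook pooled two-sample t at one lag
  li <- which(win)[1]
  t_oracle <- stats::t.test(a[, li], b[, li], var.equal = TRUE)$statistic
  expect_equal(res$t[li], unname(t_oracle), tolerance = 1e-12)
})

test_that("degenerate-variance lags are excluded from cluster formation", {
  set.seed(31)
  a <- matrix(stats::rnorm(6 * 20), 6)
  b <- matrix(stats::rnorm(6 * 20), 6)
  a[, 10] <- 1; b[, 10] <- 1 # zero pooled variance at lag 10
  res <- cluster_permutation_test(a, b, cluster_alpha = 0.5, n_perm = 50,
                                  seed = 2)
  expect_true(10 %in% res$excluded_lags)
  expect_false(any(res$clusters$lag_start <= 10 & res$clusters$lag_end >= 10))
})

test_that("rank-sum test against chance matches expectations", {
  obs <- rep(0.2, 6)
  ch <- rep(0, 6)
  res <- test_vs_chance(obs, ch)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$statistic, 36) # all observed above all chance
  set.seed(3)
  x <- stats::rnorm(8)
  same <- test_vs_chance(x, x)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
})

test_that("model comparisons adjust with BY and report undefined pairs as missing", {
  set.seed(5)
  base <- stats::rnorm(12, 0.2, 0.02)
  accs <- list(word = base - 0.05, phoneme = base,
               `word+phoneme` = base + 0.04)
  res <- compare_models(accs, list(c("word", "phoneme"),
                                   c("phoneme", "word+phoneme"),
                                   c("word", "word+phoneme")))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_true(all(res$p_adj <= 1))
  # BY monotonicity in the raw p ranks
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-15))
  # identical samples are undefined, not significant
  res2 <- compare_models(list(a = base, b = base), list(c("a", "b")))
  expect_true(is.na(res2$statistic))
  expect_true(is.na(res2$p_raw))
  expect_error(compare_models(list(a = 1:3 / 10, b = 2:4 / 10),
                              list(c("a", "b"))), "at least 5")
})
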