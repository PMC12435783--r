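# Group-level statistics: accuracy-ranked channel selection, the
# cluster-based permutation test on attend-vs-ignore difference TRFs,
# rank-sum tests against the chance distribution, and pairwise model
# comparisons with Benjamini-Yekutieli correction.

#' Select well-predicted channels
#'
#' Ranks channels by grand-average prediction accuracy (averaged over trials
#' and subjects upstream). Without the symmetry constraint the top `k`
#' channels are returned (ties broken by channel order). With
#' `symmetry_required`, channels are paired with their left-right mirror in
#' the layout and the top `k/2` pairs by pair-mean accuracy are returned —
#' the analogue of picking bilateral frontotemporal pairs.
#'
#' @param accuracy Numeric vector: grand-average accuracy per channel.
#' @param k Number of channels to select (default 12 = six bilateral pairs).
#' @param symmetry_required Select mirror pairs instead of single channels?
#' @param layout data.frame with `x`, `y` channel coordinates (required for
#'   symmetric selection; mirrors match on `(-x, y)`).
#' @return Object of class `channel_selection`: `selected` (sorted indices),
#'   `ranking`, `k`.
#' @export
select_channels <- function(accuracy, k = 12, symmetry_required = FALSE,
                            layout = NULL) {
  nc <- length(accuracy)
  stopifnot(k >= 1, k <= nc)
  if (!symmetry_required) {
    ord <- order(-accuracy, seq_len(nc))
    sel <- sort(ord[seq_len(k)])
  } else {
    if (k %% 2 != 0) stop("k must be even when symmetry is required")
    if (is.null(layout)) stop("symmetric selection requires a channel layout")
    partner <- mirror_partners(layout)
    left <- which(layout$x < 0)
    pairs <- cbind(left, partner[left])
    pair_acc <- (accuracy[pairs[, 1]] + accuracy[pairs[, 2]]) / 2
    ord <- order(-pair_acc, seq_len(nrow(pairs)))
    top <- pairs[ord[seq_len(k / 2)], , drop = FALSE]
    sel <- sort(as.integer(top))
  }
  structure(list(selected = sel, ranking = order(-accuracy, seq_len(nc)),
                 accuracy = accuracy, k = k,
                 symmetry_required = symmetry_required),
            class = "channel_selection")
}

mirror_partners <- function(layout, tol = 1e-6) {
  n <- nrow(layout)
  partner <- integer(n)
  for (i in seq_len(n)) {
    d <- (layout$x + layout$x[i])^2 + (layout$y - layout$y[i])^2
    j <- which.min(d)
    if (d[j] > tol) stop("channel ", i, " has no mirror partner in the layout")
    partner[i] <- j
  }
  if (any(partner[partner] != seq_len(n))) {
    stop("layout mirror pairing is not mutual")
  }
  partner
}

#' Cluster-based permutation test on TRF waveforms
#'
#' Runs a pointwise two-sample t test (pooled variance) between two sets of
#' waveforms over the lag axis — here, per-subject attend-minus-ignore
#' difference TRFs versus per-permutation chance difference TRFs. Contiguous
#' same-sign supra-threshold runs form clusters scored by their t-value sum;
#' the null distribution is the maximum absolute cluster sum over random
#' relabelings of group membership. The inclusive (+1) permutation
#' convention is used, so p is never zero. Lags with degenerate (zero)
#' pooled variance are excluded from cluster formation and reported.
#'
#' @param group_a,group_b Numeric matrices (waveforms x lags) on the same
#'   lag grid; at least 2 rows each.
#' @param cluster_alpha Cluster-forming two-sided alpha on the pointwise t
#'   (default 0.001).
#' @param corrected_alpha Significance level on the cluster p values
#'   (default 0.001).
#' @param n_perm Number of relabelings (default 2000; raise toward 1e5 for
#'   publication-grade resolution).
#' @param seed Integer seed.
#' @param lag_ms Optional vector of lag times in ms for reporting.
#' @return Object of class `cluster_test`: data.frame `clusters`
#'   (`lag_start`, `lag_end`, `lag_start_ms`, `lag_end_ms`, `t_sum`, `sign`,
#'   `p_value`, `significant`), per-lag `t`, `t_crit`, `excluded_lags`,
#'   `null_max` distribution.
#' @export
cluster_permutation_test <- function(group_a, group_b,
                                     cluster_alpha = 0.001,
                                     corrected_alpha = 0.001,
                                     n_perm = 2000, seed = 1,
                                     lag_ms = NULL) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  stopifnot(ncol(group_a) == ncol(group_b),
            nrow(group_a) >= 2, nrow(group_b) >= 2)
  n1 <- nrow(group_a)
  n2 <- nrow(group_b)
  L <- ncol(group_a)
  df <- n1 + n2 - 2
  t_crit <- stats::qt(1 - cluster_alpha / 2, df)
  tvals <- two_sample_t(group_a, group_b)
  excluded <- which(!is.finite(tvals))
  obs <- find_clusters(tvals, t_crit)
  # permutation null: max |cluster sum| under random relabelings
  Z <- rbind(group_a, group_b)
  Z2 <- Z^2
  N <- n1 + n2
  perm_idx <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) sample.int(N, n1), integer(n1))
  })
  P <- matrix(0, n_perm, N)
  P[cbind(rep(seq_len(n_perm), each = n1), as.vector(perm_idx))] <- 1
  s1 <- P %*% Z
  q1 <- P %*% Z2
  s2 <- matrix(colSums(Z), n_perm, L, byrow = TRUE) - s1
  q2 <- matrix(colSums(Z2), n_perm, L, byrow = TRUE) - q1
  m1 <- s1 / n1
  m2 <- s2 / n2
  ss1 <- q1 - n1 * m1^2
  ss2 <- q2 - n2 * m2^2
  sp2 <- (ss1 + ss2) / df
  tmat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_cluster_sum(tmat[p, ], t_crit)
  }, numeric(1))
  p_value <- vapply(obs$t_sum, function(ts) {
    (1 + sum(null_max >= abs(ts))) / (1 + n_perm)
  }, numeric(1))
  clusters <- data.frame(
    obs,
    lag_start_ms = if (is.null(lag_ms)) rep(NA_real_, nrow(obs)) else
      lag_ms[obs$lag_start],
    lag_end_ms = if (is.null(lag_ms)) rep(NA_real_, nrow(obs)) else
      lag_ms[obs$lag_end],
    p_value = p_value,
    significant = p_value < corrected_alpha)
  structure(list(clusters = clusters, t = tvals, t_crit = t_crit,
                 df = df, excluded_lags = excluded, null_max = null_max,
                 cluster_alpha = cluster_alpha,
                 corrected_alpha = corrected_alpha,
                 n_perm = n_perm, seed = seed),
            class = "cluster_test")
}

two_sample_t <- function(a, b) {
  n1 <- nrow(a)
  n2 <- nrow(b)
  m1 <- colMeans(a)
  m2 <- colMeans(b)
  ss1 <- colSums(a^2) - n1 * m1^2
  ss2 <- colSums(b^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[sp2 <= 0] <- NA_real_
  t
}

# Lean max |cluster t-sum| for the permutation inner loop.
max_cluster_sum <- function(tvals, t_crit) {
  state <- sign(tvals) * (abs(tvals) > t_crit)
  state[is.na(state)] <- 0
  if (!any(state != 0)) return(0)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  best <- 0
  for (i in which(r$values != 0)) {
    s <- abs(sum(tvals[(ends[i] - r$lengths[i] + 1):ends[i]]))
    if (s > best) best <- s
  }
  best
}

# Contiguous same-sign supra-threshold runs; NA lags break clusters.
find_clusters <- function(tvals, t_crit) {
  state <- ifelse(is.na(tvals), 0, sign(tvals) * (abs(tvals) > t_crit))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  data.frame(lag_start = starts[keep], lag_end = ends[keep],
             t_sum = vapply(which(keep), function(i) {
               sum(tvals[starts[i]:ends[i]])
             }, numeric(1)),
             sign = r$values[keep])
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), t_crit = %.3f (df %d), %d permutations\n",
              nrow(x$clusters), x$t_crit, x$df, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Rank-sum test of observed accuracies against chance
#'
#' Two-sided Wilcoxon rank-sum test of the per-subject observed prediction
#' accuracies against the chance-distribution entries.
#'
#' @param observed Numeric vector of per-subject accuracies.
#' @param chance Numeric vector of per-permutation chance accuracies.
#' @return List with `statistic` (rank-sum W), `p_value`, sample sizes.
#' @export
test_vs_chance <- function(observed, chance) {
  stopifnot(length(observed) >= 1, length(chance) >= 1)
  # ties trigger the intended fall-back to the normal approximation
  wt <- suppressWarnings(
    stats::wilcox.test(observed, chance, alternative = "two.sided",
                       exact = NULL, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_observed = length(observed), n_chance = length(chance))
}

#' Pairwise model comparisons with Benjamini-Yekutieli correction
#'
#' Two-sided Wilcoxon signed-rank tests on per-subject accuracy differences
#' for each requested model pair; raw p values are adjusted with the
#' Benjamini-Yekutieli procedure (FDR control under arbitrary dependence)
#' across the declared comparison family. A pair with all-zero differences
#' is undefined and reported as missing.
#'
#' @param accuracies Named list: per model id, a numeric vector of
#'   per-subject accuracies (aligned by subject).
#' @param pairs List of length-2 character vectors of model ids.
#' @return Object of class `model_comparison`: data.frame with `model_a`,
#'   `model_b`, `statistic`, `p_raw`, `p_adj`.
#' @export
compare_models <- function(accuracies, pairs) {
  stopifnot(length(pairs) >= 1)
  n <- unique(vapply(accuracies, length, integer(1)))
  if (length(n) != 1) stop("accuracy vectors must be aligned by subject")
  if (n < 5) stop("need at least 5 paired subjects")
  rows <- lapply(pairs, function(pr) {
    a <- accuracies[[pr[1]]]
    b <- accuracies[[pr[2]]]
    if (is.null(a) || is.null(b)) stop("unknown model id in pair: ",
                                       paste(pr, collapse = " vs "))
    d <- a - b
    if (all(d == 0)) {
      return(data.frame(model_a = pr[1], model_b = pr[2],
                        statistic = NA_real_, p_raw = NA_real_))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided"))
    data.frame(model_a = pr[1], model_b = pr[2],
               statistic = unname(wt$statistic), p_raw = wt$p.value)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_raw, method = "BY")
  class(res) <- c("model_comparison", "data.frame")
  res
}
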