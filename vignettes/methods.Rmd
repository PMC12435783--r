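---
title: "Methods: forward TRFs for selective attention to competing speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward TRFs for selective attention to competing speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A forward (encoding) temporal response function describes the brain's
linear transformation of a stimulus feature into the continuous EEG. For
features $x_f(t)$ (word-onset and phoneme-onset impulse trains, speech
envelope) and channel $c$,

$$\hat{y}_c(t) = b_c + \sum_f \sum_{\tau} w_{f,\tau,c} \, x_f(t - \tau),$$

with lags $\tau$ spanning 0–500 ms, the range in which phoneme- and
word-level speech tracking is expressed. The weights are estimated per
channel by ridge regression on the time-expanded (lagged) design matrix:
$(X^\top X + \lambda I')\,w = X^\top y$, where $I'$ is the identity with a
zero at the bias column, so the intercept is never penalized. The penalty
is the plain identity on lag weights; no smoothness penalty is used — the
canonical reading of "regularized linear regression" in this literature.

Pre-trial stimulus history is zero-padded: row $t$ of the design holds
$x_f(t-\tau)$, with zeros where $t - \tau < 0$. This boundary contract is
fixed so exactness tests are possible.

### Cross-validation and prediction accuracy

Model quality is assessed by leave-one-trial-out cross-validation (six
folds at the default trial count). For each fold the TRF is fitted on the
remaining trials — per-trial covariance matrices are accumulated, so fold
systems are cheap differences — and used to predict the held-out trial.
Prediction accuracy is the Pearson correlation between predicted and
measured EEG restricted to *valid samples*: the union, over every impulse
of every onset-type regressor in the model, of the 0–500 ms window after
that impulse. Onset regressors are sparse, so restricting the correlation
to post-onset windows prevents long stretches where no prediction is
possible from diluting the statistic. The envelope contributes no mask;
for envelope-only models every sample is scored (the preferred convention
is unstated upstream; we record this choice in output metadata). When
several onset features are present the *union* of their windows is used.
A constant masked segment yields an undefined correlation, reported as
missing rather than zero.

### Regularization tuning

$\lambda$ is tuned per subject on a grid of thirteen decades,
$10^{-6}..10^{6}$, minimizing cross-validated MSE averaged across test
trials and channels. MSE is computed on the same valid-sample mask as the
correlation (consistency choice; unstated upstream). Ties go to the
smaller $\lambda$. Tuning uses one combined model containing the word and
phoneme onset regressors of *both* the attended and the ignored stream, so
the selected $\lambda$ cannot be biased by the attention contrast; it is
then frozen for every later stage, including the permutation null.

Because impulse trains and the envelope live on very different scales, each
regressor is standardized to unit pooled variance before fitting (default
on), making a single $\lambda$ meaningful across features; returned TRF
weights are rescaled back to stimulus units. Standardization pools over
all trials of a subject; the leakage this introduces into a fold is a
scale factor only and does not affect the correlation-based accuracy.

### EEG preprocessing

Within this artifact's scope, preprocessing is: zero-phase low-pass at
15 Hz (windowed-sinc FIR, order 100, Hann window, applied
forward-backward) and a single z-score using the mean and standard
deviation pooled over all channels and trials *jointly*. Joint scoring
preserves the relative power across channels, which keeps parameter tuning
comparable across datasets. Artifact attenuation (ASR), re-referencing and
electrode interpolation are upstream concerns and out of scope here.

## The permutation null

Chance levels for accuracies and TRFs come from refitting on shuffled
onset regressors that preserve all duration statistics. "Rearranging word
onsets and the corresponding phoneme onsets" is implemented as a timeline
rebuild: each word unit — its duration, its internal phoneme onsets, and
the silent gap that follows it — is kept intact; the movable units are
reordered by a uniform random permutation and onsets are re-derived by
cumulative summation from the original first onset. The trial-final word
keeps its position, which makes the inter-onset-interval multiset exact
(its "following gap" does not exist and would otherwise leak into the
multiset). Under this scheme the multisets of word durations, word
inter-onset intervals and within-word phoneme offsets are all preserved —
the permuted regressors have identical word and phoneme rate statistics —
while the onset *times* genuinely move, the total span is unchanged, and
the permuted tiers remain non-overlapping and valid.

The design alternative of permuting word units across a *fixed* grid of
original onset slots also preserves every interval multiset, but it leaves
the word-onset impulse train bitwise unchanged: the chance distribution of
a word-only model would degenerate to a point mass at the observed
performance, which contradicts the reported behaviour of these nulls
(chance visibly below observed for every model). It was therefore
rejected. Permutations are unique by rejection sampling over a hash set
(default 100). The envelope, when present in a model, is left intact — only onset
regressors are permuted — and this is flagged in output metadata.
$\lambda$ and the channel selection are frozen before permutation, never
re-tuned per permutation.

Per permutation, every subject is refit and scored, and results are
averaged across subjects, giving one grand-average accuracy and one
grand-average channel-averaged TRF per permutation and condition.

## Group statistics

**Channel selection.** Prediction accuracies from the combined
attended+ignored word+phoneme model are averaged over trials and subjects,
and the best channels are picked from that grand average — by default six
bilateral mirror pairs (k = 12) when a layout is available, otherwise the
top-k channels with ties broken by channel order. TRFs and accuracies
entering the group statistics are first averaged over the selected
channels per subject.

**Attend vs ignore (cluster test).** Per lag, a two-sample t statistic
(pooled variance; the degrees-of-freedom convention is recorded in the
result) compares (a) the $n$ per-subject difference TRFs (attend − ignore)
against (b) the per-permutation grand-average chance difference TRFs,
treated as independent samples of unequal size by design. Contiguous
same-sign runs exceeding the cluster-forming threshold (two-sided
α = 0.001) form clusters scored by their t-sum; the null is the maximum
absolute cluster sum over random relabelings of group membership
(default 2,000 at desk scale, configurable up to the publication-grade
100,000 — the estimator is identical, only resolution changes). The
inclusive (+1) convention makes p never zero. Lags with degenerate
variance are excluded from cluster formation and reported.

**Against chance.** Two-sided Wilcoxon rank-sum tests compare per-subject
observed accuracies with the chance entries (α = 0.05). The upstream
description is ambiguous about whether per-subject accuracies or the
single observed grand average entered this test; per-subject is the
default here, and the grand-average variant is a one-liner on the stored
outputs.

**Between models.** Word, phoneme and word+phoneme models (each ± the
envelope regressor, fitted separately per attention condition) are
compared pairwise by two-sided Wilcoxon signed-rank tests across subjects,
with Benjamini–Yekutieli adjustment (FDR control under arbitrary
dependence) across the declared comparison family. All-zero difference
vectors are undefined and reported as missing.

## The synthetic world

The generator exists so that every stage is testable against known ground
truth without any external data. It emulates the recorded paradigm's
structure, not its physiology:

- **Annotations.** Words tile each trial with log-normal durations
  (per-stream medians 290 ms and 270 ms — the reported stimulus medians —
  dispersion 0.45 on the log scale, a typical right skew for speech units)
  separated by optional silent gaps, uniform on [0, 500 ms] with
  probability 0.3; 500 ms is the cap the stimulus material enforces.
  Phoneme counts per word are categorical (means ≈ 3.7 and 4.0 per
  stream, calibrated once so the phoneme-duration medians land near the
  reported 70 ms and 60 ms) and phoneme durations stick-break the word
  interval with Dirichlet(5) weights. The first phoneme onset equals the
  word onset exactly, matching the annotation convention that a word's
  first phoneme is the word onset.
- **Envelope.** Hann-windowed bursts (120 ms) at phoneme onsets with
  independent gamma-distributed amplitudes plus a small positive floor.
  The random amplitudes matter: they give the envelope information that is
  not a linear function of the impulse trains, keeping the three-feature
  generative model identifiable.
- **Kernels.** Per feature, a sum of three Gaussian lobes — positive at
  60 ms, positive at 220 ms, negative at 350 ms — echoing P1/P2/N2
  morphology, with a smooth frontotemporal channel profile on a bilaterally
  symmetric layout. Lobe amplitudes are free parameters (the recorded data
  constrain morphology, not amplitude); defaults set word ≥ phoneme ≥
  envelope amplitudes.
- **Attention.** Attended-stream kernels are scaled by `attend_gain`
  (default 1.0), ignored by `ignore_gain`. No ground truth exists upstream
  for how much ignored-stream response survives, so `ignore_gain` is a free
  parameter; the default 0.5 encodes "attenuated but present", consistent
  with the qualitative finding that ignored-stream tracking is reliable but
  weaker.
- **Noise.** Spatially independent $1/f$ noise per channel, scaled so the
  pooled signal-to-noise variance ratio matches `snr_db` exactly (default
  0 dB). There is no channel covariance, no eye/muscle artifact, and no
  acoustic realism — a green test therefore establishes algorithmic
  correctness and statistical calibration, not robustness to structured
  artifacts. With all-zero kernels (used by the null-calibration tests) no
  SNR can be satisfied and the output is pure unit-variance noise.

Desk scale defaults to 20 subjects × 6 trials × 60 s at 16 channels,
scaled down from the recorded 6 × 10 min × 94 channels. Identical
configuration and seed reproduce every output bit for bit; all stage
sub-seeds derive from one master seed.

## Numerical choices

- Onset-to-sample mapping is round-half-up of `onset × fs`, 0-based,
  trial time starting at 0 s; collisions keep a binary 1 (regressors code
  event presence, not count).
- The envelope is |analytic signal| → zero-phase order-4 Butterworth
  low-pass at 8 Hz at the audio rate → resampling to the EEG rate
  (decimation for integer ratios; linear interpolation otherwise, which is
  exact to well below filter ripple for content already band-limited at
  8 Hz). Small negative ripple after filtering is left in place. No DSP
  dependency is available in the target environment, so the Butterworth
  design (bilinear transform with prewarping) and zero-phase application
  (odd-reflection padding, forward–backward) are implemented here and
  tested against closed-form frequency-response oracles.
- `lambda = 0` is refused (the normal equations may be singular);
  the error points to the grid.
- Ridge solves use one Cholesky-backed `solve` per fold for all channels
  at once; designs are sparse matrices, which makes onset-only models
  essentially free and mixed models dominated by the envelope block.

## Known limitations

- The cluster test's two groups (subjects vs permutation averages) are
  treated as independent samples; permutation grand averages have smaller
  variance than single subjects by construction, which is exactly the
  contrast the upstream analysis defines, but it means the t statistic is
  not comparing like with like in the usual two-sample sense.
- EDF import is not provided (no reader available offline); real EEG
  enters via the documented CSV + JSON-sidecar container. The TextGrid
  reader covers only the minimal two-tier interval dialect that forced
  aligners emit.
- Synthetic subjects share kernel morphology up to channel scaling;
  between-subject variability enters only through stimulus and noise
  realizations, so group-level effect sizes are optimistic relative to
  real cohorts.
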