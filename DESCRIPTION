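Package: speechtrf
Title: Forward Temporal Response Functions for Selective Attention to Competing Speech
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates forward temporal response functions (TRFs) from word-onset,
    phoneme-onset and speech-envelope regressors by lagged ridge regression with
    leave-one-trial-out cross-validation, scoring prediction accuracy on valid
    post-onset samples only. Includes a duration-preserving permutation null for
    onset regressors, cluster-based permutation statistics for attend-vs-ignore
    TRF differences, rank-based model comparisons with Benjamini-Yekutieli
    correction, and a synthetic competing-speaker EEG generator with known
    ground-truth kernels and attention gain for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
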