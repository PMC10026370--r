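Package: replaydmn
Title: Replay-Evoked Default Mode Network Coupling Analysis for MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual-decoding analysis of resting magnetoencephalography (MEG):
    sparse logistic decoding of task-state reactivation, detection of
    spontaneous replay events as lagged pairwise reactivation, temporally
    delayed linear modelling (TDLM) of sequenceness, time-delay-embedded
    hidden Markov model (TDE-HMM) inference of resting-state network
    activation, transition-specific replay-evoked coupling regression with
    pre/post-learning contrasts and evoked-response PCA, stimulus-evoked
    network modulation, and non-parametric max-statistic permutation tests
    with family-wise error control. Includes a synthetic cohort generator
    with known ground truth (sensor patterns, replay onsets, Markov network
    states, planted replay-network coupling) so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
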