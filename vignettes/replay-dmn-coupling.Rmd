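---
title: "Dual decoding of replay and network states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual decoding of replay and network states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replaydmn)
```

## The analysis in one paragraph

During rest, the brain spontaneously reactivates sequences of task states
("replay"), and these reactivations tend to fall inside activation windows
of the default mode network (DMN). `replaydmn` implements a dual-decoding
analysis of resting MEG that quantifies this coupling and asks whether it
differs between groups: per-state sparse logistic classifiers decode a
state-reactivation probability time course from rest data; lagged pairwise
products of those time courses give per-transition replay evidence, whose
99th-percentile crossings define replay onsets; in parallel, a
time-delay-embedded hidden Markov model (TDE-HMM) decodes a K = 12
network-state activation time course, one state of which is DMN-like.
Epoching the (column-centred) network activation from −500 to +500 ms
around replay onsets, separately for each of the 64 ordered state pairs,
and regressing the 64 per-transition evoked values at each peri-event time
point on an indicator of task-relevant (structurally adjacent) transitions
plus an intercept yields `beta_inferred` (task-relevant coupling) and
`beta_nonspecific` (background coupling). The post-learning minus
pre-learning contrast `delta_beta_inferred` is the quantity of interest;
non-parametric sign-flip and group-membership permutation tests with a
max-statistic correction over peri-event time provide family-wise
error-controlled inference.

Because the clinical recordings this pipeline is designed for are not
redistributable, the package ships a synthetic-data generator with full
ground truth, so every stage — and the pipeline end to end — is testable.

## The model components

### Decoding state reactivation

One L1-penalised logistic classifier per task state is trained on the
sensor vector observed a fixed latency after each localizer trial onset
(default 180 ms, selectable by cross-validated decodability via
`select_training_time()`; ties go to the earlier latency). One-vs-rest
negatives are the other states' trials plus an equal number of
inter-trial "null" samples; null negatives lower the rest-state baseline
of all eight probabilities and reduce spatially correlated false
reactivations. Channels are z-scored with localizer statistics and the
same transform is applied to rest data, aligning feature scales across
sessions. Applying the weights sample-by-sample gives
`probs[t, s] = sigmoid(beta_s . [x_t; 1])` — no temporal smoothing.

### Replay evidence, onsets, sequenceness

For the ordered pair (i, j), evidence is
`R_t = probs[t, i] * probs[t + tau, j]` with tau = 40 ms (4 samples at
the 100 Hz analysis rate). The onset threshold is the transition- and
session-specific 99th percentile of the full evidence series (linear
interpolation between order statistics; comparison strictly greater, so a
constant series yields no onsets). Every suprathreshold sample counts as
an onset; an optional run-collapse mode keeps only each run's evidence
peak for sensitivity analyses. Onsets too close to a session edge to be
epoched are excluded at detection time. The percentile is computed before
edge exclusion — the threshold describes the session's evidence
distribution, the edge rule only describes usability.

Sequenceness uses temporally delayed linear modelling: at each lag the
8 × 8 matrix of lagged-influence coefficients is estimated by regressing
each state's series jointly on all lag-shifted series, then that matrix is
regressed on the forward-transition template, the backward template, the
identity and a constant. The identity regressor absorbs self-transitions,
so the templates (zero on the diagonal) are fitted on between-state
structure only. `replay_strength()` — the post- minus pre-learning forward
coefficient at 40 ms — serves as a per-participant covariate.

### Network states

The TDE-HMM observation model is a zero-mean Gaussian per state over the
time-delay-embedded (default lags ±7 samples), PCA-reduced (default
`min(2 * channels, 48)` components) and standardised signal, so each
state's covariance captures a spatial *and* spectral signature. Inference
is two-step, as is standard when a well-characterised reference data set
exists: `fit_hmm()` estimates observation models, transition matrix and
initial distribution on reference sessions by EM (scaled forward-backward
E-step, closed-form M-step, several seeded restarts); `infer_states()`
then freezes the observation models *and* the transition matrix and runs
forward-backward on each study session. Freezing the transitions keeps
all sessions on an identical model; a per-session re-estimation mode
exists but is off by default, since the coupling analysis consumes
posteriors, not transitions. Posteriors at the embedding-trimmed edges
are padded by repeating the nearest inferred row so the activation matrix
aligns sample-for-sample with the recording. Covariances get a 1e-6 ridge
for numerical stability; EM stops on a relative log-likelihood change
below `tol` and warns (returning the best fit) if `max_iter` is reached —
with K = 12 on desk-scale reference data the likelihood is effectively
flat long before formal convergence, so these warnings are expected and
harmless at the sizes used in the tests.

On synthetic data the DMN-like state of a fitted model is identified by
maximal correlation with the generator's ground-truth DMN occupancy
(`identify_dmn(..., "by_ground_truth")`; a tie within 1e-6 is an error,
not a silent pick). For real recordings a `by_power_profile` mode ranks
states by relative power over a channel-to-region map.

### Coupling regression and PCA

`epoch_evoked()` averages the centred activation over all of a
transition's onsets; transitions with no onsets are dropped listwise from
the regression (their count is recorded). With the indicator + intercept
design, ordinary least squares has the closed form
`beta_inferred = mean(inferred) − mean(non-inferred)` and
`beta_nonspecific = mean(non-inferred)` — the implementation solves the
normal equations for all (time × state) cells at once and the closed form
serves as the test oracle. Self-pairs (i → i) are kept in the 64-row
enumeration, as the 8 × 8 count implies, but never carry the indicator;
the indicator marks the 6 forward structural adjacencies by default (a
flag adds the 6 reversals — forward-only is the default because the
phenomenon being modelled is forward replay at 40 ms).

The complementary PCA stacks every (participant, session, transition)
vectorised [time × state] evoked response over the whole cohort,
column-centres, and eigendecomposes, so the projection is identical for
all participants and sessions. PCs are sign-indeterminate; PC-1 is
oriented so the DMN loading at 0 ms is positive. Per participant and
session the 64 PC-1 scores are regressed on the same design, giving
`beta_inferred[PC]` and its session contrast. The stimulus-locked
analysis mirrors this machinery around localizer stimulus onsets; its PC
is sign-aligned to the rest-derived PC by the sign of the loading
correlation (the alignment operation is an interpretation — only "aligned"
is specified upstream — and is flagged as such). A simpler deactivation
score, mean DMN activation in (−500, 0] minus (0, +500] ms, is computed
alongside.

### Permutation inference

One-sample inference uses subject sign flips of whole effect time courses
(flipping whole rows preserves within-subject autocorrelation, which the
max-statistic correction over time requires); two-sample inference
permutes group labels preserving group sizes, with a pooled-variance t
(df = n1 + n2 − 2). The family-wise peak-level p-value is the add-one
Monte-Carlo estimate `(1 + #{null max >= observed peak}) / (n_perm + 1)`,
never zero, with max t for right-tailed and max |t| for two-tailed tests.
Permutations are Monte-Carlo with a recorded seed (exhaustive enumeration
is not attempted even for small strata). `residualize()` removes
covariate-explained variance (e.g. replay strength) per time point before
a group test; `assoc()` gates Pearson vs Spearman on Shapiro-Wilk
normality at alpha = 0.05, and `covariate_regression()` is plain OLS with
t-based p-values for, e.g., diagnosis + medication-dose models.

## The synthetic generator: what it emulates, and what it does not

`synth_config()` fixes the study conditions: 100 Hz analysis rate (so
tau = 40 ms is exactly 4 samples), 8 task states forming two 4-state
structural sequences with 6 forward adjacencies, replay events on all 64
ordered pairs, K = 12 network states with state 2 DMN-like, and a
controllable coupling between task-relevant replay onsets and DMN
occupancy that is present only in POST sessions (PRE forces it to zero;
a separate `baseline_coupling`, default 0 since no magnitude is
established for it, applies to all pairs equally).

Generative choices worth knowing:

* **Replay events** are single-sample pulses of the state's sensor
  pattern convolved with a 20 ms half-sine kernel, state i at the onset
  and state j one lag later; amplitude `pattern_snr` (default 5) against
  unit-variance channel noise. Events are scheduled with non-overlapping
  coupling windows and 500 ms epochable margins.
* **Network states** follow a first-order Markov chain (uniform
  stationary law, mean dwell 200 ms). Each state adds a rank-2 signature
  on state-specific orthonormal channel directions whose factors are
  AR(1) in time (coefficient 0.7, variance 6): temporally structured,
  band-limited signatures are what a time-delay embedding can detect, and
  white instantaneous ones are not. The signature directions are drawn
  under a separate `network_seed` shared across a cohort, because real
  resting-state networks are common across brains — this is what lets one
  reference-fitted HMM transfer to every participant.
* **Ground-truth activation** is a softened one-hot law
  (`1 − soft_eps` on the chain state, `soft_eps / K` elsewhere,
  `soft_eps = 0.15` to leave headroom for the boost). The coupling adds
  exactly `coupling_amplitude` to the DMN column at onset, with a
  raised-cosine profile over ±`coupling_window_ms` (a boxcar profile is
  available; the raised cosine is the default because the evoked coupling
  this models is a transient peaking at onset, which is also what makes
  "peak within the window" a meaningful recovery question). The other
  columns are rescaled so rows still sum to one and the DMN increment is
  exact. The sampled state path realizes the boost as short DMN visits
  (mean `dmn_visit_ms`, centred on their trigger) whose hazard integrates
  to the planted increment — coupling acts on the soft law, not by
  forcing a Viterbi path.
* **Localizer trials** add the state pattern under a half-sine envelope
  peaking at 180 ms (duration 360 ms), plus a transient DMN occupancy
  reduction in the 500 ms after each stimulus (task-induced
  deactivation).

Not emulated: source anatomy and head models, 1/f background and
oscillatory rhythms beyond the AR(1) factors, artifacts (cardiac, ocular),
behaviour. Passing tests therefore show the *inference logic* is correct
and well-calibrated under a known generative model — they do not show
robustness to real MEG noise structure, preprocessing choices, or source
reconstruction, which are upstream of this package's scope.

## Cohort defaults and the a-priori power calculation

`run_config()` uses desk-scale defaults: 32 channels, 100 s rest
sessions, 8 events per ordered pair, coupling window ±50 ms, planted
amplitude 0.4 for the coupled ("control-like") group and 0 for the
uncoupled ("patient-like") group, HMM with lags ±3 and 24 PCs fitted on
3 reference sessions, 500 permutations. Two of these deserve
justification, because the percentile-based onset definition makes
effect sizes scale in a way that is easy to get wrong:

* With a 99th-percentile threshold, the number of detected onsets per
  transition is ~1% of the session length regardless of how many events
  were planted, so the planted effect is diluted by the ratio of true
  suprathreshold samples (≈ 3 per event, the pulse-kernel width) to all
  suprathreshold samples. Packing 8 events per pair into 100 s with
  ±50 ms windows puts that ratio near 25%; sparser schedules (or longer
  sessions) *reduce* the recoverable effect.
* Stage-wise measurements under the generator give a per-participant
  `delta_beta_inferred[DMN]` noise SD of about 0.012 through the full
  decode + HMM chain, and an HMM attenuation of roughly one half relative
  to the ground-truth activation route. An amplitude of 0.4 then yields a
  per-participant effect of ~0.02, i.e. a between-group Cohen's d above
  1.5, for which n = 15 + 15 exceeds 90% power at the max-statistic
  corrected alpha = 0.05 — while an amplitude of 0.1 (kept as the
  `synth_config()` default, and used for the amplitude-recovery check
  against ground truth) would leave an end-to-end cohort of this size
  underpowered.

Null-calibration replicate cohorts use n = 5 per group and 60 s sessions
with a single shared reference model: type-I behaviour does not depend on
those sizes, and the two-step scheme explicitly licenses reusing one
reference fit. The problem sizes above are also the ones the acceptance
script runs.

## Numerical conventions and degenerate inputs

* Percentile: linear interpolation (R type 7); strictly-greater
  comparison; constant evidence gives zero onsets.
* Forward-backward: scaled recursions with a per-sample log-shift,
  compiled; posteriors match exhaustive path enumeration to 1e-10 on
  small instances (a brute-force enumerator is kept in the test suite as
  the independent oracle).
* EM: non-decreasing log-likelihood per iteration (tested to numerical
  jitter); seeded random-responsibility initialisation with restarts;
  covariance ridge 1e-6.
* Ties: training-latency selection breaks ties toward the earlier
  latency; DMN identification refuses to break correlation ties.
* Missing transitions (no onsets) are dropped listwise per session and
  counted; a session with only one design level present is a rank error,
  not a silent fit.
* Determinism: every generator and every permutation test takes an
  explicit seed; identical configurations give bit-identical output.

## Known limitations

* The HMM uses maximum-likelihood EM, not variational Bayes with
  conjugate priors; with K = 12 and short reference data the likelihood
  surface is flat and different restarts can end in different local
  optima — acceptable here because the coupling analysis is driven by the
  DMN-like state's posterior, which is stable across restarts at the
  default signature strength.
* Replay detection is pairwise at a single lag; multi-step sequences and
  cross-validated decoder-shift controls are out of scope.
* The stimulus-PC alignment to the rest PC is correlation-based sign
  alignment only, an interpretation of "aligned" that is deliberately
  minimal.
* Spectral summaries (`state_spectra()`) are a plain state-masked Welch
  average, reported as a diagnostic and unused downstream.
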