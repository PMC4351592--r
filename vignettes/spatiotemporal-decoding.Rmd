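---
title: "Methods: ensemble rate statistics, resampled decoding, and session trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble rate statistics, resampled decoding, and session trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The task and the data model

A subject self-starts each trial by pressing a ready lever; a left or
right light cue comes on at that same moment, the two response levers
extend 2 s later, and the first response press decides the trial. Trials
are labelled by cue side and first press side: `L-L` and `R-R` are
correct directional trials, `L-R` and `R-L` errors (cue named first).
Lateral cue positions (`LL`/`L`, `RR`/`R`) collapse to a side; center-cue
trials are not directional-choice trials and are rejected by
`classify_trial()`. Only the *first* response press enters the analysis;
later presses within a trial are ignored.

A session bundles the trials table, one spike-time vector per unit, the
session index, and two derived quantities: the behavioral accuracy
(successes over all trials) and the inclusion flag. A session enters
analysis only with at least 20 `L-L` **and** 20 `R-R` trials
(`filter_sessions()`), which screens out early sessions where too few
correct trials exist for stable resampling.

The analysis windows are a fixed catalog (`window_catalog()`), all
half-open `[start, end)` in ms: `BC` `[-500, 0)` before cue onset; the
cue-on window `CO` `[300, 1800)`; its 500 ms sub-windows `CO1`–`CO3`
(`[500,1000)`, `[1000,1500)`, `[1500,2000)`); and `LP` `[-100, 400)`
around the first response press. Half-open intervals everywhere mean a
spike on a boundary belongs to the later bin and is never counted twice.
The placement of the 500 ms baseline window immediately before cue onset
(`[-500, 0)`) and the pooling of both lateral cue positions into one side
are the package's reading of the task; both are fixed in the catalog and
documented rather than configurable.

## Firing-rate statistics

Single-trial rates use a 100 ms boxcar sliding at 20 ms steps
(50 estimates/s). Windows are centered on the grid
`start + step/2, start + 3 step/2, ...`; with `step == bin_width` the
windows partition the interval and counts conserve total spikes (a
tested invariant). The window-mean rate of a trial is the average of all
sliding-bin rates inside the window — the slightly redundant
sliding-bin definition is kept deliberately (rather than a single
window count) because it is the same estimator the PETHs use; the two
agree in expectation.

Per unit and session, `unit_and_ensemble_summary()` computes class means
`M_L`, `M_R`, their average `M`, the signed difference `D = M_L - M_R`,
and across-trial standard deviations `S_L`, `S_R` (sample, n−1, because
session trial counts are small). The ensemble summary averages over
units, with `D(k)` the mean of *absolute* per-unit differences — two
units tuned to opposite sides give `D(k) > 0` even though the signed
mean difference cancels. `time_resolved_difference()` pools the signed
per-record (unit × session) difference series and t-tests each bin
against zero; note that for multi-unit ensembles with balanced opposite
tuning the *signed* pooled difference cancels by construction, so onset
localization is meaningful for pooled records sharing a net preferred
side (the test suite uses single-unit sessions for this check).

## The decoding protocol

Each trial's sample is a spike-count vector: non-overlapping bins tile
the window (3 × 500 ms for CO), counts are taken per unit and
concatenated unit-major in ascending unit-id order, fixed across
sessions. Bin sizes must divide the window length; a trailing remainder
is dropped only on explicit request (`truncate = TRUE`) and the result
flags it.

Per session, `decode_session()` trains `n_repeats = 100` classifiers.
Each repeat:

1. draws `trials_per_class` trials per class — the default is the
   *minimum* class count, keeping every repeat class-balanced while using
   the maximum balanced amount of data;
2. holds out `ceiling(0.2 * trials_per_class)` per class as test trials
   (ceiling guarantees at least one test sample per class);
3. forms training samples as means of `n_average = 5` same-class raw
   vectors drawn *without replacement* per sample, producing as many
   training samples per class as there are raw training vectors — this
   keeps the training-set size comparable to the raw set while the
   averaging suppresses single-trial Poisson noise;
4. fits a linear-kernel SVM (`e1071::svm`, C-classification, default
   cost 1.0, no feature scaling) or LDA (`MASS::lda`), and
5. tests on the held-out *single-trial* vectors.

The decision function is kept in explicit linear form
`df(x) = w . x + b` with the convention `df >= 0` → first class (L-L);
for SVM fits the support vectors and weights are retained so the kernel
form can be verified against the expansion (a tested invariant at
1e-9). The session's accuracy is the unweighted mean over repeats of
pooled test accuracy; the class distance is the difference of class-mean
`df` values of test samples pooled over all repeats (pooling, rather
than averaging per-repeat distances, uses every test sample once and is
the simpler estimator).

Reproducibility: repeat `r` derives its subseed as
`(seed * 613 + r) mod (2^31 - 1)`; the label shuffle of
`shuffle_control()` uses its own stream (offset `1000003`), so a
shuffled run shares its trial draws with the unshuffled run under the
same seed. Repeats draw independently (with replacement *across*
repeats), so the same trial can serve as test in one repeat and training
in another — repeats are therefore correlated, and the per-session mean
accuracy has more spread than a binomial count would suggest; chance
controls are evaluated across independently simulated sessions for that
reason.

Degenerate fits are handled conservatively: if the SVM cannot be fit
(e.g. all-identical samples) or LDA has no non-constant feature, the
decoder falls back to `w = 0, b = 0`, classifying everything as the
positive class — 50% on balanced test sets.

The controls reuse the same protocol: `single_unit_decoding()` restricts
features to one unit's sub-vector; `bin_size_sweep()` varies the CO bin
size over divisors of 1500 ms; `single_bin_time_course()` tiles the 2 s
cue-on period with 100 ms bins (feature dimension = ensemble size);
`ensemble_size_curve()` averages over random unit subsets drawn without
replacement; `error_trial_decoding()` decodes a correct class against
the error class with the same choice side, and reports ineligibility
below 20 trials per class instead of running.

## Session trends

Session indices are mapped affinely onto `[0, 1]`
(`normalize_sessions()`), measures are Z-scored per subject (sample SD)
before pooling, and `slope_with_ci()` fits OLS with the slope CI from
its standard error and the t-distribution. The sign call is read off the
99% interval: positive if the lower bound exceeds zero, negative if the
upper bound is below zero, zero otherwise. A zero-residual fit yields a
zero-width interval rather than `NaN`. The call is invariant under
positive rescaling of the response, so Z-scoring cannot flip it.

`stage_summary()` splits sessions into three contiguous stages; when the
count is not divisible by three the extra sessions go to the *last*
stage(s) — a deterministic rule chosen once. Stage pairs are compared by
one-way ANOVA; for two groups this is exactly the two-sample t-test
(F = t²), so only one implementation exists. `slope_comparison()` tests
slope equality through the interaction term of the pooled model
`y ~ x * series` (ANCOVA). `accuracy_vs_behavior()` regresses each
subject's decoding accuracy on its fraction of correct-choice trials and
t-tests the subject slopes against zero; pooling across subjects is
unweighted (no weighting by session count).

## The synthetic generator

The generator emulates the statistical structure of the study, not its
biophysics. Rates are piecewise constant on 100 ms panels spanning
−1000 to +3500 ms around cue onset; spikes are direct Poisson counts per
panel with uniform placement (exact and fast at this scale — no
thinning). Defaults are the study conditions: 4 units (observed range
3–6), 57 correct trials per class per session, 18 sessions, 10 Hz
baseline, class separation `d(k)` of order 2–3 Hz, and directional
modulation switching on 400 ms after cue onset.

- **Learning curve** (`make_learning_curve()`): a saturating exponential
  pinned exactly at the session-1 and final accuracies (defaults 30.8%
  and 76.0%), curvature 3 — smooth, monotone, two parameters. Response
  latency falls linearly over the first three sessions (0.44 s to
  0.32 s) and is constant from session 4; per-trial latencies are
  normal around the session mean (SD 0.15 s, truncated to
  [0.05, 0.99] s so every press falls inside the 1 s response window).
- **Error trials**: with the session accuracy `a`, the generator adds
  `round(2 * trials_per_class * (1 - a)/a)` trials whose first press
  opposes the cue, yielding `L-R`/`R-L` trials and a realized accuracy
  matching the curve. `error_tuning` decides whether error-trial spike
  rates follow the *chosen* side (default; error trials then share the
  choice pattern of correct trials) or the *cue* side — the two regimes
  bracket the correct-vs-error decoding control.
- **`rate_offset` mode**: after the onset, half the units fire more on
  left-choice trials and half on right-choice trials, with the amplitude
  scaled so the per-unit CO-window mean class difference equals `d(k)`
  exactly (the onset at 400 ms eats into the CO window, so the
  post-onset amplitude is `d * 1500/1400`).
- **`pattern_rotation` mode**: within the post-onset part of the CO
  window, each unit's class difference is `+d/2` for the first half of
  the panels and `-d/2` for the second half (sign alternating across
  units). Every unit's CO-window mean difference is zero, so 1-D
  mean-rate decoding carries no signal, while the 500 ms-binned
  spatiotemporal vectors separate with strength `d` — the flat-rate /
  rising-pattern regime.
- **Mean conservation**: in both modes `(lambda_L + lambda_R)/2` equals
  the baseline everywhere, so with `mean_conservation = TRUE` the
  ensemble-average rate is analytically identical across sessions;
  switching it off applies a deterministic 20% linear baseline drift.
- **Seeds**: one master seed; session `k` uses
  `(seed * 1009 + k) mod (2^31 - 1)`, so any session is reproducible in
  isolation.

What the generator does **not** emulate: refractoriness or any
spike-history dependence, correlated noise across units or trials,
within-session nonstationarity, multi-press trial structure, and
movement kinematics beyond the scalar latency. Passing tests therefore
show that the *pipeline* recovers the structure it is pointed at under
Poisson variability — not that real motor cortical data has that
structure. The per-session growth schedule `d(k)` is a free parameter
(the linear 0–6 Hz ramp used in tests is a convenient choice), not an
estimate of any empirical effect size.

## Problem sizes and numerical choices

The test suite runs desk-scale versions of every analysis: sessions of
40–60 trials per class with 1–4 units, 30–100 protocol repeats,
20-seed chance batteries, a 21-session dissociation experiment, 1000
brute-force oracle cases, and 1000-draw CI calibration — all chosen to
give stable Monte-Carlo margins at interactive runtimes. Tolerances in
tests reflect the estimators' own noise (binomial bands for accuracies,
3-SE bands for Poisson means), not tuned constants.

Interchange files are plain text: trial event times as integer ms,
spike times with three decimals (sub-ms), both for diff-able,
byte-stable round trips. `read_session()` re-validates everything
(timeline consistency, sorted spikes, schema version) and reports the
offending row on failure.

## Known limitations

- The pooled trend regressions treat unit-session records and
  subject-sessions as independent samples (as the analysis convention
  dictates); a mixed-effects layer would be the natural extension.
- Only linear decision rules are implemented (linear SVM, LDA) — by
  design: the point of the protocol is discriminability of the
  representation, not classifier engineering.
- The ANCOVA slope comparison assumes shared covariate values for both
  series; unequal designs are out of scope.
- `single_bin_time_course()` and the bin-size sweep inherit the
  protocol's correlated-repeat caveat; their values are comparable
  within a session but are not unbiased estimates of out-of-session
  generalization.
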