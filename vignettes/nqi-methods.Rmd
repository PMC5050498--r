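---
title: "The nQi pipeline: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nQi pipeline: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroqwerty)
```

## The signal and its model

The package treats the keyboard as a passive motor probe. Every key press
and release is timestamped; the *hold time* of a key — release minus press,
typically near 100 ms for fluent typists — is a repeated measurement of a
fast, largely automatic motor program. The working hypothesis is that early
Parkinsonian motor impairment shows up not as a shift in typical hold time
but as *dynamic variance*: transient episodes in which hold times become
noisier and heavy right tails appear, superimposed on otherwise normal
typing.

Only keys with an expected short hold enter the signal: letters, digits,
printable symbols, and the space bar. Modifier, navigation, editing and
function keys (`shift`, `ctrl`, arrows, `enter`, `backspace`, ...) are held
deliberately and are excluded. Whether backspace should count as an
eligible "symbol" is debatable; we exclude it because its hold reflects
correction behaviour rather than motor timing, and `compute_hold_times()`
takes an `eligible` argument for users who want it back in.

## Windowing and features

The hold-time series is cut into non-overlapping windows of
`window_seconds = 90` s, half-open `[i·90, (i+1)·90)` and anchored at the
first retained key press (`t = 0`); assignment uses the press time only, so
a hold may extend past its window boundary. Typing is bursty, so windows
covering pauses are sparse: windows with fewer than `min_samples = 30`
(one third of the window length in seconds) hold times are discarded
rather than padded.

Each retained window yields seven features, in fixed order:

| feature | definition | units / range |
|---|---|---|
| `v_out` | fraction of holds beyond 1.5 IQR below q1 or above q3 | [0, 1] |
| `v_skew` | (q2 − q1) / (q3 − q1) | [0, 1] |
| `h1..h4` | normalized histogram, 4 equal bins over [0, 0.5) s | [0, 1] each |
| `v_de` | mean clamped overlap of consecutive keystrokes | seconds ≥ 0 |

Numerical conventions, chosen where the definitions are silent:

* **Quartiles** use linear interpolation between order statistics (the
  type-7 rule, R's default). Any consistent rule would do; one rule is used
  everywhere, including the test oracles.
* **Degenerate skewness** (`q3 == q1`, e.g. a constant window) returns the
  symmetric value 0.5, flagged via an attribute, instead of NaN.
* **Histogram normalization** divides by *all* samples in the window, not
  only in-range ones, so holds ≥ 0.5 s reduce the bin sum below 1 rather
  than silently vanishing. Holds ≥ 0.5 s still participate in `v_out` and
  `v_skew`.
* **`v_de` aggregation**: the per-pair overlap `release₁ − press₂` (clamped
  at 0) is averaged over all consecutive pairs in the window. The mean
  keeps seconds as units and is invariant to window sample count; pairs
  never span window boundaries. A single-keystroke window scores 0,
  flagged.

## The ensemble regressor

Each window's feature vector is mapped to a *partial nQi* by an ensemble of
`n_models = 200` linear ε-SVR models with `C = 0.094` and `ε = 0.052`,
solved by LibSVM (via e1071) at tolerance 1e-6. The hyperparameters are the
pipeline's operating constants, originally selected by leave-one-subject-out
AUC grid search on an independent tuning cohort; `grid_search_nqi()`
reproduces that procedure (default grids: `C` log-spaced `2^-10..2^4`, `ε`
from 0.01 to 0.1).

Bagging draws, for each base model, a bootstrap resample (with replacement,
same size) of the **window-level** training vectors. The training unit is a
deliberate choice: window-level resampling matches a training set defined
as a pool of feature vectors; a `bootstrap_unit = "subject"` option
resamples whole subjects instead, for probing sensitivity to within-subject
correlation. Targets are UPDRS-III motor scores divided by the fixed
108-point scale maximum — a convention that keeps targets comparable across
cohorts, where per-cohort min–max normalization would leak test-set
statistics. Features are not standardized by default (they are already
bounded fractions, histogram masses, and small overlaps in seconds);
`scale_features = TRUE` enables z-scoring fit on the training set only.

A window's score is the **median** over the 200 model outputs (for an even
ensemble, the mean of the two central order statistics); a subject's nQi is
the **mean** of their window scores. All resampling derives from
`cfg$seed`, so training is bit-reproducible; models serialize to versioned
JSON at full precision.

## Evaluation stack

* `roc_auc()` computes the AUC as the exact normalized Mann–Whitney U
  statistic (ties counted ½) with a fixed orientation — higher score means
  PD — so null data give AUC near 0.5 instead of being optimistically
  re-oriented. The 95% CI uses the DeLong structural-components variance;
  above AUC 0.95 the interval is computed on the logit scale so it stays in
  [0, 1].
* `delong_test()` is the paired DeLong test. Identical score vectors give
  z = 0, p = 1; two degenerate (zero-variance) curves with different AUCs
  give p = 0; a NaN statistic with distinct AUCs is reported as an error.
* `youden_cutoff()` maximizes the generalized Youden index
  `J = se − m·(1 − sp)` with `m = (cost_FP/cost_FN)·(1 − prev)/prev` and
  prevalence estimated from the sample. The cost-and-prevalence-weighted
  form is one of several "generalized Youden" variants in the literature;
  the published cutoff values alone cannot disambiguate them, so the choice
  is documented here. Candidate thresholds are midpoints of adjacent unique
  scores plus ±∞, the decision rule is `score ≥ threshold → PD`, and ties
  break toward higher specificity.
* `cross_dataset_validate()` trains on each cohort and scores the other;
  the combined list is the union of held-out scores, evaluated once.
  `per_window_auc()` repeats this at window level with labels inherited
  from subjects.
* `adjusted_logistic()` fits the label on the score plus age, sex,
  education and typing speed by maximum likelihood, reporting Wald
  statistics; perfect separation is flagged and the score p-value withheld.

## The synthetic cohort generator

`simulate_cohort()` exists so the full pipeline can be exercised and
validated without clinical data. It emulates:

* sessions of 14 ± 2.9 min (truncated to 9–20 min so every subject has at
  least six full windows);
* burst–pause typing: lognormal inter-key intervals within bursts of ~30
  keys, pauses of ~3 s, and occasional long breaks (~45 s) that produce
  sparse windows and exercise the 30-sample filter;
* lognormal hold times with median ~100 ms, within-subject shape 0.35
  (~36% coefficient of variation) and between-subject location spread 0.10
  on the log scale;
* for PD subjects, a two-state Markov regime process: impaired episodes of
  a few tens of seconds during which the lognormal shape is inflated by
  `1 + severity_effect·severity` (capped at 0.9 so holds stay physically
  plausible) and heavy-tail holds (> 0.3 s) occur with extra probability.
  Both the episode entry rate and the tail rate grow with
  `severity_effect·severity`; the graded tail channel matters because
  occupancy and window-relative outlier fractions saturate at high
  severity, and without it the score would plateau across severity levels.
* a latent severity per PD subject (normal, mean 0.19, sd 0.07, clipped to
  [0.05, 0.6]) chosen so that `round(108·severity)` reproduces the
  UPDRS-III spread typical of an early-PD cohort (patient mean near 20,
  controls near 2); controls have severity exactly 0, making the null
  generator (`severity_effect = 0`) exactly label-exchangeable.
* group-balanced covariates (age ~60, education ~15 y, typing speed 60–160
  keys/min), so covariate-adjusted tests exercise the no-confounding case.

The default `severity_effect = 8` is the generator's *strong* regime: at a
typical severity of 0.19 the impaired-state shape parameter saturates its
cap and roughly 7% of impaired-state keys are heavy-tail holds, which is
what gives the windowed variance features something to detect.

**What passing synthetic tests does and does not show.** The generator
reproduces the statistical *structure* the method targets — sparse bursty
sessions, bounded hold times, transient heteroscedasticity tied to a
severity that also drives the training targets — so end-to-end tests verify
the pipeline's mechanics, determinism, and its ability to recover a known
signal (and to find nothing under the null). It does not emulate real
typing content, key-identity sequences, error/backspace behaviour,
medication state, fatigue drift, or hardware timing jitter; synthetic AUCs
near 0.98 therefore say nothing quantitative about clinical performance,
where the published cross-validated AUCs on real cohorts are far lower.

## Problem sizes and numerical choices in the test suite

The shipped tests use cohorts of 40 subjects per dataset (the scale of the
original two-cohort design) for end-to-end checks, 500-window feature
oracle sweeps, 1000-instance AUC oracle sweeps, a 2000-replicate bootstrap
for the DeLong variance, and 500 replications for logistic null
calibration — sizes chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error well inside the asserted tolerances. Brute-force
oracles (pair-counting AUC, primal-objective SVR optimization, manual
quantile interpolation) are implemented independently in the test helpers.

Two numerical subtleties are worth recording. First, the AUC is computed
in rank form rather than as the trapezoidal area, because the rank form is
exact in floating point and matches pair counting bit for bit. Second,
linear ε-SVR optima are unique in `w` but can be non-unique in `b` (the
ε-insensitive loss can be flat in an interval); correctness tests compare
against the primal optimum only on problems verified to have a unique
minimizer, and otherwise compare objective values.

## Known limitations

* Subject scores average window scores without weighting by window sample
  count; very uneven sessions could benefit from weighting.
* The generalized-Youden variant and the UPDRS normalization are
  conventions (documented above), not established facts of the original
  method.
* `v_de` aggregation (mean of clamped overlaps) is likewise a documented
  choice; sum or count-fraction variants would change its scale but not
  the windowing or eligibility logic.
* The DeLong CI switches to the logit scale only above AUC 0.95; intervals
  for mid-range AUCs are plain Wald intervals clamped to [0, 1].
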