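---
title: "Actigraphy features and nested-LOOCV classification of dementia etiologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actigraphy features and nested-LOOCV classification of dementia etiologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actidx)
```

## The problem

Rest–activity patterns measured by body-worn accelerometers are altered in
dementia: overall activity falls, the circadian rhythm becomes less robust
and more fragmented, and the composition of daily behaviour (walking,
sitting, lying) shifts. `actidx` implements an analysis chain for week-long
two-sensor actigraphy in a memory-clinic setting: epoch-level activity
categories and intensity counts are aggregated to clock-aligned 15-minute
windows, summarized into per-day features over clinically motivated clock
periods, and fed to a feature-selecting logistic classifier that
discriminates Alzheimer's disease (AD), dementia with Lewy bodies (DLB) and
cerebrovascular cognitive dysfunction (the merged Mixed AD + VCD class,
"CVD") from each other and from healthy controls (HC).

Because no clinical recordings ship with the package, a first-class
synthetic cohort generator emulates the group-level structure of such a
cohort; every stage is exercised and tested end-to-end on generated data.

## Data model

An **epoch series** is a per-subject sequence of classified 5-second epochs:
one of nine activity categories (upright standing, sporadic walking,
walking, running, moderate intensity, lying rest, lying movement, sitting,
cycling) plus a nonnegative unitless intensity count. The sensor system that
motivates this schema actually uses 5.128-second epochs; we model them as
exactly 5 s (the length is configurable) since nothing downstream depends on
the 2.5% difference. Gaps in the epoch grid encode non-wear.

A **window series** summarizes epochs in clock-aligned windows (default
15 minutes): per-category time fractions (taken over all epoch slots, so
fractions plus the non-wear share sum to one exactly), the summed intensity
count, the wear fraction, and two event signals — sit-to-stand transitions
and step counts. The sensor export provides the event signals directly; when
windows are derived from epoch CSVs they are reconstructed (sitting →
upright-standing transitions between consecutive epochs; a nominal cadence
of 4/8/9/12 steps per 5-s epoch for sporadic walking, walking, moderate
intensity and running). Only the thigh sensor feeds the default feature set;
chest-sensor series are accepted and stored but not merged, since no
principled fusion rule is available.

Three **analysis periods** are cut from each recording by window start time:
the full period (22:00 to 22:00 the next day, 96 windows), night (00:00 to
06:00, 24 windows) and day (09:00 to 21:00, 48 windows), the latter two
falling on the morning and daytime after the 22:00 anchor. A full period
with mean wear below 80% is excluded from feature summarization; the
threshold is a package default (no wear rule is established for this
setting) chosen so that fragmentation indices cannot be driven by gaps.

## Features

For each period, each activity category's fraction series `x` yields:

* its mean,
* the percentage of windows with **strictly** more than 5%, 10% and 25% of
  time in the category, and
* the intra-daily variability

$$IV = \frac{n\sum_{i=2}^{n}(x_i - x_{i-1})^2}{(n-1)\sum_{i=1}^{n}(\bar x - x_i)^2},$$

the ratio of the mean squared successive difference to the variance: near 0
for a smooth consolidated rhythm, about 2 for white noise, at most 4
(attained by an even-length 0/1 alternation). A constant series leaves IV
undefined and propagates as missing rather than crashing; IV is invariant to
shifting and positive scaling, and is computed over the observed windows in
order when windows are missing.

The intensity-count series yields its mean, its mean during windows whose
modal category is sitting, and its IV; within the full period it
additionally yields **M10** and **L5** — the extreme means over contiguous
10-hour and 5-hour blocks, stepped one window at a time without wrapping
past the period boundary, ties to the earliest start — their onset clock
times, and the **relative amplitude**

$$RA = \frac{M10 - L5}{M10 + L5} \in [0, 1],$$

a robustness measure of the rest–activity rhythm. M10/L5/RA are computed on
the full period only: the night period cannot contain a 10-hour block and
computing them inside the 12-hour day period would change their meaning.
Event signals get a mean and an IV per period.

This gives 161 per-day features; summarizing each by its average and
unbiased (n−1) variance across valid days gives **322 features per
subject**. (The clinical description this design follows reports 255/510;
that enumeration cannot be reconciled from the listed feature families and
category count, so the registry here is explicit, its size asserted in
tests, and categories/signals can be added or removed.) Subjects with no
valid day are excluded; a single valid day leaves variances missing and
drops the subject from classification by default.

## Synthetic cohorts

`generate_subject_windows()` draws one subject at window resolution:

* a deterministic circadian **drive** — mesor + 24-h cosine (acrophase
  default 14:00) + optional late-afternoon Gaussian bump — sets the expected
  intensity;
* a rest/active **gate** opens where the normalized drive exceeds 0.5, and a
  two-state disruption chain (entry probability `frag_rate` per window, mean
  disruption two windows) flips windows relative to the gate, fragmenting
  the rhythm; a Poisson number of extra active windows per night
  (`night_wake_rate`) models nocturnal wake bouts;
* the window's modal category is drawn from a state-conditional mix, walking
  extends in geometric bouts (`walk_bout_mean`), and the window's count is
  the drive times the category-mix intensity weight times multiplicative
  log-normal noise — so category composition and counts stay consistent;
* epoch series are an exact refinement: epochs are allocated to categories
  by the window fractions and the window count is distributed over epochs
  by category weight, so re-aggregation recovers the windows.

The `cohort_preset_table2()` preset encodes the published group contrasts as
generative directions, not as a fit: per-window mean intensity ordered
HC (39.1) > AD (31.7) > DLB (29.1) > VCD (21.4) ≈ Mixed AD (19.5); weaker
amplitude, higher fragmentation, shorter walking bouts and 4–5 nightly wake
bouts in DLB and the cerebrovascular groups (elevating their L5 and
depressing RA); an afternoon bump in HC only. Covariates (age, sex, MMSE,
medication flags) are drawn per group from a cohort-like model,
independently of the activity profiles. Per-subject seeds are derived
deterministically from the master seed, so cohorts are byte-reproducible and
order-insensitive.

What the generator does **not** emulate: biomechanically realistic
accelerometry, sleep stages and REM-behaviour phenomena, weekday/weekend
structure, weather- or season-driven behaviour, wear artefacts, and the
overlap of real clinical groups. Its planted contrasts are several pooled
SDs wide, so classification accuracies on synthetic cohorts sit far above
published clinical figures; passing tests demonstrate that the pipeline
recovers structure that is present and reports chance when none is, not
that these accuracies transfer to patients.

## The classifier

For each binary contrast (AD vs HC; HC vs all disease; AD vs DLB; AD vs
CVD, with Mixed AD and VCD merged), `nested_loocv_predict()` runs
leave-one-out cross-validation in which **all** model selection is redone on
each training fold of N−1 subjects:

1. features are standardized with training-fold statistics only;
2. **mRMR** (greedy MID scheme: first maximize relevance MI(f; y), then
   MI(f; y) minus mean MI with the already-selected set; mutual information
   after equal-frequency 3-bin discretization; ties to registry order)
   keeps the top 30 candidates;
3. **sequential forward selection** adds the candidate that maximizes inner
   leave-one-out accuracy of an unregularized logistic fit, stopping when no
   candidate strictly improves the criterion or at 10 features. The
   empty-model reference is the training majority-class rate — the literal
   LOO accuracy of an intercept-only model is 0 under exact class balance, a
   degenerate artifact, so it is not used. On pure noise the selection
   terminates well below the cap, but chance improvements of a quantized
   LOO criterion mean it does not reliably stop at zero or one features;
   the leakage guard below is the meaningful null check;
4. an unregularized maximum-likelihood logistic model is fitted on the
   selection and predicts the held-out subject's probability.

Separation (infinite MLE) is handled by clamping coefficients at ±15 on the
standardized scale and flagging the fold; a 1e-10 diagonal jitter stabilizes
the IRLS solve numerically and is not statistical regularization. The hot
loop (roughly 10^5–10^6 small logistic fits per task) is implemented in
C++ with warm starts; `stats::glm` serves as an independent cross-check in
the tests, never as the implementation.

Out-of-fold probabilities are evaluated both at the default 0.5 threshold
and at the ROC point closest to (0, 1), scanned over midpoints between
sorted distinct probabilities plus 0 and 1 (ties to the lower threshold).
Sensitivity, specificity, accuracy and precision carry exact-binomial
Clopper–Pearson 95% intervals on their natural denominators; F1 (the
harmonic mean of precision and sensitivity) is not a binomial proportion
and is reported without an interval. The comparator is a single-feature
leave-one-out logistic model on the mean 24-hour intensity count (the
default; the daytime mean is one flag away). Feature importance is the mean
over outer folds of the absolute standardized coefficient, counting
unselected folds as zero.

A deliberately leaky variant (`leaky_loocv_predict()`, selection on all
subjects before the loop) is exported only as a negative control: on
pure-noise cohorts the nested scheme stays in the chance band while the
leaky one exceeds it, and that contrast is a regression test. Note that
out-of-fold predictions share selected features across folds and are
therefore positively correlated: single-cohort noise accuracies scatter
more widely than a binomial band suggests, which is why the guard averages
over five seeded cohorts.

## Numerical and design choices

* Windows are clock-aligned; leading epochs before the first boundary and
  trailing partial windows are dropped, making the 22:00 anchor exact.
* Period membership is by window start time (half-open intervals):
  deterministic and resolution-independent.
* The group-average 24-h curve is smoothed by a centered one-hour circular
  moving average (weights 1/8, 1/4, 1/4, 1/4, 1/8 at 15-minute resolution),
  which conserves the daily mean; the uncertainty band is the SE across
  subjects (not subject-days).
* The confounder probe regresses out-of-fold probabilities on age, sex and
  medication flags by OLS within the control and disease subgroups
  (identity link by default, logit optional), dropping constant covariates
  with a warning.
* Kruskal–Wallis tests delegate to `stats::kruskal.test` (tie-corrected H,
  chi-square approximation); the all-constant degenerate input returns
  H = 0, p = 1. No multiplicity correction is applied to descriptive
  feature screens.
* All randomness is seeded; classification is fully deterministic given its
  inputs (ties break to registry/candidate order, never randomly).

## Problem sizes used by the tests and acceptance script

The test suite exercises: oracle equivalence on 200 random series (IV and
M10/L5); 2000-replicate interval-coverage and type-I-error simulations;
five-seed noise cohorts of 40 subjects × 100 features for the leakage
guard; five-seed preset cohorts of 50 AD + 50 DLB × 7 days for parameter
recovery; and one study-sized smoke run (170 subjects × 7 days, all four
contrasts) with deterministic-rerun checks. `scripts/acceptance.R` re-runs
the worked examples and a scaled preset cohort (58 subjects at the study's
group ratios, 7 days). These sizes were chosen so the whole suite completes
in minutes on one core while keeping every estimate comfortably inside its
tolerance.

## Known limitations

* The pipeline starts from classified activity categories; raw
  accelerometry and the sensor vendor's classification algorithm are out of
  scope, as are time-zone and daylight-saving arithmetic.
* Sleep metrics are deliberately not extracted; nighttime activity features
  are at best a proxy for sleep-related behaviour.
* Clopper–Pearson intervals are reported only for proportion-type metrics;
  how one would attach an exact-binomial interval to F1 is left open.
* The two sensor streams are not fused; analyses use the thigh sensor.
* Synthetic cohorts validate mechanics, not clinical performance.
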