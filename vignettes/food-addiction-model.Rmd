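---
title: "Phenotyping food addiction from operant event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping food addiction from operant event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodaddictr)
```

## The model

Rodent food addiction is operationalized with an operant
self-administration protocol: mice earn highly palatable pellets by
pressing an active lever under schedules of reinforcement, and three
addiction-like criteria are read off their behavior.

1. **Persistence to response** — non-reinforced active presses during the
   10-min *pellet-free period* in the middle of each self-administration
   session, averaged over the 3 sessions preceding the progressive-ratio
   test. Pressing while reward is signalled as unavailable quantifies
   persistent food seeking.
2. **Motivation** — the *breaking point* of a progressive-ratio (PR)
   session: the response requirement escalates along a fixed 35-step
   series (1, 5, 12, ..., 5000, 5500) and the breaking point is the last
   requirement completed.
3. **Compulsivity** — total footshocks endured in a 50-min punished
   session: within each FR5 block the 4th active press delivers only a
   shock and the 5th a shock plus a pellet, so continuing to respond
   despite punishment accumulates shocks.

A mouse is *positive* for a criterion when its score is at or beyond the
75th percentile of the control group's distribution for that criterion;
mice positive for 2 or 3 criteria are classified **addicted**, the rest
non-addicted. With continuous, independent scores, a control-like animal
is positive for each criterion with probability 1/4, so the expected
addicted fraction in a control population is
$3 \cdot 0.25^2 \cdot 0.75 + 0.25^3 = 0.15625$ — a useful calibration
target for the whole classification machinery.

## Schedule state machines

Everything downstream consumes an **event log**: a time-ordered record of
presses, pellets, shocks, period boundaries and time-outs. Three
deterministic state machines produce the logs from timed press streams:

* `run_fr_session()` — fixed ratio. Sessions are two pellet periods
  separated by the 10-min pellet-free period (the default long protocol is
  25/10/25 min, one hour; `protocol = "short"` gives 55/10/55 min, two
  hours — the session structure is fully configurable because the two
  stated descriptions of the in-vivo session are not mutually consistent,
  and both sub-protocols are in use). Every `fixed_ratio`-th countable
  active press delivers a pellet and opens a 10-s time-out in which
  presses are recorded but do not count. Time conventions are continuous
  seconds with half-open intervals: a press exactly at a time-out's end is
  countable. The ratio counter persists across the pellet-free period.
* `run_pr_session()` — progressive ratio. Driven by a response-emitting
  policy (or a precomputed press-time vector; the two paths are tested to
  be equivalent). The session ends at 5 h, or after 1 h without any lever
  response, or when the series is exhausted. PR sessions are modelled as a
  single continuous period with no post-pellet ratio suppression: the
  protocol description attaches the time-out and pellet-free structure to
  the self-administration sessions only, and the natural reading of the
  escalation arithmetic (e.g. 1 + 5 + 12 presses completing exactly three
  ratios) requires every press to count.
* `run_shock_session()` — the punished FR5 test. The 60-s reinitiation
  window opens at the 4th response; if the 5th response does not arrive in
  time the press counter resets, and the 4th press of the new block
  delivers a shock again (the literal reading of "reinitiated"; the
  alternative — no second shock until a pellet intervenes — is not
  described anywhere, so we kept the plain one).

A breaking point with zero completed ratios is defined as 0; the first
series value (1) is reserved for animals that complete at least one
requirement.

Each machine is verified event-for-event against an independently written
brute-force chronological walk on randomized press streams (including
exact ties and presses on period boundaries), and the log invariants — no
pellet in the pellet-free period, ratio bookkeeping, countability inside
time-outs — are re-checked by `validate_event_log()`.

## The synthetic cohort generator

Virtual mice are parameterized by a small latent `trait_profile()`:

| trait | meaning | control default |
|---|---|---|
| `active_rate` | pellet-period press rate (presses/min) | lognormal, median 4 |
| `inactive_rate` | inactive-lever rate (presses/min) | lognormal, median 0.5 |
| `persistence_factor` | multiplier on `active_rate` in the pellet-free period | lognormal, median 0.5 |
| `motivation_cap` | largest PR requirement the mouse will work through | lognormal, median 150 |
| `shock_continue_prob` | probability of continuing after a shock | logit-normal, median 0.25 |
| `acquisition_gain` | per-session FR1 learning factor | 1.3 (fixed) |

Presses are Poisson processes at these rates; the pellet-free rate is
`active_rate * persistence_factor`; post-shock suppression is absorbing
within a session (once a mouse stops after an intolerable shock it stays
stopped — the simplest mechanism that yields a graded shock count); PR
quitting happens when the current requirement exceeds `motivation_cap`,
mapping the cap directly onto the breaking point. The defaults were chosen
once as field-realistic magnitudes — a trained mouse presses a few hundred
times per hour under FR5, earning tens of pellets, and breaking points sit
in the low hundreds — and are *not* fitted to any dataset: per-session
press-rate distributions are not reported for the in-vivo experiments, so
generator parameters are free and documented as such. The
`vulnerable_group()` preset shifts the three criterion-relevant traits
upward (persistence factor ×2.5, motivation cap ×4, shock-continuation
probability centred at 0.75), the synthetic analogue of a vulnerable
phenotype.

`run_protocol()` runs FR1 acquisition sessions (rate ramp
`active_rate * gain^(i - n_fr1)`, so the trained rate is reached at the
last FR1 session), the FR5 sessions, the PR test and the shock test, with
one RNG substream per mouse so cohorts are reproducible regardless of
iteration order.

**What the generator does and does not emulate.** It reproduces the
protocol's event-level structure, group-level trait shifts, and
criterion-score gradients. It does not model within-session satiation,
circadian structure, session-to-session autocorrelation beyond the FR1
ramp, or any mechanistic pharmacology — group differences enter only as
trait-distribution shifts. Passing tests therefore certify the *pipeline*
(state machines, scoring, thresholds, statistics), not any claim about
real mouse behavior.

## Classification, exclusion and calibration

`check_acquisition()` requires some 3 consecutive sessions with <20%
deviation of each session's reinforcers from the triple mean, at least 75%
active-lever responding, and at least 5 reinforcers per session.
`apply_exclusion()` removes mice that responded (≥1 reinforcer — our
documented reading of "responded") in fewer than 25% of FR5 sessions *and*
never acquired; the rule is a conjunction, following the operative
sentence. Thresholds use the linear-interpolation empirical quantile
(`type = 7`; for control scores 1, 2, 3, 4 the 75th percentile is 3.25) —
the percentile convention is not stated in the protocol, so one was fixed
and documented. The criterion comparison is *at or beyond* (`>=`) the
threshold, the operative wording of the classification; a strict-mode
option exists because the protocol text also uses "above" once.

Calibration of the full classifier against the analytic 15.625% uses
`simulate_control_scores()`, which draws the three criterion scores from
continuous, independent lognormals (with an optional correlation knob,
since real criteria correlate). Event-level scores cannot be used for this
check: breaking points live on the 35-value series and shock counts are
small integers, so ties at the threshold distort per-criterion flag rates
— the identity holds only for continuous scores. Event-level simulation is
instead exercised by planted-effect recovery: vulnerable-vs-control
cohorts of 50/50 must yield a significantly higher addicted fraction
(chi-square against the control frequencies) in ≥90% of replicates.

## Statistics

`mann_whitney()` reports U = min(U1, U2) with a two-sided p (exact for
small tie-free samples, tie-corrected normal approximation otherwise);
`chi_square_vs_control()` is the 1-df goodness-of-fit test of the observed
addicted/non-addicted split against expected counts n·(p, 1−p) under the
control proportion, uncorrected by default with a Yates option (whether
the original analyses used the correction is not stated);
`pearson_correlation()` relates criterion values to the number of criteria
achieved. No multiple-testing correction is applied by default, matching
the per-test reporting of this literature; a Bonferroni switch exists.

## The differential-expression stage

The transcriptomic arm compares addicted and non-addicted animals on a
gene-by-sample count matrix. The stage reimplements the classic
normalization-plus-NB-test workflow rather than calling an existing DE
package, because the filters and conventions are part of what this
pipeline specifies; exact numerical parity with any particular DE package
is a non-goal.

* **Size factors** (`estimate_size_factors()`): median over
  all-positive genes of the count over the gene's geometric mean, rescaled
  to geometric mean 1. Recovery of planted depth factors is tested to 5%,
  and agreement with an established median-of-ratios implementation to
  1e-8.
* **Testing** (`nb_differential_test()`): per-gene method-of-moments
  dispersion from the pooled within-condition variance of normalized
  counts (shot-noise corrected, floored at 1e-8, no information sharing
  across genes), then the exact conditional NB test on the two condition
  count sums. Because the exact test treats the estimated dispersion as
  known, the raw p-value is anti-conservative with few samples; it is
  mapped through a Student reference with the dispersion's residual
  degrees of freedom — the same adjustment that turns a known-variance
  z-test into a t-test — which restores null calibration (empirically
  ~1.1% of null genes at p < 0.01 with 5 samples per group) and vanishes
  as samples accumulate.
* **Filters** (`apply_de_filters()`): |FC| > 1.5 in either direction
  (the stated threshold is printed without a direction, so it is applied
  symmetrically), p < 0.01, and mean normalized counts > 40 in at least
  one condition; fold changes are raw normalized-mean ratios, not
  shrunken. BH-adjusted p-values at FDR 0.1 are carried in the result for
  users who prefer FDR filtering.
* **PCA** (`top_variance_pca()`): top-500-variance genes on
  log2(normalized + 1), then sample principal components.

## Problem sizes and numerical choices

Simulated checks are sized to run on a desk machine: classifier
calibration uses 2,000 score-level mice; planted-effect recovery 100
cohorts of 50 + 50 event-level mice under a shortened protocol (3 FR1 + 4
FR5 sessions — criterion scores depend only on the 3 pre-PR FR5 sessions,
the PR test and the shock test, so the 112-session in-vivo history adds
nothing to these checks); DE checks use 4,000–5,000 genes. Ties in event
times are processed in input order (stable); simultaneous events are
ordered so that a closing boundary (time-out or period end) precedes the
press that lands on it, and a pellet follows the press that earned it.
Degenerate inputs — empty streams, all-zero genes, zero-variance
correlation inputs, empty control groups — raise errors or documented
neutral values (an all-zero gene gets p = 1).

## Known limitations

* The generator's trait distributions are stipulated, not estimated; only
  qualitative directions of the in-vivo group differences are meaningful
  targets for it, never the published percentages, which depend on real
  animals.
* The DE stage's per-gene dispersion uses no shrinkage, so it needs
  moderate counts (tens) to be well behaved; with 2–3 samples per group
  the Student correction is blunt.
* The exact conditional NB test enumerates the count-sum split, costing
  O(total count) per gene; it is sized for simulated matrices and
  moderate sequencing depths rather than ultra-deep libraries.
* PR sessions model active presses only; inactive-lever activity during
  PR is not generated (it enters no score).
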