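---
title: "Analyzing single-case multiple-baseline studies of corticospinal excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing single-case multiple-baseline studies of corticospinal excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedtms)
library(dplyr)
```

## The design and the analysis model

`scedtms` analyzes single-case concurrent multiple-baseline experiments:
a handful of participants (five in the reference design, three is the
accepted minimum) all start a baseline phase in the same week, the
intervention is introduced staggered — one extra baseline week per
successive participant (3 to 7 weeks by default) — and each series is
followed by a descriptive follow-up phase. Because each participant acts
as their own control and the intervention onset is staggered, an effect
that appears at each participant's own onset (and not before) supports a
causal interpretation despite the tiny sample.

Every outcome is a *series*: one participant x measure x body side
sequence of `(week, phase, value)` points. Measures carry a registry
entry (`measure_spec()`) declaring their unit, their family
(neurophysiological or clinical) and, critically, their **therapeutic
direction**: for conduction times (CMCT, MEP latency), the resting motor
threshold, timed walking and fatigue scores a *decrease* is an
improvement; for MEP amplitude, balance, arm function, strength and
processing speed an *increase* is. All between-phase summaries and
effect sizes are direction-adjusted, so "better" always means better for
the patient.

The analysis proceeds in two stages, mirroring standard single-case
methodology:

1. **Visual analysis** of each series, quantified into eight criteria
   (four within-phase: level, trend, stability, variability; four
   between-phase: overlap, immediacy, percentage exceeding the median,
   cross-participant consistency). The conjunction of the enabled
   criteria is a *gate*.
2. **Effect estimation** only for series that pass the gate: the
   nonoverlap-of-all-pairs (NAP) effect size with a randomization-test
   p-value and a Bonferroni-corrected significance verdict. Gated-out
   series never receive a p-value — running inferential statistics on
   series whose baselines are unstable invites spurious findings, so
   withholding the test *is* the procedure, not a missing feature.

## Neurophysiological derivations

The TMS-derived measures are computed from raw ingredients before the
series-level analysis starts:

* **Peripheral conduction time** `(F + M - 1) / 2` ms from the F-wave
  and M-wave latencies of median-nerve stimulation.
* **CMCT** = MEP onset latency − peripheral conduction time. The
  identity `CMCT + PCT = MEP latency` holds exactly and is enforced by a
  property test. Non-positive CMCT values are flagged as degenerate but
  kept, so the visual-analysis stage sees them.
* **MEP peak-to-peak amplitude**: max minus min of the sweep inside a
  configurable post-stimulus window (default 15–60 ms; wide enough for
  upper-limb latencies, late enough to exclude the stimulus artifact —
  the choice is ours, as no standard window exists).
* **MEP onset latency**: the reference procedure scores onsets by
  visual inspection, which is not reproducible by software. We use a
  threshold detector instead: the first post-stimulus sample whose
  rectified amplitude exceeds the pre-stimulus mean + `k_sd` (default 3)
  standard deviations and stays above threshold for `min_duration`
  (default 0.5 ms), with backtracking to the start of the sustained run
  so noise dips just after the true onset do not bias the latency late.
  On noiseless synthetic traces the detector recovers the programmed
  onset to within one sample at 24 kHz; at a noise SD of 0.002 mV and an
  amplitude of 0.1 mV it stays within 0.2 ms.
* **Bout summaries**: a session applies a fixed bout (30 stimuli at
  120% of the resting motor threshold, rounded to integer %MSO and
  capped at 100 with a flag); per-trace amplitudes and latencies are
  averaged, unweighted, into one value per session. Traces without a
  detectable onset are excluded from the latency mean only. An exclusion
  hook for artifact-contaminated sweeps exists but defaults to "none".
  (Aside: hot-spot search criteria are sometimes printed as "50 mV"
  peak-to-peak in the TMS literature; that magnitude is implausible for
  surface EMG and is surely 50 µV. The package records hot-spot settings
  as metadata only and computes nothing from them.)

## The gate criteria, precisely

With `b` the baseline values, `i` the intervention values, `med` the
phase median and direction-adjusted comparisons throughout:

| criterion | definition | default threshold |
|---|---|---|
| level | mean(i) − mean(b) in the therapeutic direction | any change |
| trend | OLS slope projected over the phase, `slope * (n-1)`, within ±15% of \|med\| → stable; baseline must be stable, intervention improving or stable-with-level-change | band 0.15 |
| stability | share of points within ±15% of \|med\| (inclusive) | ≥ 80% |
| variability | share of points outside reference mean ± 2 SD | ≤ 20% |
| overlap | share of intervention points inside [min(b), max(b)] | 0% tolerated |
| immediacy | mean(first 3 of i) − mean(last 3 of b) in direction | any change |
| PEM | share of i strictly beyond med(b) in direction; ties don't count | ≥ 70% |
| consistency | share of participants matching the modal improvement verdict | ≥ 0.8 |

Decisions worth spelling out, because each was genuinely open:

* **Stability at exactly 80% counts as stable.** Reporting practice in
  this literature treats an 80% phase as meeting the criterion even when
  the criterion is verbally stated as "higher than 80%"; a
  `stability_strict` switch restores the strict reading.
* **Trend is a slope classifier, not strict monotonicity.** No noisy
  series is literally monotone; the slope-projection band (15% of the
  absolute median, the same band as stability) is the operational
  reading, with `strict_monotone_trend = TRUE` available.
* **The variability reference is configurable** (`own_phase`,
  `whole_series`, `baseline`) and defaults to the phase's own mean ± 2
  SD, the literal two-standard-deviation-band wording. Note the
  arithmetic consequence: for a phase of n points the share outside its
  *own* 2-SD band can never exceed 1/4, and is exactly 0 for n ≤ 5
  (the largest standardized deviation of n points is (n−1)/√n < 2).
  Published variability figures of 40–50% on 5-point phases therefore
  cannot arise from own-phase referencing; the alternative references
  exist for that reason, and the default keeps the literal wording.
* **PEM ties do not exceed.** "Exceeding the median" is read strictly;
  an intervention point equal to the baseline median contributes 0.
* **Zero tolerated overlap.** In the reference results every
  gate-passing series showed no overlap at all while 40% overlap failed,
  so the default threshold is 0%, exposed in the configuration.
* **Median = 0 bands** fall back to an absolute half-width
  (`median_epsilon`, default 0.5 measure units) so clinical scores near
  zero do not produce zero-width stability bands.
* **Consistency is vacuous for an isolated series** (fewer than two
  participants): it passes with a note. The study-level pipeline
  computes it across participants per measure/side and feeds it to each
  gate; it can be disabled via `enabled` without touching the others.
* **Level and immediacy magnitudes**: whether a *minimum* magnitude
  should be demanded is unstated in the methodology this implements;
  the default accepts any direction-consistent change
  (`immediacy_min_change = 0`).
* **Follow-up** is summarized descriptively (level, trend, stability)
  wherever points exist, and never contributes to the gate: a "return
  toward baseline" has no agreed criterion, so none is invented.

## Effect size and inference

**NAP.** Over all `nA x nB` baseline-intervention pairs, NAP is the
share of pairs in which the intervention point is strictly better in
the therapeutic direction, ties counting one half. NAP = 1 is complete
nonoverlap; 0.5 is chance. NAP is rank-based, hence invariant under any
strictly increasing re-expression of the measurement scale, and
satisfies `NAP(decrease) + NAP(increase) = 1`. The implementation
enumerates pairs directly; the test suite cross-checks it against the
tie-corrected Mann-Whitney rank-sum identity, computed independently.

**Randomization test.** The null hypothesis is exchangeability of the
phase labels within a series: reassign the observed `nA + nB` values to
phases of the observed sizes, recompute the statistic (NAP by default;
the phase mean difference is available), and report the two-sided
p-value — the share of assignments whose statistic is at least as far
from the null center (0.5 for NAP, 0 for the mean difference) as the
observed one. The observed assignment is always counted, so p > 0. All
`choose(nA+nB, nB)` assignments are enumerated exactly up to
`max_exact = 50000`; beyond that a seeded Monte-Carlo sample is drawn
and the observed assignment is added to numerator and denominator.
Which scheme produced a p-value is recorded in the result.

Two properties deserve emphasis. First, with the NAP statistic the
p-value inherits monotone-transform invariance. Second, the test is
*discrete*: with 3 baseline and 5 intervention points only
`C(8,5) = 56` assignments exist and the smallest attainable two-sided p
is 2/56 ≈ 0.036. A participant with a three-week baseline therefore can
reach raw significance at 0.05 but *never* a 0.025 Bonferroni-corrected
level — exactly the pattern a staggered design produces for its
shortest-baseline participant. This is a feature of exact inference at
single-case sample sizes, not an implementation limitation.

**Correction.** `alpha_corrected = alpha / n_tests`, with `n_tests` the
number of body sides tested for the measure (0.05/2 = 0.025 for
bilateral measures). Because per-measure correction is anti-conservative
when many measures are tested, the report also carries a study-wide
corrected level (`alpha / number of tests actually performed`) alongside,
without changing the primary verdict.

**Randomization scheme choice.** Within-series permutation of values
between the two phases was chosen over intervention-start-point
randomization across the stagger because the reference reporting style
is per-series ("participant X: NAP = 1, p < 0.05"), which a start-point
scheme cannot produce. Whether the original analyses enumerated
exactly or sampled is not documented anywhere we could check; both
schemes are implemented and labelled, and neither is presented as a
certified reconstruction.

**Agreement.** `interassessor_agreement()` scores the share of
co-scored points on which two assessors agree within a tolerance
(default exact), with the conventional 0.8 pass mark. Checking that the
co-scored subset covers at least 20% of each condition's points is left
to the caller, because it depends on the full assessment schedule.

## The synthetic-data generator

`generate_design()` reproduces the staggered schedule: concurrent start,
baselines of 3, 4, 5, ... weeks (one assessment per baseline week), a
12-week intervention with five weekly assessments starting at
intervention week 3, and follow-up assessments 4, 8 and 12 weeks after
the intervention ends. Generated designs always pass
`validate_design()`.

`generate_series()` draws each scheduled value as *phase level +
Gaussian noise*, i.e. an immediate step-change model — the structure the
visual analysis is designed to detect. Identical seeds give
bit-identical datasets. Three scenarios ship as fixtures, with levels
chosen to mimic the group-level magnitudes of a bilateral TMS exercise
study and noise levels chosen once as plausible fixtures (published
phase summaries include no within-phase variances to estimate from):

* `rmt_effect`: resting motor threshold, left 64 → 50 → 65 %MSO, right
  62 → 52 → 62 %MSO, noise SD 0.8 %MSO, with participant E missing one
  baseline and one intervention assessment. Follow-up levels return to
  baseline, emulating the reversibility of the excitability effect.
* `cmct_null_highvar`: CMCT around 13 ms (left) and 11 ms (right) with
  no step and noise at roughly 15% of the level — series that fail
  stability/variability and are gated out, the published CMCT outcome
  pattern.
* `clinical_clean`: a unilateral balance score 20 → 26 → 22 with zero
  noise, reproducing the idealized 100%-stability, zero-overlap,
  PEM-100% clinical pattern exactly.

The generator is deliberately simple. It does **not** emulate
autocorrelated measurement error by default (an AR(1) option exists to
stress-test the exchangeability assumption), session-level drifts,
learning effects across assessments, floor/ceiling effects of bounded
scores, or any dependence between sides or measures. Passing tests on
these scenarios therefore demonstrate that the pipeline detects clean
step effects and withholds inference from unstable null series; they do
not certify behaviour on real EMG drift or practice effects.

A trace-level generator (`generate_mep_trace()`) produces one EMG sweep
as pre-stimulus Gaussian noise plus a biphasic 10-ms sine template with
a programmed onset and peak-to-peak amplitude at 24 kHz, so the onset
detector and amplitude reader can be validated by round-trip.

## Numerical choices

* Exact enumeration switches to Monte-Carlo above 50 000 assignments;
  Monte-Carlo p-values use the add-one rule. Ties in the permutation
  distribution are compared with a 1e-12 slack so floating-point noise
  cannot flip an assignment out of the rejection count.
* Per-series Monte-Carlo seeds are derived deterministically from the
  study seed and the series position (a fixed linear-congruential map
  below 2^31), so a full report is a pure function of
  (data, configuration, seed).
* The calibration suite simulates 1000 null Gaussian series of
  8 baseline + 6 intervention points (3003 assignments), a size at
  which the discrete null grid resolves a 5% level; at the study's own
  smallest sizes the exact test is conservative (largest attainable
  sub-0.05 rejection rate 14/462 ≈ 0.030), which the discreteness
  paragraph above explains.
* Degenerate inputs: all-equal series give p = 1; empty phases error;
  zero-SD variability references error unless the assessed values are
  equally constant; non-positive CMCT is flagged, not dropped.
* Long-CSV output is written at fixed six-decimal precision in a
  canonical row order, so write → read → write is byte-identical.

## Worked example

```{r}
data <- generate_series(scenario("rmt_effect"), seed = 1)
report <- analyze_study(data, seed = 1)
report
report$effects |>
  select(participant, side, nap, p_value, alpha_corrected, significant)
```

All ten series pass the gate with NAP = 1. Participants with four or
more baseline points fall below the corrected 0.025 level; participant
A (three baseline points) reaches p = 2/56 ≈ 0.036 — significant raw,
not after bilateral correction, the expected shortest-baseline outcome.

```{r}
null_report <- analyze_study(
  generate_series(scenario("cmct_null_highvar"), seed = 1), seed = 1)
null_report
```

Every null series is gated out and carries no p-value.

```{r, fig.width = 7, fig.height = 9}
plot_series(data, "rmt")
```

## Known limitations

* The long-CSV schema is this package's canonical format; converting a
  study's deposited spreadsheets into it is a manual step.
* Consistency is quantified as modal agreement on the improvement
  verdict, a deliberately simple formalization of what is usually a
  qualitative judgement.
* The within-series randomization test conditions on the realized
  intervention onset. Design-based inference over the stagger is
  available separately (`mb_startpoint_p()` permutes the observed
  onsets across participants and ranks the realized assignment among
  all `n!`), but it yields one panel-level p-value, not the per-series
  reporting the primary path produces, so the two are complementary
  rather than interchangeable.
* No Tau-U or baseline-trend-corrected nonoverlap variants, and no
  Bayesian single-case models.
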