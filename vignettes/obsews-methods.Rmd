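---
title: "Comparing early warning scores on obstetric wards: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing early warning scores on obstetric wards: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsews)
```

## The problem

Pregnant and postpartum patients deteriorate rarely but quickly, and their
normal vital-sign ranges differ from the general ward population (resting
heart rate is higher, blood pressure lower). Hospitals therefore choose among
several bedside early warning systems: general aggregate scores (MEWS, NEWS)
that sum per-variable points, and obstetric trigger systems (MEOWS, MEWC,
MEWT) that fire on combinations of abnormality flags. `obsews` implements
these five rule-based systems over longitudinal EHR event streams, phenotypes
the two outcomes they are meant to anticipate (ward-to-ICU transfer or death,
and new infection), and evaluates all systems in a common observation-level,
forward-looking framework. Because real obstetric EHR data are protected, the
package also ships a seeded synthetic cohort generator so the entire pipeline
is reproducible from nothing.

## Data model and snapshot assembly

Input is six long-format CSV tables per cohort: encounters, location
intervals (ward, labor & delivery, ICU), vitals, labs, medication
administrations, and blood-culture orders. Timestamps are ISO-8601 at minute
resolution in a single implicit timezone; values outside configurable
physiologic plausibility bounds (for example temperature outside 30–43 °C,
heart rate outside 20–250) are rejected at read time with a reason, never
silently dropped.

Scores are computed on *observation snapshots*: one per distinct vital-sign
charting time per patient while the patient is on the ward. Each snapshot
carries, for every variable, the most recent value within a staleness
horizon (last observation carried forward): 24 h for vitals and the
consciousness/supplemental-oxygen flags, 48 h for labs, never across an
encounter boundary. These horizons are package choices — standard ward-score
practice, preventing stale labs from dominating — and are configurable via
`locf_config()`. Lab-only times do not create snapshots, because bedside
scores are anchored to vital-sign observations. Setting all horizons to zero
reduces snapshots to same-timestamp values, a property the test suite
verifies on random cohorts.

## The five scoring systems

Each system is a declarative table of threshold bands with explicit interval
endpoints, checked at load time for overlap and (for point systems) complete
coverage of the real line. The shipped tables follow the systems' source
publications (Subbe for MEWS, the national score for NEWS, Singh for MEOWS,
Mhyre for MEWC, Shields for MEWT) and every value can be overridden with a
YAML config, so a site can substitute its local thresholds exactly.

Printed threshold tables are stated at charting resolution (e.g. "35–38.4"
then "≥38.5"), which leaves gaps on the real line; the shipped point-system
bands use half-open `[lower, upper)` intervals that tile the line and agree
with the printed values at measurement resolution.

Combination rules:

* **MEWS, NEWS** — sum of per-variable points. Missing variables contribute
  zero and lower the reported `completeness` fraction.
* **MEOWS** — one *red* (markedly abnormal) or two simultaneous *yellows*
  trigger. Ordinalized as `yellow + 2·red`, so the published rule is exactly
  `ordinal ≥ 2`, and the graded value is usable for ROC analysis.
* **MEWT** — one severe or two non-severe triggers; same ordinalization.
  Mean arterial pressure is derived as `(SBP + 2·DBP)/3` when both pressures
  are present. The source publication's 20-minute persistence requirement is
  available as `apply_persistence_filter()` but off by default, since
  snapshot-level scoring is the common deployed form.
* **MEWC** — any single criterion triggers; the ordinal value counts
  criteria met.

Subjective elements of the obstetric tools (nursing concern, non-remitting
headache) are not representable in EHR event streams and are excluded.
MEWC's oliguria criterion (< 35 mL/h) is applied to the charted 12-h urine
total (< 420 mL/12 h) and only to quantified outputs: unquantified urine is
charted as zero and must not read as anuria. AVPU is scored on the numeric
coding A=0, V=1, P=2, U=3.

Machine-learning risk scores such as random-forest deterioration models are
represented by a pluggable interface: `fit_surrogate_risk_model()` trains a
random forest on labeled snapshots (median-imputing missing predictors) and
`predict_risk()` returns probabilities; any fitted object with the same
contract can stand in. The surrogate is a stand-in trained on synthetic
data — it makes the comparison pipeline executable end-to-end, and is not a
reimplementation of any proprietary score.

## Outcome phenotypes

**Deterioration** is the composite of death or ward-to-ICU transfer: a ward
interval immediately followed by ICU, or ward → labor & delivery → ICU with
ICU entry within 24 h of leaving the ward. Direct L&D-to-ICU transfers with
no prior ward stay are excluded — the analysis concerns ward surveillance.
A death during or after ward care without a qualifying transfer is an event
at the death time; only the first event per encounter counts.

**Infection** uses the antibiotic/blood-culture temporal rule: an IV
antibiotic within ±2 calendar days of a blood culture order, followed by
IV or oral antibiotics on at least four consecutive calendar days or on
every day up to the day before discharge. Days are local-midnight calendar
days; the streak is anchored at the qualifying IV day, and a single
antibiotic-free day breaks it. The event time is anchored to the earliest
qualifying culture order (the anchor is configurable; first-dose or
day-boundary anchors are equally defensible and the source operationalization
does not pin one down). The test suite checks this detector against
exhaustive enumeration over random day sets.

## Evaluation framework

The unit of analysis is the observation, not the patient: each ward snapshot
is labeled 1 if the patient's first outcome event falls in `(t, t + 24 h]`,
and observations at or after the event are excluded. A patient-level
sensitivity analysis (maximum score per patient) can be assembled from the
same tables but is not the default. Observations in the final 24 h before an
event-free discharge are retained as negatives.

* **AUC** uses the midrank estimator (ties counted one-half) with the
  DeLong structural-component variance; the 95% CI is the normal
  approximation truncated to `[0, 1]`. Constant scores give AUC exactly 0.5
  with zero variance.
* **Paired comparisons** use the DeLong covariance z-test; two-sided
  p-values from the normal reference, no multiplicity adjustment (matching
  standard practice for these head-to-head score comparisons). Comparing a
  score with itself yields difference 0 and p = 1 exactly.
* **Threshold tables** report exact confusion counts with the alert rule
  `score ≥ threshold` at every distinct value.
* **Efficiency curves** plot the fraction of observations alerting against
  sensitivity, one point per threshold — the alarm-burden trade-off that
  matters at very low event prevalence.
* **Cohort summaries** give median (IQR) and n (%) by outcome group with
  rank-sum and chi-squared comparisons; percentages are rounded to one
  decimal, half away from zero, the convention of clinical tables.

## The synthetic cohort generator

`sim_config()` parameterizes everything: cohort size, event prevalences,
charting cadence (4 h ± 1 h jitter), baseline vital and lab distributions,
pre-event drift, lengths of stay, transfer-chain mix, and decoy antibiotic
courses. Baselines are anchored to published obstetric ward distributions
(heart rate median 85, IQR 75–94; respiratory rate 18 (18–20); temperature
36.6 °C; systolic pressure 117 mm Hg; oxygen saturation 98%; and a standard
lab panel), mapped to normal or log-normal marginals with the IQR setting
the spread. The marginal variance is split 0.6/0.8 between a per-patient
baseline and independent per-observation noise.

Deteriorating patients receive a linear drift over the final 12 h before
their event — heart rate +25, respiratory rate +8, systolic pressure −20,
temperature +1.2 °C at the event, scaled by `drift_scale` — plus occasional
consciousness and supplemental-oxygen changes near the event. Infected
patients receive a fever/tachycardia drift peaking at the culture order and
an antibiotic course constructed to satisfy the infection rule; a
configurable fraction of non-infected patients receive decoy courses (short
runs, cultures without antibiotics, late IV starts) that must not satisfy
it. Transfer chains mix direct ward→ICU, qualifying ward→L&D→ICU,
non-qualifying chains with L&D dwell over 24 h, and ward deaths.

Per-patient RNG substreams are keyed by (seed, patient index), so output is
byte-identical under a fixed seed and enlarging a cohort never perturbs
existing patients. Default prevalence is 5% — stable observation-level AUCs
at desk-scale n — while `paper_scale_sim_config()` ships the realistic 0.2%
deterioration / 0.4% infection rates for large runs.

What the generator does *not* emulate: within-patient autocorrelation
beyond the baseline/noise split (an AR(1) option is deliberately left out of
the default), charting intensification when a patient looks unwell,
medication effects on vitals, seasonal or secular trends, and any
mechanistic physiology. Passing recovery tests therefore show that the
pipeline's plumbing and statistics are sound, not that any score would
achieve a particular accuracy on real patients.

## Numerical choices and problem sizes

Tolerances and sizes used by the package's own test analyses, chosen as a
balance of statistical resolution and desk-scale runtime: AUC oracle
equivalence on 100 random instances up to n = 200; DeLong standard error
against a 500-resample bootstrap at n = 500; type-I error over 1,000
permuted-label replicates at n = 200; infection oracle over 1,000 random
day-set ledgers; drift recovery at n = 2,000 patients across drift scales
{0, 1, 2} and five seeds; null calibration over 20 replicates at n = 500.

## Known limitations

* Under the default drift model, tie-heavy single-parameter triggers
  discriminate weakly: roughly a tenth of event-free observations cross at
  least one MEWC threshold under realistic baseline noise (consistent with
  the published observation-level specificity of such criteria), while
  injected drift only crosses those extreme thresholds in the last hours of
  the 12 h ramp. MEWC's observation-level AUC on synthetic cohorts
  accordingly sits near 0.58–0.60 even at doubled drift, below what it
  attains on real data, where pre-event physiologic abnormality is
  longer-lived.
* Observation-level DeLong inference treats observations as independent,
  but longitudinal ward data are clustered: all of a patient's observations
  share a baseline, and all positive labels come from the few event
  patients. With the generator's default between-patient baseline share,
  the 95% CI for a null (zero-drift) AUC covers 0.5 in roughly 70–90% of
  replicates rather than 95%. This anti-conservatism applies equally to
  real-data analyses that use observation-level DeLong tests; a
  patient-level bootstrap is the appropriate remedy when formal coverage
  matters.
* The infection rule is a specific EHR operationalization; it will miss
  infections treated without blood cultures and cannot distinguish
  prophylaxis continued for other reasons.
* Scores computed from EHR snapshots may differ from hand-calculated
  bedside scores, particularly in how missing and stale values are handled;
  the `completeness` field makes the former visible.
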