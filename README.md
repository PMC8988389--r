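# obsews

Early warning score comparison for obstetric ward patients.

Hospitals monitoring antepartum and postpartum wards choose among several
bedside early warning systems: general aggregate scores (MEWS, NEWS) that
sum points over vital-sign threshold bands, and obstetric trigger systems
(MEOWS: one red or two yellow flags; MEWT: one severe or two non-severe;
MEWC: any single criterion). Their comparative accuracy matters because
deterioration (ward-to-ICU transfer or death) is rare — on the order of 2 in
1,000 admissions — so small accuracy differences translate into large
false-alarm differences. `obsews` implements the five rule-based systems
over longitudinal EHR event streams, phenotypes the deterioration composite
and an antibiotic/blood-culture infection criterion, and compares all
systems in an observation-level, forward-looking framework:

* each ward observation *t* is labeled by whether the patient's first
  outcome event falls in (*t*, *t* + 24 h];
* discrimination is the AUC under the midrank (ties = ½) estimator,

  AUC = Pr(S⁺ > S⁻) + ½ Pr(S⁺ = S⁻),

  with DeLong structural-component variance and paired DeLong z-tests for
  head-to-head comparisons;
* accuracy tables (sensitivity, specificity, PPV, NPV at every threshold)
  and efficiency curves (alert fraction vs sensitivity) quantify the
  alarm-burden trade-off;
* cohort characteristics are summarized as median (IQR) and n (%) by
  outcome group with rank-sum / chi-squared comparisons.

Because obstetric EHR data are protected, the package includes a seeded
synthetic cohort generator (obstetric baseline distributions, pre-event
physiologic drift, antibiotic/culture event streams, ward→L&D→ICU transfer
chains) so the full pipeline runs end-to-end from nothing. A pluggable
continuous risk-model interface with a random-forest surrogate stands in
for proprietary machine-learning scores.

## Worked example

```r
library(obsews)

res <- run_pipeline(run_config(sim_config(n_patients = 300, seed = 42),
                               outdir = "run42"))
res$comparison$auc[, c("system", "auc", "ci_lower", "ci_upper", "n_pos", "n_neg")]
#> # A tibble: 5 × 6
#>   system   auc ci_lower ci_upper n_pos n_neg
#> 1 NEWS   0.661    0.578    0.743    58  6597
#> 2 MEOWS  0.621    0.547    0.694    58  6597
#> 3 MEWS   0.616    0.541    0.690    58  6597
#> 4 MEWT   0.580    0.517    0.642    58  6597
#> 5 MEWC   0.480    0.446    0.514    58  6597
```

The 300 simulated encounters yield 6,655 ward observations, 11 detected
deterioration events and 58 positively labeled observations (within 24 h of
an event). Each AUC row is that system's probability of ranking a
pre-deterioration observation above an event-free one; at this small n the
confidence intervals are wide and the tie-heavy single-parameter MEWC sits
near chance. Pairwise differences come with DeLong p-values:

```r
head(res$comparison$delong[, c("system_a", "system_b", "difference", "p_value")], 3)
#>   system_a system_b difference   p_value
#> 1 MEOWS    MEWC        0.140   0.0000574
#> 2 MEOWS    MEWS        0.00481 0.826
#> 3 MEOWS    MEWT        0.0410  0.147
```

`run_pipeline()` writes `auc.csv`, `delong_matrix.csv`,
`threshold_table.csv`, `efficiency_curve.csv`, `cohort_summary.csv`,
`scores.csv`, `outcomes.csv` and a `manifest.json` with per-stage counts and
file checksums; `render_report()` turns the bundle into a markdown summary,
and `plot_auc_forest()` / `plot_efficiency_curves()` draw the standard
figures. A thin command-line wrapper lives at `inst/cli/obsews`
(`obsews simulate|run|report`).

Individual pieces are exported on their own: `read_cohort()` /
`validate_cohort()` / `assemble_snapshots()` for data handling,
`score_mews()` … `score_mewt()` and `load_score_config()` for scoring
(thresholds fully overridable via YAML), `detect_deterioration()` /
`detect_infection()` for phenotyping, and `compute_auc()` /
`delong_compare()` / `threshold_metrics()` / `efficiency_curve()` for the
statistics.

See `vignettes/obsews-methods.Rmd` for the models, assumptions, default
parameters, and known limitations.

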