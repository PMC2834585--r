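# adherr

Adherence and attendance indicators for antiretroviral therapy (ART),
computed from the routine records that African HIV clinics already keep:
pharmacy dispensing logs, clinic visit/attendance logs, and CD4 laboratory
results. The package is for epidemiologists and HIV-program analysts who
want to monitor treatment adherence — at the patient or facility level —
without electronic pill monitors or research-grade interviews, and to check
that record-derived indicators actually track clinical benefit.

## What it computes

From each patient's event log, cumulatively from ART initiation (day 0) to
any "as-of" day *t* (the window is `[0, t)`, half-open):

**Dispensing-based adherence**

- *Percent of days covered.* Dispensed supply accumulates in a pool
  (early-refill carryover included); one day of supply is consumed per day;
  day *d* is covered iff the pool is positive entering *d*:
  `PDC(t) = 100 · #{covered days} / t`.
- *Treatment gap.* The longest run of consecutive uncovered days; the gap
  flag is strict: `max gap > 30` days. Days after the last supply runs out
  count, so a patient who stops refilling accrues a gap.

**Self-reported adherence** (codes recorded at visits: 1 = perfect,
2 = good, 3 = poor): the running mean of codes, plus "ever reported poor"
and "ever reported less than perfect" flags. Facilities that record only a
2-level scale are excluded from self-report analyses.

**Appointment keeping**: percent of visits on/before the scheduled date and
within 3 days after it; and a schedule-free proxy — percent of visits
arriving on/before the expected finish date of the *previous* visit's
supply (deliberately without carryover, so it is computable where scheduled
dates are not).

Validation follows the study design the package implements: pairwise
correlations among the measures at the index visit (the visit nearest day
180) using Pearson's *r* for continuous pairs and Kendall's tau-b
otherwise; a Gaussian GEE of weight change on each indicator (patient as
cluster, exchangeable working correlation, bias-corrected sandwich
variance, first 270 days); and OLS for CD4 change between the baseline
count and a follow-up test in days 91–270. A seeded synthetic-cohort
generator with a single latent adherence propensity per patient makes the
whole pipeline testable end to end without patient data.

## Worked example

```r
library(adherr)

g <- generate_cohort(cohort_config(n_patients = 488), seed = 2026)
elig <- screen_eligibility(g$cohort)
elig
#> <eligibility_report> 488 included / 0 excluded of 488 screened

snaps <- cohort_snapshots(g$cohort, at = "index", include = elig$included)
snaps[1:3, c("patient_id", "asof_day", "pct_days_covered", "gap_gt30", "avg_selfreport")]
#>   patient_id asof_day pct_days_covered gap_gt30 avg_selfreport
#> 1 P00001          171              100 FALSE              1.17
#> 2 P00002          170              100 FALSE              1
#> 3 P00003          178              100 FALSE              1

panel <- build_weight_panel(g$cohort, include = elig$included)
fit_weight_model(panel, indicator = "coverage_band")
#> <adherence_model> gee_weight | indicator: coverage_band
#>   n = 488 patients, 4046 observations ( 0 patients excluded )
#>                       term estimate  p.value conf.low conf.high
#>          coverage_band<80%   -3.335 1.68e-07   -4.221    -2.449
#>   coverage_band80% to <90%   -0.509 1.19e-01   -1.155     0.137
#>  coverage_band90% to <100%   -0.309 1.63e-01   -0.746     0.128
```

Reading the fit: relative to patients with 100% of days covered, patients
whose coverage fell below 80% gained about 3.3 kg less over the first nine
months of treatment (95% CI −4.2 to −2.4); the intermediate coverage bands
show small, non-significant deficits. `fit_cd4_model()` does the analogous
cross-sectional analysis for CD4 change, `correlation_matrix()` gives the
indicator inter-correlations, and `adjusted_prediction()` produces
typical-patient or population-averaged adjusted gains. `run_pipeline()`
chains every stage and writes the five report tables plus a reproducibility
manifest.

Each patient's dispensing history can also be inspected directly:

```r
tl <- build_coverage_timeline(
  dplyr::filter(g$cohort$dispensings, patient_id == "P00007"),
  initiation = g$cohort$patients$initiation_date[7],
  asof = g$cohort$patients$initiation_date[7] + 270
)
tl
#> <coverage_timeline> window [0, 270 ) days; 4 covered interval(s); 75.9 % of days covered
plot_coverage_timeline(tl)
```

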