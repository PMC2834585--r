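---
title: "Measuring ART adherence from routine clinic records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ART adherence from routine clinic records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherr)
```

adherr implements a complete adherence-measurement analysis for
antiretroviral therapy (ART) programs that run on paper-and-ledger routine
data: it derives eight dispensing-, self-report-, and attendance-based
indicators from clinic event logs, estimates how the indicators relate to
one another, and validates them against early clinical response (weight
gain and CD4 recovery). This vignette is the package's account of the
methods: the exact measure definitions and their conventions, the
statistical models, the synthetic-cohort generator that stands in for
clinic data, and the places where the design was genuinely open and a
choice had to be made.

## 1. The indicator engine

All measures are cumulative from ART initiation. Initiation day is day 0,
and a measure "as of" day $t$ is computed on the half-open window $[0, t)$:
the as-of day itself — typically a visit, with its own dispensing — is not
part of the window. This avoids crediting a refill for coverage it has not
yet provided; the alternative (closing the window at $t$) changes percent
of days covered by at most one day and is flagged as a sensitivity concern,
not implemented.

**Coverage (percent of days covered).** Dispensed medicines accumulate in
a supply pool on the dispensing day; the patient consumes one day of supply
per day while the pool is positive; day $d$ is covered iff the pool is
positive entering $d$. Early refills therefore *carry over*: a patient who
refills ten days early banks ten days against future lateness. The
implementation is a closed-form interval recursion (coverage end
$E_j = \max(E_{j-1}, d_j) + s_j$, gap $g_j = \max(0, d_j - E_{j-1})$),
which the test suite proves equal to a literal day-by-day pool simulation
on 1,000 random histories. For multi-component regimens the effective
supply of one dispensing day is the *minimum* days-of-supply across
components: therapy is only covered while every drug is on hand. (Same-drug
rows on one day sum; the source records are silent on intent, and the
minimum is the conservative reading.)

**Treatment gap.** The longest maximal run of uncovered days in the
window. The flag is strict — a gap qualifies only when *more than* 30 days
long — and the run after the last exhausted supply counts, so a patient who
simply stops refilling accrues a gap.

**Self-reports.** Visit codes 1/2/3 (perfect/good/poor). The engine keeps
the running mean, plus ever-poor and ever-less-than-perfect flags.
Facilities recording only a two-level scale (good-or-fair vs. poor) are
structurally different, so those patients carry absent self-report fields
and drop out of any self-report analysis; their dispensing and attendance
measures are unaffected.

**Appointment keeping.** Percent of visits on/before the scheduled date,
and within three days after it, both over visits that *have* a recorded
scheduled date (no imputation). The schedule-free alternative — percent of
visits arriving on/before the expected finish of the previous visit's
supply — deliberately ignores carryover from earlier visits; it is a field
indicator designed for settings without appointment books, and its known
bias (overstating how often patients truly run out) is part of its
definition. The asymmetry with the coverage measure is intentional.

**Index visit.** Cross-sectional summaries are taken at the visit nearest
day 180, an equidistant tie going to the earlier visit; the same
nearest-with-earlier-tie rule picks the follow-up CD4 test in days 91–270.
Snapshots are refused beyond `min(18 months, data collection date)`.

Percentages are carried at full floating precision internally; report
tables round to one decimal, model coefficients to three.

## 2. Validation models

**Weight.** Weight change from baseline is modeled at every visit in the
first 270 days with a Gaussian generalized estimating equation: patient as
cluster, exchangeable working correlation re-estimated by moments, and
robust (sandwich) variance, so inference does not depend on the working
correlation being right. Each adherence indicator enters *one at a time*,
alongside time since initiation and the full covariate set (gender, age
band, marital status, clinic location, baseline CD4, baseline weight, WHO
stage 3–4, TB at initiation, side-effects/OIs to date, number of distinct
regimens to date, ever on a protease inhibitor). Time is coded as a
categorical month index (30-day bins, nine levels), matching how adjusted
monthly gains are displayed; a continuous-linear coding is available via
`time = "linear"`.

No GEE implementation ships in this environment, so `gee_gauss()` is part
of the package and is oracle-tested against a dense per-cluster reference
implementation. Two small-sample choices matter and are defaults for a
reason:

- the *Mancl–DeRouen bias-corrected sandwich* replaces the classic one.
  The rare indicators here (a >30-day gap touches only ~2–4% of patients)
  concentrate information in a handful of clusters, where the classic
  sandwich is biased downward; and
- Wald intervals use *t* quantiles with Satterthwaite-style effective
  degrees of freedom per coefficient (the squared-contribution ratio
  $(\sum_i w_i)^2 / \sum_i w_i^2$ over cluster influences). For a rare
  binary exposure the effective df is close to the number of informative
  clusters (single digits to tens), not the number of patients.

In null simulations (200 replicates, 488 patients) these two choices take
the empirical 95%-interval coverage of the gap effect from 0.885 (classic
sandwich, normal quantiles) to 0.95. The classic estimator remains
available (`sandwich = "classic"`) and is what the dense-reference oracle
test checks.

**CD4.** Change from the baseline count to the selected follow-up test is
cross-sectional, so ordinary least squares with the same covariates
(baseline weight replaced by days-to-test) is used. The categorical
coverage indicator uses bands `<80%`, `80–<90%`, `90–<100%` with exact
`100%` as the reference.

**Adjusted predictions.** `adjusted_prediction()` supports a fixed
typical-patient profile and population-averaged standardization (set the
indicator level, average the linear predictor over the observed covariate
rows). By linearity, the population mode equals the mean of per-patient
predictions, which is how it is tested.

**Correlations.** Pearson's product-moment coefficient for
continuous-continuous pairs, Kendall's tau for pairs with a binary member.
The tie-corrected tau-b is used: with binary measures, uncorrected tau is
degenerate, so tau-b is forced in practice — recorded as an assumption, not
a reproduction. The estimate is delegated to `stats::cor.test` and proven
equal to exhaustive concordant/discordant pair counting with tie correction
on hundreds of random vectors ($n \le 50$); p-values use the two-sided
normal approximation with tie-corrected variance. An exact
full-enumeration permutation p-value is available under `exact = TRUE` for
$n \le 7$ (enumeration beyond that is not tractable and the function says
so rather than approximating silently).

## 3. The synthetic cohort generator

The original clinic records are not distributable, so the package ships a
generator whose output has the statistical structure the analysis assumes,
and every pipeline stage is tested against it.

**Behavioural core.** The source analyses report that dispensing,
self-report, and attendance measures are positively inter-correlated; no
generative model is given. The generator's central choice is a *single
latent adherence propensity* per patient, $z_i \sim N(0, 1)$, moving three
behaviours jointly through logistic links: the probability of a
perfect (0–3 days early) refill (default marginal 0.93 per visit), of
effectively skipping an appointment (0.04; the visit then happens 10+ days
late), and of one long treatment interruption (0.027, lasting
31 + Geometric(mean 15) days). Ordinary lateness is 1 + Geometric(mean 4)
days. Visits are scheduled every 30 days from the previous *actual* visit,
each attended visit dispensing 30 days of supply. These defaults were
calibrated once to the anchor distribution of the study population —
roughly 63% with perfect coverage, ~3% with a long gap, ~73% reporting
perfect adherence at every visit, ~20% attending fewer than 80% of visits
on time — and are not adjusted per analysis.

**Self-report optimism.** A true lapse since the previous visit is still
reported as "perfect" with probability 0.8, reflecting the well-documented
optimism of self-reports relative to dispensing records; lapse-free visits
report perfect with probability 0.97. Two-level facilities (default: 4 of
16) record only good-or-fair vs. poor.

**Outcomes.** Weight follows a concave piecewise-linear monthly gain curve
summing to 3.9 kg at month 6 under full adherence and flat after month 9,
with band penalties (−2.24 kg below 80% coverage, −0.51/−0.52 kg in the
middle bands) and a −3.26 kg penalty once a >30-day gap has occurred, all
applied to the *cumulative* indicator state at each visit. Residuals are
exchangeable within patient: total SD 4.5 kg split by $\rho = 0.5$ — the
within-patient correlation of repeated weights is not reported anywhere, so
this is a free choice, flagged here. The follow-up CD4 test date is uniform
on days 91–270; the change is 148.8 cells/mm³ under full coverage with
band penalties (−97.3 below 80%) and residual SD 120. Follow-up counts are
floored at zero (counts cannot be negative); this truncation mildly
attenuates recovered large negative CD4 effects (a configured −97 penalty
recovers ≈ −91 on average across 200 replicates — within the tolerance the
recovery tests use, and an inherent feature of bounded outcomes rather than
an estimator defect).

**Eligibility by construction.** The study this emulates could only
include patients still in care through month 6, so the generator caps
per-visit lateness at 55 days within the first two quarters and starts
interruptions no earlier than the fifth scheduled visit. Every
default-config patient therefore passes the screen — deliberate emulation
of an *included* cohort. The corollary is stated under limitations.

**Determinism.** All randomness flows from one seed;
identical (config, seed) pairs produce byte-identical written cohorts, and
the full pipeline is byte-identical across runs.

**What passing tests do and do not show.** The generator reproduces the
marginal structure, the sign pattern of indicator inter-correlations, and
configured effect sizes. It does not model mortality or loss to follow-up,
early treatment abandonment, viral load, drug resistance, facility-level
clustering, seasonal supply ruptures, or data-quality pathologies beyond
parse-level rejects. Tests passing on this cohort demonstrate that the
*computations* are correct and the *estimators* recover known truth under
realistic event-log structure — not that real clinic data are this clean.

## 4. Eligibility screen conventions

Criteria apply in fixed order (age ≥ 18; no prior ART, PMTCT exempt; a
visit in each of days 1–91 and 92–182; a self-report in those two quarters;
dispensing data; a CD4 count within 91 days before initiation and one in
the 18 months after), and an exclusion is attributed to the *first* failed
criterion, so per-criterion fractions can sum to more than the overall
exclusion rate. Quarter boundaries in days are a convention (91-day
quarters); the source reports exclusion percentages without stating the
screening denominator, so the package exposes fractions over its own
screened input and does not claim to reproduce published screening
denominators. Pill counts — accepted as an alternative to self-reports in
the original criteria — are out of scope throughout (they were dropped from
the source analysis for data-quality reasons), so criterion four is
satisfied by self-reports alone.

## 5. Numerical conventions and degenerate inputs

- Dates are calendar days; all arithmetic is whole days, no time-of-day.
- Coverage at `pct_days_covered()` never exceeds 100 regardless of
  oversupply; an empty window is an error, as is a dispensing before
  initiation; dispensings on/after the as-of day are ignored with a note.
- Visits without scheduled dates leave timeliness absent (never zero);
  zero-denominator percentages are absent, with reasons carried in
  correlation cells.
- Ties: index visit and CD4-test selection break equidistant ties to the
  earlier date.
- The GEE refuses rank-deficient designs and constant indicators rather
  than silently dropping terms; `lm`-side aliasing surfaces as missing
  terms in the tidy output.
- File dialect: one CSV per event type, ISO-8601 dates (validated
  strictly — `31-02-2007` is a reject, not year 31), UTF-8, header row
  mandatory, absent values as empty fields. Malformed rows go to a rejects
  report with reasons; a missing mandatory column is a hard error naming
  the column.

## 6. Problem sizes used by the test suite

Unit tests run on hand-built fixtures and cohorts of 20–600 patients. The
property and acceptance tests use the sizes the properties demand: 1,000
random histories for the coverage oracle, 500 vectors for the tau oracle,
200 replicates of 488 patients (the study's scale) for parameter recovery
and null CI coverage, and single cohorts of 10,000 for marginal fidelity
and correlation sign structure. The full suite completes in a few minutes
on one core.

## 7. Known limitations

- The generator cannot exhibit — and the models therefore cannot be tested
  against — informative dropout or early adherence failure; the emulated
  design conditions on surviving in care to month 6.
- Exchangeable within-patient weight correlation (ρ = 0.5) and the
  logistic propensity links are modelling conveniences, not estimates.
- The exhaustion-timeliness indicator is biased by construction (no
  carryover) and should be read as an attendance proxy, not a coverage
  estimate.
- Correlation cells are reported without multiple-testing adjustment,
  matching the descriptive use of the matrix.
- Month-binned time and the exchangeable working correlation are
  configurable assumptions; the underlying study does not state its
  choices, and no claim of exact reproduction is made.
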