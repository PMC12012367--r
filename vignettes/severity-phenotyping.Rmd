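---
title: "Severity phenotyping of diverticular disease and social-needs analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity phenotyping of diverticular disease and social-needs analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

divertiphen implements a rule-based phenotyping algorithm that grades the
severity of colonic diverticular disease from OMOP-style electronic health
record event tables, together with the chart-review concordance statistics
used to validate such algorithms and a social-determinants-of-health (SDOH)
analysis pipeline. This vignette explains the rules, the statistical
machinery, the tunable parameters, and the design decisions taken where the
underlying methodology leaves room for choice.

## The phenotyping rules

Diverticular disease spans a wide severity spectrum, from incidental
diverticulosis to recurrent inpatient or operative diverticulitis.
Diagnosis codes alone are unreliable for grading it — code-only definitions
of complicated diverticulitis have shown positive predictive values as low
as about 0.67 — so case ascertainment here requires objective confirmation:

* **Index pair.** A person becomes a confirmed case only when a diverticular
  diagnosis code (ICD-9-CM or ICD-10-CM) is dated within **7 days after** an
  abdominal CT scan or a lower gastrointestinal endoscopy. "Within 7 days
  after" is implemented as inclusive day offsets 0..7, with the diagnosis
  never before the confirming study: same-day coding after imaging is the
  norm, and the directionality keeps presumptive pre-imaging codes from
  qualifying. When several pairs exist, the earliest by diagnosis date, then
  confirmation date, is the index pair; remaining ties break on code text so
  assignment is deterministic under any row ordering.
* **Classes.** Confirmed cases are split by a fixed decision order:
  1. no diverticular codes at all → `control`;
  2. diverticular codes but no index pair → `excluded`;
  3. no diverticulitis codes ever → `diverticulosis`;
  4. a qualifying procedure or more than one inpatient diverticulitis
     admission → `operative_or_recurrent`;
  5. otherwise → `mild_diverticulitis`.

  "Only diverticulosis codes" is a **global** condition: one diverticulitis
  code anywhere in the record, however old, removes a person from the
  diverticulosis class.
* **Admission counting.** An inpatient diverticulitis admission is a
  distinct inpatient encounter carrying at least one linked diverticulitis
  code. Overlapping or date-adjacent stays (gap of 0 days) are merged before
  counting, so inter-facility transfers cannot fabricate recurrence.
  Emergency-department visits are a separate care setting and never count as
  admissions; unknown visit settings are conservatively treated as
  outpatient (with a logged diagnostic), so bad metadata can never create
  the most severe class. Diverticulitis codes without an encounter link
  count toward no admission and are tallied in a diagnostics report.
* **Qualifying procedures.** Colectomy, percutaneous drain placement, and
  intestinal fistula repair qualify when "performed for diverticulitis".
  The source description does not operationalize that phrase, so the package
  exposes it as a knob: a diverticulitis code in the same encounter always
  qualifies, and otherwise a code within ±`link_window_days` (default 30
  days) of the procedure date does. The window is symmetric because the
  indication may be coded at the pre-operative visit or at discharge.
* **The excluded bucket.** Persons with diverticular codes but no
  confirming study are neither cases nor controls. Relabelling them as
  controls would contaminate NPV-style evaluations of the control class, so
  they are kept in an explicit `excluded` class.

Two points left open by the source description were resolved as follows:
the 7-day relation is evaluated on **date proximity**, not on linkage of
the diagnosis to the confirming encounter (only the temporal relation is
stated); and a diverticulitis code in **any** position of an inpatient
encounter qualifies the admission (primary-position restriction is not
stated).

All code matching is dot- and case-insensitive and goes through a named,
user-editable code-set registry; a code matching both the diverticulosis
and diverticulitis sets is rejected at load time because the severity logic
requires a partition. The shipped registry is an illustrative demo —
institutional users must review the CT/endoscopy/procedure lists.

## Cohort inclusion

The analysis cohort keeps cases whose index diagnosis lies within
`window_years` (default 5 years, i.e. 1826 days) of the chosen inclusion
survey date, in either direction, and drops persons lacking that survey
date. Sensitivity variants narrow the window to 2.5 years or switch the
anchoring survey (earliest, healthcare-access, or SDOH survey); the
sensitivity driver rebuilds the cohort from raw assignments for each
variant.

## Chart-review concordance

Validation mirrors a blinded chart-review design: a seeded, per-class
uniform sample (200 charts per class in the original design), per-class
one-versus-rest PPV and NPV against a reference labelling, Cohen's kappa
between two raters, and the percentage of records per class on which
reviewers disagreed. Design choices:

* When reviewers disagree, the consensus reference is the majority vote;
  residual ties fall to the first reviewer and are flagged. (The original
  iterative review-and-discussion process is not mechanizable.) Because it
  is unstated whether published PPV/NPV used the blinded expert or the
  consensus as reference, reports include both.
* Kappa is computed pairwise between two raters, not as a pooled
  multi-rater statistic. Note that the degenerate case "expected agreement
  1 with observed agreement below 1" cannot actually occur — expected
  agreement 1 forces both raters onto the same single category — so the
  defensive flag for it is unreachable; perfect agreement returns 1 by
  convention.
* Metrics with zero denominators (a class never assigned, or always
  assigned) are reported as undefined with a reason, never as 0.

## SDOH scoring

Twelve social variables are scored from item-level survey responses:
Hunger Vital Sign (2-item screen; positive iff either item is endorsed
"often true"/"sometimes true"), Brief Health Literacy Screen (3 items,
sum in [3, 15]), the Ross-Mirowsky perceived neighborhood physical disorder
subscale (6 items, mean in [1, 5], low is favorable), a modified MOS Social
Support Survey (8 items, mean in [1, 5], high is favorable), single-item
housing instability and housing quality, the two delayed/can't-afford-care
items (either endorsement is the barrier), insurance, annual income,
highest education, English proficiency, and employment.

The **top-box** conversion binarizes scored instruments: 1 (no barrier)
only when *every* item is answered at its most favorable level; any less
favorable answered item — or a missing item among answered ones — gives 0,
and an all-missing instrument is missing. Categorical variables use
designated barrier levels instead (income below 50k; education below high
school; no/unaccepted insurance; limited English; out of work), matching
the published table groupings. Both routes are available because it is not
stated whether the original top-box applied to categorical items.

The composite **unmet social need** flag is 1 if any of food insecurity,
housing instability, or delayed/can't-afford care is endorsed; 0 only when
all three are observed absent; missing otherwise.

**Deprivation quintiles** are cut at the 20/40/60/80th percentiles of the
analysis cohort's non-missing deprivation-index values (quintile 5 = most
deprived; boundary ties go lower). The published index is consumed
pre-computed without stated cut points, so cohort-empirical quintiles are
the default and fixed external cut points are accepted through an argument.
**Fold enrichment** of a barrier is the ratio of its within-variable share
in quintile 5 to quintile 1; the within-variable totals cancel, so it is
computed as `count[Q5]/count[Q1]`, with a zero reference quintile reported
as an undefined sentinel rather than infinity.

## Descriptive tables and the adjusted model

Continuous variables are summarised as median (IQR) and compared with
Kruskal-Wallis (Wilcoxon rank-sum for two groups); categorical variables as
frequency (percent of the variable's non-missing denominator) with
Pearson's chi-squared test. Cell counts from 1 up to the suppression
threshold (default 20) are flagged and masked **in displayed output only**;
internal computation always uses true counts, suppression is idempotent,
and zero counts are displayed — the policy exists to protect small
non-zero cells, and masking structural zeros would only distort tables.

The adjusted model is a maximum-likelihood logistic regression of
operative/recurrent inpatient diverticulitis versus diverticulosis (mild
cases and controls are excluded rather than pooled — the contrast is the
most against the least severe case group) on the binary unmet-need flag,
age, sex at birth, BMI, Charlson Comorbidity Index, insurance, education
and income, with unmet-need-by-income and unmet-need-by-education
interactions. Preprocessing:

* covariates with under 20% missingness are imputed by bootstrap-aggregated
  decision trees (25 `rpart` trees per covariate, trained on the complete
  covariates; numeric targets average the trees, categorical targets take a
  majority vote); covariates at or above 20% are left missing and flagged;
  the outcome and the exposure are never imputed;
* near-zero-variance filtering drops factors whose dominant level
  outnumbers the runner-up more than 19:1 and collapses levels below 1%
  prevalence into the reference; one member of any predictor pair with
  |r| > 0.90 (on the indicator expansion) is dropped, the later column by
  convention, with both members reported;
* variance inflation factors are computed on the pre-interaction design
  matrix as 1/(1 − R²) — exactly 1 for an orthogonal design, independent of
  outcome weighting.

Odds-ratio intervals are Wald by default (the original interval method is
unstated); profile-likelihood intervals are available behind an argument.
Interaction p-values are Wald tests on the interaction coefficients.
Separation or non-convergence sets an explicit flag on the result — no
silent coefficient clipping. Reference levels: no unmet need, female,
income above 100k, at least some college, insured.

## The synthetic cohort generator

Every module is testable without access to restricted data because the
generator builds cohorts whose ground truth is known by construction. Each
severity class template is the inverse of one decision branch (e.g. mild =
confirmation plus a diverticulitis code at a uniform 0–7-day offset and at
most one inpatient admission; operative/recurrent = either two disjoint
coded admissions 60 days apart or a linked procedure within the 30-day
window), so the phenotyper must recover the target class with 100%
agreement — the generator's defining test.

Default calibration follows the published cohort: class mix control 0.645,
diverticulosis 0.24, mild 0.05, operative/recurrent 0.0125, excluded
0.0525, which puts ~5% of the modeled diverticulosis + severe pool in the
severe class; quintile-graded barrier probabilities giving a composite
unmet-need prevalence near 40% (38–50% across case groups in the published
tables); and a survey-to-index lag uniform on ±4 years, so the 5-year
inclusion window keeps nearly all cases and the 2.5-year sensitivity window
strictly fewer. The severe-versus-diverticulosis outcome is drawn from a
configurable logistic model (default unmet-need coefficient log 1.61,
modest covariate effects); the intercept is calibrated numerically so the
marginal severe share matches the class-mix target, and a configuration
whose implied prevalence is degenerate errors out before generation.
Survey missingness is missing-at-random by default, masking the three
unmet-need component instruments jointly per person (emulating a skipped
survey block) at a base rate of 0.30 with higher masking odds at low income
(log-odds +0.65) and low education (+0.5), reproducing in expectation the
published pattern that persons with missing social-needs data skew toward
lower income and education.

What the generator does **not** emulate: realistic ICD code frequency
distributions beyond what the phenotyper reads, clinical-note text (so
misassignment caused by outside-hospital records mentioned only in notes is
out of reach), correlated comorbidity structure, or informative visit
timing. Passing round-trip tests therefore demonstrates rule correctness
and pipeline integrity, not real-world PPV.

One engineering deviation: the generator uses a single seeded RNG stream
with a fixed field-major draw order rather than per-person counter-derived
sub-streams. Output is exactly reproducible for a given (seed, cohort
size); changing the cohort size redraws the cohort.

## Numerical choices and problem sizes

* Dates are calendar dates; all intervals are whole days; a year is
  365.25 days.
* Timeline order is total: person, date, event class, code, encounter id.
* Quintile boundary ties go to the lower quintile; `quantile()` type 7.
* The intercept calibration solves `mean(plogis(lp + c)) = target` by
  Brent's method on [−40, 40] at tolerance 1e−8.
* Separation is declared when the fit fails to converge, any |coefficient|
  exceeds 15, or any standard error exceeds 100.

The test suite exercises the generator/phenotyper round trip on ≥1000
timelines per class, parameter recovery on 200 replicates of n = 20 000
with ~5% outcome prevalence (mean recovered unmet-need OR within 5% of the
generating 1.61, 95% interval coverage ≥90% over 100 replicates), and fold
enrichment against generating ratios at n = 50 000 within binomial
tolerance. These sizes were chosen to make Monte-Carlo error small relative
to the tolerances being asserted while keeping the default run fast on a
laptop.

## Limitations

The severity classes deliberately differ from the clinical
complicated/uncomplicated standard (modified Hinchey staging); isolating
complicated diverticulitis would require restricting the severe class to
operative cases and extending the code sets. The shipped code lists and
instrument definitions are demonstrative stand-ins for institutional lists.
Confidence intervals for PPV/NPV, multi-rater kappa, survey weighting, and
multiple-imputation pooling are out of scope.
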