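---
title: "Validating a claims-based DKA case definition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a claims-based DKA case definition: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkaclaims)
```

## What this package estimates

A *computer case definition* is a deterministic rule over coded claims that
flags probable cases of a clinical outcome without reading charts. Its
usefulness for pharmacoepidemiology hinges on the positive predictive value
(PPV): of the admissions the rule flags, how many are real? `dkaclaims`
implements the full validation pipeline for an incident-DKA definition in a
Medicaid-like population of children and youth (ages 6–24) initiating
antipsychotics or control psychotropics, and estimates PPV with Wilson
score intervals, overall and by subgroup.

Sensitivity is deliberately out of scope: a validation sample drawn from
flagged cases carries no information about cases the definition misses, so
no sensitivity estimate is possible from this design.

## The pipeline and its rules

### New-user cohort

A dispensing of a study drug (antipsychotic, mood stabilizer, ADHD drug,
antidepressant, benzodiazepine) *qualifies* when the 365 days strictly
before it contain no study-drug dispensing. The source description of the
washout is internally inconsistent — it asks both for no fill "more than 90
days prior" and for 365 clean prior days — and the two cannot both be read
literally; we implement the stricter, conventional new-user washout of 365
days (`washout_days` in `cohort_config()` lets a user adopt the 90-day
reading instead). Any study-drug class breaks the washout for any other
(whether a control-drug fill should reset the washout for antipsychotic
qualification is genuinely undecidable from the design description; treating
all study drugs symmetrically is the conservative choice and is what the
single-parameter washout expresses). Fills of class `other` neither qualify
nor break the washout. Same-day fills do not disqualify each other, because
the window is *strictly* before the fill date.

Eligibility at the qualifying fill requires: completed age 6–24; merged
enrollment spans covering the entire 365-day baseline window; at least one
baseline outpatient visit (our operationalization of "adequate health care
utilization" — it is a qualitative phrase, so the check is a config switch,
`require_baseline_visit`); no baseline diagnosis in the psychosis, diabetes,
pregnancy, PCOS or life-threatening-illness code sets; and no inpatient stay
overlapping the 30 days before the fill. All failures are evaluated and
reported together (`failed_criteria`), never short-circuited — essential
when debugging a cohort that is smaller than expected. A person enters at
their first qualifying fill that passes *all* criteria.

Follow-up runs from the day after the fill to the earliest of: study end;
the 25th birthday; the end of the continuous enrollment span (spans merge
when adjacent within one day); death; an exclusion diagnosis appearing on a
claim ("criteria failure" — re-evaluated at claim dates only, since
criteria can only change when new claims appear); or 365 days after the
last day of *current use*. Current use is the chain of dispensings in which
each fill lands before the running supply end plus the 365-day post-use
extension (plus a configurable grace, default 0): a refill during the
extension resumes use, because the person is still under follow-up when it
happens. Date ties between terminating events are broken by a fixed
precedence — death, disenrollment, age 25, criteria failure, use lapse,
study end — so output is deterministic.

### Case finding and the index date

Potential cases are inpatient encounters during follow-up with *any*
diagnosis position in the DKA family — ICD-9 250.1x or ICD-10 E10.1–E14.1.
Outpatient and emergency-only claims never trigger. "Incident" means the
first such admission with no DKA-coded claim of any setting during the
baseline window; the baseline diabetes exclusion already removes prevalent
diabetes, and the explicit check makes incidence testable on hand-built
inputs. Same-day duplicate admissions break ties by lowest encounter id.

The index date is the admission date unless an emergency-department claim
with any diabetes code (ICD-9 250.x) exists on the *day immediately before*
admission, in which case the index date is reset to the emergency visit.
The reset code set is ICD-9 only by default (`er_reset_icd10 = TRUE`
extends it to E10–E14) because the reset rule is defined on ICD-9; the
flagging code set, by contrast, always includes both systems.

One interaction deserves note. Because any diabetes diagnosis is an
exclusion criterion, the flagging admission itself terminates follow-up on
its own date — and under the reset rule the terminating claim can be the
prior-day emergency visit. An encounter therefore counts as a case when its
*index date* lies within follow-up; this keeps the event that ends
follow-up countable, which is the standard reading of an incident-outcome
design, while an admission genuinely after follow-up (e.g. after
disenrollment) is still rejected.

### ICD matching semantics

Codes are canonicalized to dotted form (`25011` → `250.11`) and matched
dotlessly, so formatting never matters. A pattern is a truncated prefix
(`250.1` accepts the whole 250.1x family), and `x` is a one-digit wildcard
expanded at digits 0–9 — `E1x.1` therefore covers E10.1–E19.1 as prefixes.
The diabetes families of interest stop at E14, and no E15–E19 code has a
`.1` child that could collide, so the generic expansion is safe and keeps
the matcher free of system-specific special cases. A code never matches a
pattern from the other code system.

### Adjudication

The gold-standard rule is deterministic: glucose > 250 mg/dL *and*
laboratory acidosis — any pH below its specimen threshold (7.25 venous,
7.30 arterial or capillary) or bicarbonate below 15 mmol/L; all
comparisons strict; missing labs never count. The rule as stated lists a
DKA discharge diagnosis as a third qualifying criterion yet also bars
confirmation without laboratory acidosis; the override must govern (it is
what makes hyperglycemia-without-acidosis cases non-confirmed), so the
default `strict` policy records the discharge diagnosis among
`criteria_met` but never lets it decide. The `dx_fallback` policy confirms
on discharge diagnosis *only* when no pH and no bicarbonate were recorded
at all — acidosis unevaluable rather than absent. "Random blood glucose"
uses the maximum recorded value of the episode (most favorable to
detection, and unambiguous); pH is stored as the per-specimen minimum,
which under the any-of semantics is information-equivalent to the raw lab
list and makes adjudication trivially order-independent. Records whose
charts could not be abstracted are *not adjudicable* — a distinct state
from not-confirmed, excluded from both numerator and denominator.

The two-reviewer workflow of a real validation study is modeled as a single
deterministic rule application; with fully specified numeric criteria there
is no disagreement left to model.

### PPV and Wilson intervals

PPV = x/n over adjudicated cases. The Wilson score interval uses the exact
normal quantile `qnorm(0.975)` ≈ 1.959964 rather than 1.96 — at one-decimal
display rounding both give identical results for every n in this package's
range, and the exact quantile is the correct inversion of the score test.
No continuity correction is applied. Displayed percentages round half-up at
one decimal (`round_half_up()`), matching how such tables are
conventionally printed; full precision is retained in the tibbles. One
consequence: the control stratum of the reference study, 19/21, displays as
90.5% (some published renderings of the same counts print 90.0%, which is
inconsistent with the interval printed beside it — the interval, 71.1 to
97.3, matches 19/21 exactly).

Stratification rules are plain functions from the adjudicated tibble to
level labels; the defaults stratify by exposure (antipsychotic vs control),
age at index (≤ 10 vs 11–24), gender, and ADHD diagnosis. A rule returning
`NA` for any record is an error naming the record, because a partition must
be exhaustive.

## The synthetic data generator

`simulate_claims()` emulates the *structure* of the study setting so that
every pipeline stage is testable without protected data: persons aged 6–24
(ages drawn with a mild skew toward ~11, the reference sample's median);
20% antipsychotic initiators; one qualifying fill per person with
Poisson-many consecutive refills; a baseline outpatient visit for everyone;
tagged ineligible persons violating exactly one criterion each (including
washout violators, whose breaking fill predates the study window so that
the washout is their *only* failure); flagged cases carrying an inpatient
DKA admission during follow-up, in a secondary diagnosis position 40% of
the time, with a prior-day emergency diabetes visit 25% of the time; and a
ground-truth label drawn with probability `true_ppv` (default 0.889, the
working estimate for this definition).

`simulate_abstractions()` draws labs consistent with the truth label. No
lab-value distributions are reported for the real study, so defaults are
clinically plausible shapes chosen once: true cases glucose ~ LogNormal
around 450 mg/dL, venous pH ~ Normal(7.10, 0.08) truncated below the 7.25
threshold, bicarbonate ~ Normal(9, 3) truncated below 15;
hyperglycemia-without-acidosis false positives glucose ~ LogNormal around
350 with pH floored above 7.26 and bicarbonate above 15.5; coding-error
false positives glucose ≤ 250. Only the ordering of draws against the
diagnostic thresholds matters for pipeline correctness, and the truncation
gives a strict separation property: on complete records, adjudication
recovers the truth label exactly, which the tests exploit. The default
false-positive mix puts all mass on hyperglycemia-without-acidosis, the
only mode observed in the reference study. A fraction (default 10%) of
charts is unabstractable, assigned at random — whether real unabstracted
charts differ systematically is unknowable from a validation sample, and
random assignment is the neutral choice.

What the generator does *not* emulate: realistic DKA incidence (the
flagged-case rate `p_case` is a study dial — recovery tests raise it to get
thousands of flagged cases from modest populations), Medicaid enrollment
churn, seasonality, miscoded non-diabetes claims, or correlated
demographics. Passing recovery tests therefore demonstrates that the
*pipeline logic* is correct under known truth, not that the case definition
would achieve any particular PPV on other real data.

The packaged reference study (`dka_reference_study()`) is different in
kind: a deterministic, hand-constructed database whose pipeline output
reproduces the published validation counts (30 flagged, 27 adjudicated, 24
confirmed) and every stratified margin simultaneously. The reported margins
do not uniquely determine the joint stratum table; the fixture fixes one
feasible joint assignment (the three non-confirmed cases are lower-age,
female, with ADHD; one initiated an antipsychotic), which is all that any
of the published figures require.

## Numerical and scale choices

Dates are day-granular throughout; all intervals are closed unless stated
otherwise, matching how claims are dated. Grouped scans in the cohort
builder (washout lags, span merging, use-episode chaining) are implemented
as vectorized operations on sorted tables, so building a cohort of a few
thousand persons takes well under a second; the recovery tests run the full
generate-build-find-adjudicate-estimate loop on populations of 1,600
persons (~1,200 flagged cases) a hundred times within a few minutes. The
statistical property tests use 10,000 binomial replicates for interval
coverage and an exhaustive sweep of all (x, n) with n ≤ 50 against an
independent root-finding inversion of the score test.

## Known limitations

* The validation design estimates PPV only; sensitivity, specificity and
  NPV are not estimable and not offered.
* Procedure codes, revenue codes and real Medicaid extract layouts
  (MAX/TAF) are out of scope; the CSV schemas are deliberately minimal.
* The eligibility code sets are compact research defaults, not exhaustive
  clinical groupers; real studies should supply their own
  `exclusion_codes`.
* The adjudicator consumes already-abstracted structured records; chart
  abstraction itself (and its inter-rater reliability) is outside the
  model.
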