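# dkaclaims

Validation tools for a claims-based (computer) case definition of incident
diabetic ketoacidosis (DKA) in children and youth.

## The problem

Drug-associated DKA — for example after initiation of atypical
antipsychotics — is too rare for clinical trials or prospective cohorts to
quantify. Automated claims databases (Medicaid-like pharmacy, enrollment and
encounter files) are the practical data source, but a diagnosis code on a
claim is not a diagnosis: before DKA can be used as a study endpoint, the
case-finding rule must be validated against medical-record review, and its
**positive predictive value** (PPV) — the proportion of algorithm-flagged
cases the gold standard confirms — estimated with honest uncertainty.

`dkaclaims` implements that whole validation pipeline for pharmacoepidemiologists:

1. **New-user cohort construction** (`build_cohort()`): qualifying
   dispensings of antipsychotics or control psychotropics (mood stabilizers,
   ADHD drugs, antidepressants, benzodiazepines) with a 365-day study-drug
   washout; eligibility screening (age 6–24, continuous baseline enrollment,
   baseline utilization, no baseline psychosis/diabetes/pregnancy/PCOS/
   life-threatening-illness diagnosis, no hospitalization in the prior 30
   days); follow-up from the day after the fill to the earliest of study
   end, 25th birthday, disenrollment, death, criteria failure, or 365 days
   after the last day of current use.
2. **Case finding** (`find_potential_cases()`): inpatient encounter claims
   with any diagnosis position in the DKA code family — ICD-9 250.1x,
   ICD-10 E10.1–E14.1 — during follow-up; first (incident) event per
   person; index date = admission date, reset to the previous day when an
   emergency-department claim with any diabetes code (ICD-9 250.x) sits
   there.
3. **Adjudication** (`adjudicate()`): the deterministic clinical rule —
   random blood glucose > 250 mg/dL **and** laboratory acidosis (pH < 7.25
   venous or < 7.30 arterial/capillary, or bicarbonate < 15 mmol/L). A DKA
   discharge diagnosis alone never confirms a case under the default
   `strict` policy.
4. **Statistics** (`compute_ppv()`, `stratified_ppv()`, `wilson_interval()`):
   PPV with Wilson score 95% confidence intervals,

   PPV = x/n, CI = ( p̂ + z²/2n ± z √( p̂(1−p̂)/n + z²/4n² ) ) / (1 + z²/n),

   overall and stratified by exposure, age stratum, gender and ADHD
   diagnosis.

Because real Medicaid data are protected, the package ships a synthetic
claims generator with known ground truth (`simulate_claims()`,
`simulate_abstractions()`) and a packaged reference study
(`dka_reference_study()`) on which every stage of the pipeline is exercised.

## Worked example

```r
library(dkaclaims)

study <- dka_reference_study()
fit <- validate_case_definition(study$db, study$abstractions)
fit
#> Claims-based DKA case-definition validation (policy: strict )
#>   potential cases: 30; adjudicated: 27; confirmed: 24
#>   PPV 88.9% (95% CI 71.9 to 96.1)

ppv_report(tidy(fit))
#> stratum      level              n     x   PPV(%)  95% CI
#> overall      all               27    24     88.9  71.9 to 96.1
#> exposure     antipsychotic      6     5     83.3  43.6 to 97.0
#> exposure     control           21    19     90.5  71.1 to 97.3
#> age          lower_6_10        10     7     70.0  39.7 to 89.2
#> age          upper_11_24       17    17    100.0  81.6 to 100.0
#> gender       female            13    10     76.9  49.7 to 91.8
#> gender       male              14    14    100.0  78.5 to 100.0
#> adhd         no                12    12    100.0  75.8 to 100.0
#> adhd         yes               15    12     80.0  54.8 to 93.0
```

Reading the output: 30 potential cases were flagged by the computer
definition, 27 charts could be abstracted, and 24 met the clinical rule, so
roughly nine of ten claims-flagged DKA admissions are real DKA — the
remaining three presented with severe hyperglycemia but no laboratory
acidosis. Small strata (e.g. 5/6 antipsychotic initiators) carry
correspondingly wide Wilson intervals. `autoplot(fit)` draws the forest
plot; `glance(fit)` gives the one-row summary; `tidy(fit)` the full table
at double precision.

For simulation studies with known truth:

```r
cfg <- sim_config(n_persons = 2000, true_ppv = 0.85, p_case = 0.25)
sim <- simulate_claims(cfg, seed = 1)
ab  <- simulate_abstractions(sim$truth, cfg, seed = 2)
fit <- validate_case_definition(sim$db, ab)
glance(fit)   # recovers PPV ~ 85%
```

## CSV schemas

`read_claims_db()` / `write_claims_db()` exchange a directory of five
comma-separated, UTF-8, ISO-8601-dated files:

| file | columns |
|---|---|
| `persons.csv` | `person_id`, `birth_date`, `gender` (male/female), `race` (caucasian/african_american/other), `urban` (logical), `adhd_dx` (logical) |
| `enrollment.csv` | `person_id`, `start_date`, `end_date` (closed spans) |
| `pharmacy.csv` | `person_id`, `fill_date`, `drug_class` (antipsychotic/mood_stabilizer/adhd_drug/antidepressant/benzodiazepine/other), `days_supply` |
| `encounters.csv` | `encounter_id`, `person_id`, `setting` (inpatient/outpatient/emergency), `start_date`, `end_date`, `dx_codes` (semicolon-joined `system:code` tags, e.g. `icd9:250.11;icd9:486`) |
| `deaths.csv` | `person_id`, `death_date` |

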