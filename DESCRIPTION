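Package: dkaclaims
Title: Validation of a Claims-Based Case Definition for Diabetic
    Ketoacidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to validate a computer (claims-based) case definition
    for incident diabetic ketoacidosis (DKA) against chart-review
    adjudication. Implements a new-user cohort builder for Medicaid-like
    pharmacy and encounter claims (qualifying fills, 365-day washout,
    eligibility exclusions, follow-up termination), inpatient case
    finding over ICD-9/ICD-10 diagnosis code families with the prior-day
    emergency-department index-date rule, a deterministic clinical
    adjudication rule (hyperglycemia plus laboratory acidosis), and
    positive predictive value estimation with Wilson score confidence
    intervals, overall and stratified. A synthetic claims generator with
    known ground truth and a packaged reference study dataset make every
    pipeline stage testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
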