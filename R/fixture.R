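#' Packaged reference validation study
#'
#' A deterministic, hand-constructed claims database and chart-abstraction
#' set reproducing the published validation-study counts for this case
#' definition: 30 potential DKA cases flagged from inpatient claims, of which
#' 3 could not be abstracted (2 records not located, 1 facility refusal) and
#' 27 were adjudicated; 24 are confirmed and the 3 non-confirmed all show
#' severe hyperglycemia without laboratory acidosis. The joint stratum
#' assignment reproduces every reported margin simultaneously: 5/6 confirmed
#' among antipsychotic initiators and 19/21 among control initiators; 17/17
#' in the upper age stratum (11-24) and 7/10 in the lower (10 and below);
#' 14/14 males and 10/13 females; 12/15 with an ADHD diagnosis and 12/12
#' without. The margins do not determine the joint table uniquely; any
#' feasible joint table yields the same stratified results.
#'
#' The database also contains two cohort members who are never flagged (one
#' with a non-DKA hospitalization) and one person excluded for a recent
#' hospitalization whose later DKA admission must therefore not be counted —
#' so running the full pipeline on this fixture exercises cohort exclusion
#' and case finding, not just the arithmetic.
#'
#' @return A list with elements `db` (a [claims_db()]) and `abstractions`
#'   (an abstraction tibble; see [simulate_abstractions()] for the schema).
#' @examples
#' study <- dka_reference_study()
#' cohort <- build_cohort(study$db)
#' cases <- find_potential_cases(cohort, study$db)
#' nrow(cases)  # 30
#' @export
dka_reference_study <- function() {
  # --- joint stratum table -------------------------------------------------
  # confirmed rows C01..C24: margins assigned independently per attribute
  conf <- tibble::tibble(
    case_id = sprintf("C%02d", 1:24),
    confirmed = TRUE,
    exposure_group = rep(c("antipsychotic", "control"), c(5, 19)),
    age_years = c(c(11, 11, 11, 11, 12, 12, 13, 13, 14, 14, 15, 15, 16, 17,
                    18, 19, 24),            # upper stratum, 17 rows
                  c(6, 7, 8, 9, 10, 10, 9)),  # lower stratum, 7 rows
    gender = rep(c("male", "female"), c(14, 10)),
    adhd_dx = rep(c(TRUE, FALSE), c(12, 12)))
  # non-confirmed rows: hyperglycemia without acidosis; all lower-age,
  # female, ADHD; one antipsychotic initiator
  nonconf <- tibble::tibble(
    case_id = sprintf("N%02d", 1:3), confirmed = FALSE,
    exposure_group = c("antipsychotic", "control", "control"),
    age_years = c(7, 9, 10), gender = "female", adhd_dx = TRUE)
  # unabstracted rows: chosen so the all-30 margins match the sample
  # description (6 antipsychotic, 14 female, 16 ADHD)
  unabs <- tibble::tibble(
    case_id = sprintf("U%02d", 1:3), confirmed = NA,
    exposure_group = "control", age_years = c(12, 9, 14),
    gender = c("female", "male", "male"), adhd_dx = c(TRUE, FALSE, FALSE))
  strata <- dplyr::bind_rows(conf, nonconf, unabs)

  n30 <- nrow(strata)
  qual <- as.Date("1999-03-01") + 80L * (seq_len(n30) - 1L)
  admission <- qual + 100L
  birth <- qual - round(strata$age_years * 365.25) - 50L
  ctrl_classes <- setdiff(study_drug_classes(), "antipsychotic")
  drug <- ifelse(strata$exposure_group == "antipsychotic", "antipsychotic",
                 ctrl_classes[(seq_len(n30) - 1L) %% 4L + 1L])

  persons <- tibble::tibble(
    person_id = strata$case_id, birth_date = birth, gender = strata$gender,
    race = rep(c("caucasian", "african_american", "other"), c(21, 6, 3)),
    urban = seq_len(n30) %% 3L != 0L, adhd_dx = strata$adhd_dx)

  enrollment <- tibble::tibble(person_id = strata$case_id,
                               start_date = qual - 450L,
                               end_date = admission + 600L)
  pharmacy <- tibble::tibble(person_id = strata$case_id, fill_date = qual,
                             drug_class = drug, days_supply = 90L)
  baseline_visit <- tibble::tibble(
    person_id = strata$case_id, setting = "outpatient",
    start_date = qual - 90L, end_date = qual - 90L, dx_codes = "icd9:V20.2")

  # flagging admissions: C02 carries the DKA code in secondary position,
  # C03 is coded ICD-10; C01 and N01 get the prior-day emergency diabetes
  # visit that resets the index date
  dka_dx <- rep("icd9:250.11", n30)
  dka_dx[strata$case_id == "C02"] <- "icd9:486;icd9:250.11"
  dka_dx[strata$case_id == "C03"] <- "icd10:E11.10"
  dka_enc <- tibble::tibble(person_id = strata$case_id, setting = "inpatient",
                            start_date = admission, end_date = admission + 3L,
                            dx_codes = dka_dx)
  er_ids <- c("C01", "N01")
  er_enc <- tibble::tibble(
    person_id = er_ids, setting = "emergency",
    start_date = admission[match(er_ids, strata$case_id)] - 1L,
    end_date = admission[match(er_ids, strata$case_id)] - 1L,
    dx_codes = "icd9:250.00")

  # cohort members never flagged, and one ineligible person whose DKA
  # admission must not be counted
  extra_persons <- tibble::tibble(
    person_id = c("X01", "X02", "Z01"),
    birth_date = as.Date(c("1988-05-20", "1992-11-02", "1990-07-15")),
    gender = c("male", "female", "male"),
    race = c("caucasian", "caucasian", "african_american"),
    urban = c(TRUE, FALSE, TRUE), adhd_dx = c(TRUE, FALSE, FALSE))
  xq <- as.Date(c("2001-04-10", "2003-09-05", "2002-06-01"))
  extra_enroll <- tibble::tibble(person_id = extra_persons$person_id,
                                 start_date = xq - 450L, end_date = xq + 700L)
  extra_fills <- tibble::tibble(person_id = extra_persons$person_id,
                                fill_date = xq,
                                drug_class = c("adhd_drug", "antidepressant",
                                               "antipsychotic"),
                                days_supply = 90L)
  extra_enc <- dplyr::bind_rows(
    tibble::tibble(person_id = extra_persons$person_id,
                   setting = "outpatient", start_date = xq - 120L,
                   end_date = xq - 120L, dx_codes = "icd9:V20.2"),
    # X02: a non-DKA hospitalization during follow-up (never flags)
    tibble::tibble(person_id = "X02", setting = "inpatient",
                   start_date = xq[2] + 150L, end_date = xq[2] + 153L,
                   dx_codes = "icd9:486"),
    # Z01: hospitalized 10 days before the fill (ineligible), DKA later
    tibble::tibble(person_id = "Z01", setting = "inpatient",
                   start_date = xq[3] - 15L, end_date = xq[3] - 10L,
                   dx_codes = "icd9:486"),
    tibble::tibble(person_id = "Z01", setting = "inpatient",
                   start_date = xq[3] + 100L, end_date = xq[3] + 103L,
                   dx_codes = "icd9:250.11"))

  encounters <- dplyr::bind_rows(baseline_visit, dka_enc, er_enc, extra_enc)
  encounters <- encounters |>
    dplyr::mutate(encounter_id = sprintf("E%03d", seq_len(nrow(encounters))),
                  .before = 1L)

  db <- claims_db(persons = dplyr::bind_rows(persons, extra_persons),
                  enrollment = dplyr::bind_rows(enrollment, extra_enroll),
                  pharmacy = dplyr::bind_rows(pharmacy, extra_fills),
                  encounters = encounters)

  # --- abstraction records -------------------------------------------------
  i <- seq_len(24)
  evidence <- i %% 3L
  abstr_conf <- tibble::tibble(
    person_id = conf$case_id, abstraction_status = "complete",
    glucose_mg_dl = 300 + 10 * i,
    ph_venous = ifelse(evidence == 1L, round(7.00 + 0.01 * (i %% 20L), 2),
                       NA_real_),
    ph_arterial = ifelse(evidence == 2L, 7.21, NA_real_),
    ph_capillary = NA_real_,
    bicarbonate_mmol_l = c(8, 9, 10, 11, 12, 13, 14, 14.5)[i %% 8L + 1L],
    discharge_dx = "icd9:250.11")
  abstr_nonconf <- tibble::tibble(
    person_id = nonconf$case_id, abstraction_status = "complete",
    glucose_mg_dl = c(356, 428, 515),
    ph_venous = c(7.33, 7.36, 7.40), ph_arterial = NA_real_,
    ph_capillary = NA_real_, bicarbonate_mmol_l = c(18, 20.5, 24),
    discharge_dx = "icd9:250.11")
  abstr_unabs <- tibble::tibble(
    person_id = unabs$case_id,
    abstraction_status = c("record_not_located", "record_not_located",
                           "facility_refused"),
    glucose_mg_dl = NA_real_, ph_venous = NA_real_, ph_arterial = NA_real_,
    ph_capillary = NA_real_, bicarbonate_mmol_l = NA_real_,
    discharge_dx = NA_character_)
  abstractions <- dplyr::bind_rows(abstr_conf, abstr_nonconf, abstr_unabs) |>
    dplyr::left_join(dplyr::select(strata, person_id = "case_id",
                                   "age_years", "gender", "adhd_dx",
                                   "exposure_group"),
                     by = "person_id")

  list(db = db, abstractions = abstractions)
}
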