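#' Apply the computer case definition for incident DKA
#'
#' Flags potential incident diabetic-ketoacidosis cases from inpatient
#' encounter claims: any diagnosis position matching the DKA code family
#' (ICD-9 250.1x, ICD-10 E10.1-E14.1) on an inpatient admission during
#' follow-up. Outpatient and emergency-only encounters never trigger. Only
#' the first (incident) event per person is retained, and persons with any
#' DKA-coded claim of any setting during the baseline window are excluded
#' (prevalent disease). The index date is the admission date unless the
#' prior-day emergency-department rule applies (see [resolve_index_date()]);
#' an encounter is a case when its index date falls inside follow-up, so an
#' event whose terminating emergency visit lands on the last follow-up day is
#' still captured.
#'
#' @param cohort A cohort tibble from [build_cohort()].
#' @param db A [claims_db()].
#' @param config A [cohort_config()].
#' @return Tibble of potential cases: `person_id`, `encounter_id`,
#'   `admission_date`, `index_date`, `exposure_group`.
#' @examples
#' study <- dka_reference_study()
#' cases <- build_cohort(study$db) |> find_potential_cases(study$db)
#' nrow(cases)
#' @export
find_potential_cases <- function(cohort, db, config = cohort_config()) {
  stopifnot(inherits(db, "claims_db"))
  empty <- tibble::tibble(person_id = character(), encounter_id = character(),
                          admission_date = as.Date(character()),
                          index_date = as.Date(character()),
                          exposure_group = character())
  if (nrow(cohort) == 0L || nrow(db$encounters) == 0L) return(empty)

  dx <- dx_unnest(db$encounters)
  dka <- dx[icd_match_any(dx$dx_code, dx$dx_system, dka_codes()), ]
  if (nrow(dka) == 0L) return(empty)

  inpt <- dka |>
    dplyr::filter(.data$setting == "inpatient") |>
    dplyr::distinct(.data$person_id, .data$encounter_id,
                    admission_date = .data$start_date) |>
    dplyr::inner_join(
      dplyr::select(cohort, "person_id", "fill_date", "followup_start",
                    "followup_end", "exposure_group"),
      by = "person_id")

  # incidence: no DKA-coded claim (any setting) during the baseline window
  prevalent <- dka |>
    dplyr::inner_join(dplyr::select(cohort, "person_id", "fill_date"),
                      by = "person_id") |>
    dplyr::filter(.data$start_date >= .data$fill_date - config$baseline_days,
                  .data$start_date <= .data$fill_date) |>
    dplyr::distinct(.data$person_id)

  cases <- inpt |>
    dplyr::filter(!.data$person_id %in% prevalent$person_id) |>
    resolve_index_date(db, config) |>
    dplyr::filter(.data$index_date >= .data$followup_start,
                  .data$index_date <= .data$followup_end) |>
    dplyr::arrange(.data$person_id, .data$admission_date,
                   .data$encounter_id) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE)

  dplyr::select(cases, "person_id", "encounter_id", "admission_date",
                "index_date", "exposure_group") |>
    dplyr::arrange(.data$person_id)
}

#' Resolve the index date for flagged admissions
#'
#' The index date of a DKA event is the hospital admission date, unless an
#' emergency-department claim carrying any diabetes diagnosis (ICD-9 250.x;
#' ICD-10 E10-E14 when `er_reset_icd10` is enabled) exists on the day
#' immediately before admission — then the index date is reset to that
#' emergency visit's date. A diabetes emergency visit two or more days before
#' admission never resets.
#'
#' @param cases Tibble with `person_id` and `admission_date`.
#' @param db A [claims_db()].
#' @param config A [cohort_config()].
#' @return `cases` with an `index_date` column added (or replaced).
#' @export
resolve_index_date <- function(cases, db, config = cohort_config()) {
  if (nrow(cases) == 0L) {
    return(dplyr::mutate(cases, index_date = as.Date(character())))
  }
  dx <- dx_unnest(dplyr::filter(db$encounters, .data$setting == "emergency"))
  dm <- dx[icd_match_any(dx$dx_code, dx$dx_system,
                         diabetes_codes(include_icd10 = config$er_reset_icd10)), ]
  er_days <- dplyr::distinct(dm, .data$person_id, er_date = .data$start_date)
  cases |>
    dplyr::left_join(
      dplyr::mutate(er_days, er_next = .data$er_date + 1L, reset = TRUE) |>
        dplyr::select("person_id", "er_next", "reset"),
      by = dplyr::join_by("person_id", "admission_date" == "er_next"),
      relationship = "many-to-one") |>
    dplyr::mutate(
      index_date = dplyr::if_else(!is.na(.data$reset),
                                  .data$admission_date - 1L,
                                  .data$admission_date)) |>
    dplyr::select(-"reset")
}
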