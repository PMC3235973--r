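# a one-person cohort row for direct case-finder tests
mk_member <- function(id = "p1", fill = "2000-06-01", end_days = 500L,
                      exposure = "antipsychotic") {
  fill <- d(fill)
  tibble::tibble(person_id = id, fill_date = fill,
                 drug_class = exposure, exposure_group = exposure,
                 followup_start = fill + 1L, followup_end = fill + end_days,
                 end_reason = "study_end")
}

test_that("inpatient DKA claims flag cases in any diagnosis position;
           other settings never do", {
  fill <- d("2000-06-01")
  member <- mk_member()
  # secondary diagnosis position still flags
  db <- mk_simple_db(extra_enc = mk_enc("p1", "inpatient", fill + 100L,
                                        fill + 102L,
                                        dx = "icd9:486;icd9:250.11"))
  cases <- find_potential_cases(member, db)
  expect_equal(nrow(cases), 1L)
  expect_equal(cases$admission_date, fill + 100L)
  # outpatient encounter with the same code does not
  db <- mk_simple_db(extra_enc = mk_enc("p1", "outpatient", fill + 100L,
                                        dx = "icd9:250.11"))
  expect_equal(nrow(find_potential_cases(member, db)), 0L)
  # emergency-only encounters do not flag either
  db <- mk_simple_db(extra_enc = mk_enc("p1", "emergency", fill + 100L,
                                        dx = "icd9:250.11"))
  expect_equal(nrow(find_potential_cases(member, db)), 0L)
  # an admission after followup_end is outside the interval
  db <- mk_simple_db(extra_enc = mk_enc("p1", "inpatient", fill + 510L,
                                        fill + 512L, dx = "icd9:250.11"))
  expect_equal(nrow(find_potential_cases(member, db)), 0L)
  # ICD-10 family codes flag too
  db <- mk_simple_db(extra_enc = mk_enc("p1", "inpatient", fill + 100L,
                                        fill + 102L, dx = "icd10:E11.10"))
  expect_equal(nrow(find_potential_cases(member, db)), 1L)
})

test_that("only the first (incident) event per person is retained", {
  fill <- d("2000-06-01")
  member <- mk_member()
  db <- mk_simple_db(extra_enc = dplyr::bind_rows(
    mk_enc("p1", "inpatient", fill + 200L, fill + 202L,
           dx = "icd9:250.11", enc_id = "B"),
    mk_enc("p1", "inpatient", fill + 100L, fill + 102L,
           dx = "icd9:250.13", enc_id = "A")))
  cases <- find_potential_cases(member, db)
  expect_equal(nrow(cases), 1L)
  expect_equal(cases$admission_date, fill + 100L)
  # same-day duplicate admissions: lowest encounter id wins
  db <- mk_simple_db(extra_enc = dplyr::bind_rows(
    mk_enc("p1", "inpatient", fill + 100L, fill + 102L,
           dx = "icd9:250.11", enc_id = "B"),
    mk_enc("p1", "inpatient", fill + 100L, fill + 102L,
           dx = "icd9:250.13", enc_id = "A")))
  expect_equal(find_potential_cases(member, db)$encounter_id, "A")
})

test_that("a DKA-coded claim in the baseline window marks the disease
           prevalent and suppresses flagging", {
  fill <- d("2000-06-01")
  member <- mk_member()
  db <- mk_simple_db(extra_enc = dplyr::bind_rows(
    mk_enc("p1", "outpatient", fill - 50L, dx = "icd9:250.11"),
    mk_enc("p1", "inpatient", fill + 100L, fill + 102L,
           dx = "icd9:250.11")))
  expect_equal(nrow(find_potential_cases(member, db)), 0L)
})

test_that("the index date resets only for a prior-day emergency diabetes
           claim", {
  fill <- d("2000-06-01")
  member <- mk_member()
  adm <- fill + 100L
  dka <- mk_enc("p1", "inpatient", adm, adm + 2L, dx = "icd9:250.11")
  # ER visit with any diabetes code on the day before admission
  db <- mk_simple_db(extra_enc = dplyr::bind_rows(
    dka, mk_enc("p1", "emergency", adm - 1L, dx = "icd9:250.00")))
  cases <- find_potential_cases(member, db)
  expect_equal(cases$index_date, adm - 1L)
  # no emergency claim: index is the admission date
  db <- mk_simple_db(extra_enc = dka)
  expect_equal(find_potential_cases(member, db)$index_date, adm)
  # a diabetes ER visit two days before does not reset
  db <- mk_simple_db(extra_enc = dplyr::bind_rows(
    dka, mk_enc("p1", "emergency", adm - 2L, dx = "icd9:250.00")))
  expect_equal(find_potential_cases(member, db)$index_date, adm)
  # a prior-day ER visit without a diabetes code does not reset
  db <- mk_simple_db(extra_enc = dplyr::bind_rows(
    dka, mk_enc("p1", "emergency", adm - 1L, dx = "icd9:786.50")))
  expect_equal(find_potential_cases(member, db)$index_date, adm)
  # ICD-10 ER diabetes codes reset only when enabled
  db <- mk_simple_db(extra_enc = dplyr::bind_rows(
    dka, mk_enc("p1", "emergency", adm - 1L, dx = "icd10:E11.9")))
  expect_equal(find_potential_cases(member, db)$index_date, adm)
  cfg10 <- cohort_config(er_reset_icd10 = TRUE)
  expect_equal(find_potential_cases(member, db, cfg10)$index_date, adm - 1L)
})

test_that("the case list ignores within-day claim order and unrelated
           claims", {
  sim <- simulate_claims(sim_config(n_persons = 150), seed = 21)
  cohort <- build_cohort(sim$db)
  cases <- find_potential_cases(cohort, sim$db)
  # shuffle encounter rows: identical case list
  set.seed(1)
  enc2 <- sim$db$encounters[sample(nrow(sim$db$encounters)), ]
  db2 <- claims_db(persons = sim$db$persons, enrollment = sim$db$enrollment,
                   pharmacy = sim$db$pharmacy, encounters = enc2,
                   deaths = sim$db$deaths)
  expect_equal(find_potential_cases(build_cohort(db2), db2), cases)
  # adding a non-DKA, non-ER claim leaves cases and index dates unchanged
  extra <- mk_enc(cases$person_id[1], "outpatient",
                  cases$admission_date[1] - 5L, dx = "icd9:786.50",
                  enc_id = "noise-claim")
  db3 <- claims_db(persons = sim$db$persons, enrollment = sim$db$enrollment,
                   pharmacy = sim$db$pharmacy,
                   encounters = dplyr::bind_rows(sim$db$encounters, extra),
                   deaths = sim$db$deaths)
  expect_equal(find_potential_cases(build_cohort(db3), db3), cases)
  # at most one case per person, all inside follow-up
  expect_false(anyDuplicated(cases$person_id) > 0L)
  m <- match(cases$person_id, cohort$person_id)
  expect_true(all(cases$index_date >= cohort$followup_start[m]))
  expect_true(all(cases$index_date <= cohort$followup_end[m]))
  expect_true(all(cases$index_date %in%
                    c(cases$admission_date, cases$admission_date - 1L)))
})

test_that("the reference study yields exactly 30 potential cases and the
           excluded person's admission is not among them", {
  study <- dka_reference_study()
  cohort <- build_cohort(study$db)
  cases <- find_potential_cases(cohort, study$db)
  expect_equal(nrow(cases), 30L)
  expect_false("Z01" %in% cases$person_id)
  expect_false("Z01" %in% cohort$person_id)
  expect_true(all(c("X01", "X02") %in% cohort$person_id))
  # the two fixture cases with a prior-day ER diabetes visit reset
  reset <- cases[cases$person_id %in% c("C01", "N01"), ]
  expect_equal(reset$index_date, reset$admission_date - 1L)
  others <- cases[!cases$person_id %in% c("C01", "N01"), ]
  expect_equal(others$index_date, others$admission_date)
})
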