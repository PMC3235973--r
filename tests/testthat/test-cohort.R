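test_that("washout logic admits and rejects fills per the new-user rule", {
  cfg <- cohort_config()
  # a person's only fill ever: vacuous washout
  one <- mk_fill("p1", "2000-06-01")
  expect_equal(nrow(find_qualifying_fills(one, cfg)), 1L)
  # fill 200 days after a prior study-drug fill does not qualify
  two <- dplyr::bind_rows(mk_fill("p1", "2000-06-01"),
                          mk_fill("p1", "2000-12-18", "antidepressant"))
  q <- find_qualifying_fills(two, cfg)
  expect_equal(q$fill_date, d("2000-06-01"))
  # 400-day gap satisfies the washout
  spaced <- dplyr::bind_rows(mk_fill("p1", "2000-06-01"),
                             mk_fill("p1", "2001-07-06"))
  expect_equal(nrow(find_qualifying_fills(spaced, cfg)), 2L)
  # a gap of exactly washout_days is still inside the window
  edge <- dplyr::bind_rows(mk_fill("p1", "2000-06-01"),
                           mk_fill("p1", d("2000-06-01") + 365L))
  expect_equal(nrow(find_qualifying_fills(edge, cfg)), 1L)
  # non-study fills neither qualify nor break the washout
  other <- dplyr::bind_rows(mk_fill("p1", "2000-06-01", "other"),
                            mk_fill("p1", "2000-09-01"))
  q <- find_qualifying_fills(other, cfg)
  expect_equal(q$fill_date, d("2000-09-01"))
  # same-day fills do not disqualify each other
  same <- dplyr::bind_rows(mk_fill("p1", "2000-06-01"),
                           mk_fill("p1", "2000-06-01", "adhd_drug"))
  expect_equal(nrow(find_qualifying_fills(same, cfg)), 2L)
  expect_equal(nrow(find_qualifying_fills(one[0, ], cfg)), 0L)
})

test_that("exposure groups follow the drug class of the qualifying fill", {
  fills <- dplyr::bind_rows(mk_fill("p1", "2000-06-01", "antipsychotic"),
                            mk_fill("p2", "2000-06-01", "mood_stabilizer"),
                            mk_fill("p3", "2000-06-01", "benzodiazepine"))
  q <- find_qualifying_fills(fills)
  expect_equal(q$exposure_group[order(q$person_id)],
               c("antipsychotic", "control", "control"))
})

test_that("eligibility failures are named and exhaustive", {
  fill <- d("2000-06-01")
  cand <- tibble::tibble(person_id = "p1", fill_date = fill)
  # clean record: eligible, no failures
  db <- mk_simple_db()
  res <- check_eligibility(cand, db)
  expect_true(res$eligible)
  expect_equal(res$failed_criteria, "")
  # age 25 at the qualifying date
  db_old <- mk_simple_db(birth = "1975-01-15")
  res <- check_eligibility(cand, db_old)
  expect_false(res$eligible)
  expect_equal(res$failed_criteria, "age")
  # inpatient discharge 10 days before the fill
  db_hosp <- mk_simple_db(extra_enc = mk_enc("p1", "inpatient",
                                             fill - 15L, fill - 10L,
                                             dx = "icd9:486"))
  expect_equal(check_eligibility(cand, db_hosp)$failed_criteria,
               "recent_hospitalization")
  # baseline schizophrenia diagnosis
  db_scz <- mk_simple_db(extra_enc = mk_enc("p1", "outpatient", fill - 120L,
                                            dx = "icd9:295.30"))
  expect_equal(check_eligibility(cand, db_scz)$failed_criteria,
               "dx_psychosis")
  # enrollment not covering the whole baseline year
  db_gap <- mk_simple_db(enroll_start = fill - 100L)
  expect_equal(check_eligibility(cand, db_gap)$failed_criteria,
               "enrollment")
  # several failures are all reported, not just the first
  db_multi <- mk_simple_db(birth = "1975-01-15",
                           extra_enc = mk_enc("p1", "inpatient", fill - 15L,
                                              fill - 10L, dx = "icd9:486"))
  expect_equal(check_eligibility(cand, db_multi)$failed_criteria,
               "age;recent_hospitalization")
  expect_error(check_eligibility(tibble::tibble(person_id = "nope",
                                                fill_date = fill), db),
               "not in database")
})

test_that("follow-up ends at the earliest terminating event", {
  fill <- d("2000-06-01")
  member <- tibble::tibble(person_id = "p1", fill_date = fill)
  # death 100 days in beats everything later
  db <- mk_simple_db(deaths = tibble::tibble(person_id = "p1",
                                             death_date = fill + 100L))
  f <- compute_followup(member, db)
  expect_equal(f$followup_start, fill + 1L)
  expect_equal(f$followup_end, fill + 100L)
  expect_equal(f$end_reason, "death")
  # last covered supply day + 365 when no refill occurs
  db <- mk_simple_db(supply = 31L)
  f <- compute_followup(member, db)
  expect_equal(f$followup_end, fill + 30L + 365L)
  expect_equal(f$end_reason, "use_lapse")
  # continuous refills to the study end
  refills <- mk_fill("p1", seq(fill + 300L, d("2007-12-31"), by = 300))
  db <- mk_simple_db(supply = 365L, extra_fills = refills,
                     enroll_end = d("2009-12-31"))
  f <- compute_followup(member, db)
  expect_equal(f$followup_end, d("2007-12-31"))
  expect_equal(f$end_reason, "study_end")
  # disenrollment cuts follow-up short
  db <- mk_simple_db(enroll_end = fill + 50L)
  f <- compute_followup(member, db)
  expect_equal(f$followup_end, fill + 50L)
  expect_equal(f$end_reason, "disenrollment")
  # the 25th birthday ends follow-up for a 24-year-old entrant
  db <- mk_simple_db(birth = "1976-01-15", supply = 365L)
  f <- compute_followup(member, db)
  expect_equal(f$followup_end, d("2001-01-15"))
  expect_equal(f$end_reason, "age_25")
  # an exclusion diagnosis during follow-up is a criteria failure
  db <- mk_simple_db(supply = 365L,
                     extra_enc = mk_enc("p1", "outpatient", fill + 60L,
                                        dx = "icd9:295.00"))
  f <- compute_followup(member, db)
  expect_equal(f$followup_end, fill + 60L)
  expect_equal(f$end_reason, "criteria_failure")
})

test_that("ties break by the fixed reason precedence", {
  fill <- d("2000-06-01")
  member <- tibble::tibble(person_id = "p1", fill_date = fill)
  # death and disenrollment on the same day: death wins
  db <- mk_simple_db(enroll_end = fill + 50L,
                     deaths = tibble::tibble(person_id = "p1",
                                             death_date = fill + 50L))
  f <- compute_followup(member, db)
  expect_equal(f$end_reason, "death")
  expect_equal(f$followup_end, fill + 50L)
})

test_that("use episodes chain through overlapping refills", {
  fill <- d("2000-06-01")
  member <- tibble::tibble(person_id = "p1", fill_date = fill)
  # refill 10 days before supply runs out extends the episode
  db <- mk_simple_db(supply = 30L,
                     extra_fills = mk_fill("p1", fill + 20L, supply = 30L))
  f <- compute_followup(member, db)
  expect_equal(f$followup_end, fill + 20L + 29L + 365L)
  expect_equal(f$end_reason, "use_lapse")
})

test_that("cohort members re-verify the washout by brute force", {
  sim <- simulate_claims(sim_config(n_persons = 250, p_ineligible = 0.2),
                         seed = 3)
  cohort <- build_cohort(sim$db)
  expect_gt(nrow(cohort), 50L)
  ph <- sim$db$pharmacy
  for (i in seq_len(nrow(cohort))) {
    mine <- ph[ph$person_id == cohort$person_id[i] &
                 ph$drug_class %in% dkaclaims:::study_drug_classes(), ]
    gap <- cohort$fill_date[i] - mine$fill_date
    expect_false(any(gap >= 1 & gap <= 365))
  }
})

test_that("follow-up never outlives death, disenrollment or the 25th
           birthday, and later claims cannot move it", {
  sim <- simulate_claims(sim_config(n_persons = 200, p_death = 0.1), seed = 8)
  cohort <- build_cohort(sim$db)
  db <- sim$db
  pers <- db$persons[match(cohort$person_id, db$persons$person_id), ]
  expect_true(all(cohort$followup_end <=
                    dkaclaims:::birthday(pers$birth_date, 25L)))
  dd <- db$deaths$death_date[match(cohort$person_id, db$deaths$person_id)]
  expect_true(all(is.na(dd) | cohort$followup_end <= dd))
  spans <- dkaclaims:::normalize_spans(db$enrollment)
  last_enr <- vapply(cohort$person_id, function(p) {
    max(as.integer(spans$end_date[spans$person_id == p]))
  }, integer(1))
  expect_true(all(as.integer(cohort$followup_end) <= last_enr))
  # locality: a claim strictly after followup_end changes nothing
  m1 <- cohort[1, ]
  later <- mk_enc(m1$person_id, "outpatient", m1$followup_end + 30L,
                  dx = "icd9:295.00", enc_id = "late-claim")
  db2 <- claims_db(persons = db$persons, enrollment = db$enrollment,
                   pharmacy = db$pharmacy,
                   encounters = dplyr::bind_rows(db$encounters, later),
                   deaths = db$deaths)
  cohort2 <- build_cohort(db2)
  expect_equal(cohort2[cohort2$person_id == m1$person_id, ], m1)
})

test_that("members enter at their first qualifying eligible fill", {
  fill1 <- d("1998-03-01"); fill2 <- d("2001-05-01")
  # first qualifying fill is ineligible (recent hospitalization); the
  # second, more than washout_days later, gets the person in
  db <- mk_simple_db(fill = fill1, enroll_end = fill2 + 600L,
                     extra_fills = mk_fill("p1", fill2, "antidepressant"),
                     extra_enc = dplyr::bind_rows(
                       mk_enc("p1", "inpatient", fill1 - 12L, fill1 - 8L,
                              dx = "icd9:486"),
                       mk_enc("p1", "outpatient", fill2 - 100L)))
  cohort <- build_cohort(db)
  expect_equal(nrow(cohort), 1L)
  expect_equal(cohort$fill_date, fill2)
  expect_equal(cohort$exposure_group, "control")
  expect_equal(nrow(build_cohort(claims_db(persons = mk_person("p9")))), 0L)
})
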