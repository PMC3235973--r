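#' Configuration for the synthetic claims generator
#'
#' Parameters of the simulated Medicaid-like study population. Defaults
#' emulate the validation-study setting: children and youth aged 6-24
#' initiating an antipsychotic (20% of initiators) or a control psychotropic,
#' with the dominant false-positive mode being severe hyperglycemia without
#' acidosis. Event rates (`p_case`, `p_ineligible`, `p_death`) are study
#' dials, not epidemiologic estimates — DKA incidence realism is a non-goal.
#'
#' @param n_persons Number of persons to simulate.
#' @param exposure_mix Probability a new user initiates an antipsychotic
#'   (otherwise one of the four control classes, equiprobable).
#' @param true_ppv Probability that a flagged potential case is true DKA;
#'   default 0.889, the working estimate for this case definition.
#' @param fp_mode_weights Named weights over the false-positive modes
#'   `hyperglycemia_no_acidosis` and `coding_error`; must sum to 1.
#' @param age_range Completed-age range (within 6-24) at the qualifying fill.
#' @param p_case Probability an eligible cohort member is given an inpatient
#'   DKA-coded admission during follow-up.
#' @param p_ineligible Probability a person is constructed to violate exactly
#'   one eligibility criterion (tagged in the `ineligible` output).
#' @param p_er_reset Probability a flagged case also gets a prior-day
#'   emergency diabetes claim (exercising the index-date reset).
#' @param p_death Probability an eligible, unflagged member dies during
#'   follow-up.
#' @param p_secondary_dx Probability the DKA code sits in a secondary
#'   diagnosis position on the flagging admission.
#' @param days_supply Days supplied per dispensing.
#' @param mean_refills Poisson mean of the number of consecutive refills.
#' @param unabstractable_frac Fraction of flagged cases whose chart cannot be
#'   abstracted (record not located or facility refused).
#' @param labs Lab-value distribution parameters (means/SDs on the scales of
#'   mg/dL, pH units and mmol/L); only their ordering against the diagnostic
#'   thresholds matters for correctness.
#' @param study_start,study_end Study window.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(n_persons = 500L,
                       exposure_mix = 0.2,
                       true_ppv = 0.889,
                       fp_mode_weights = c(hyperglycemia_no_acidosis = 1,
                                           coding_error = 0),
                       age_range = c(6L, 24L),
                       p_case = 0.08,
                       p_ineligible = 0.10,
                       p_er_reset = 0.25,
                       p_death = 0.01,
                       p_secondary_dx = 0.4,
                       days_supply = 30L,
                       mean_refills = 2,
                       unabstractable_frac = 0.10,
                       labs = list(glucose_true_meanlog = log(450),
                                   glucose_true_sdlog = 0.25,
                                   glucose_fp_meanlog = log(350),
                                   glucose_fp_sdlog = 0.20,
                                   ph_true_mean = 7.10, ph_true_sd = 0.08,
                                   ph_fp_mean = 7.36, ph_fp_sd = 0.04,
                                   bicarb_true_mean = 9, bicarb_true_sd = 3,
                                   bicarb_fp_mean = 22, bicarb_fp_sd = 3),
                       study_start = as.Date("1996-01-01"),
                       study_end = as.Date("2007-12-31")) {
  stopifnot(n_persons >= 0,
            exposure_mix >= 0, exposure_mix <= 1,
            true_ppv >= 0, true_ppv <= 1,
            length(fp_mode_weights) == 2L,
            all(fp_mode_weights >= 0),
            abs(sum(fp_mode_weights) - 1) < 1e-8,
            all(names(fp_mode_weights) %in%
                  c("hyperglycemia_no_acidosis", "coding_error")),
            length(age_range) == 2L, age_range[1] >= 6, age_range[2] <= 24,
            age_range[1] <= age_range[2],
            p_case >= 0, p_case <= 1, p_ineligible >= 0, p_ineligible <= 1,
            unabstractable_frac >= 0, unabstractable_frac <= 1)
  structure(list(n_persons = as.integer(n_persons),
                 exposure_mix = exposure_mix, true_ppv = true_ppv,
                 fp_mode_weights = fp_mode_weights,
                 age_range = as.integer(age_range), p_case = p_case,
                 p_ineligible = p_ineligible, p_er_reset = p_er_reset,
                 p_death = p_death, p_secondary_dx = p_secondary_dx,
                 days_supply = as.integer(days_supply),
                 mean_refills = mean_refills,
                 unabstractable_frac = unabstractable_frac, labs = labs,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end)),
            class = "sim_config")
}

rtrunc_below <- function(n, mean, sd, upper) {
  pmin(stats::rnorm(n, mean, sd), upper)
}
rtrunc_above <- function(n, mean, sd, lower) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Generate a synthetic claims database with known ground truth
#'
#' Simulates a claims database in which the new-user pipeline's behaviour is
#' known by construction: eligible new users satisfy the 365-day washout and
#' all entry criteria; tagged ineligible persons violate exactly one named
#' criterion; flagged cases carry an inpatient admission with a DKA
#' diagnosis code during follow-up (secondary position with probability
#' `p_secondary_dx`, prior-day emergency diabetes claim with probability
#' `p_er_reset`); and each flagged case is truly DKA with probability
#' `true_ppv`. All randomness flows through R's RNG: set a seed before
#' calling, or pass `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return A list: `db` (a [claims_db()]), `truth` (one row per flagged case:
#'   `person_id`, `admission_date`, `index_date`, `is_true_dka`,
#'   `error_mode`, plus the strata attributes `age_years`, `gender`,
#'   `adhd_dx`, `exposure_group`) and `ineligible` (`person_id`,
#'   `violated_criterion`).
#' @examples
#' sim <- simulate_claims(sim_config(n_persons = 50), seed = 1)
#' sim$db
#' nrow(sim$truth)
#' @export
simulate_claims <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_persons
  if (n == 0L) {
    return(list(db = claims_db(),
                truth = empty_truth(),
                ineligible = tibble::tibble(person_id = character(),
                                            violated_criterion = character())))
  }
  start_i <- as.integer(config$study_start)
  end_i <- as.integer(config$study_end)

  person_id <- sprintf("S%05d", seq_len(n))
  role <- ifelse(stats::runif(n) < config$p_ineligible, "ineligible",
                 "eligible")
  modes <- c("washout", "age", "enrollment_gap", "recent_hosp",
             "exclusion_dx")
  inel_mode <- ifelse(role == "ineligible",
                      sample(modes, n, replace = TRUE), NA_character_)

  flagged <- role == "eligible" & stats::runif(n) < config$p_case
  dies <- role == "eligible" & !flagged & stats::runif(n) < config$p_death

  # qualifying fill date: room for 365-day lookback and ~700 days of
  # follow-up; washout-violators sit early so their breaking fill predates
  # the study window (their only criterion failure is the washout)
  qual_off <- 365L + as.integer(floor(stats::runif(n) *
                                        (end_i - start_i - 365L - 700L)))
  early <- !is.na(inel_mode) & inel_mode == "washout"
  qual_off[early] <- 50L + as.integer(floor(stats::runif(sum(early)) * 100))
  qual <- as.Date(start_i + qual_off, origin = "1970-01-01")

  # demographics; flagged persons capped at 23 so nobody ages out of
  # follow-up before the simulated admission
  ages <- seq.int(config$age_range[1], config$age_range[2])
  age_q <- sample(ages, n, replace = TRUE,
                  prob = stats::dnorm(ages, mean = 11, sd = 5))
  age_q[flagged] <- pmin(age_q[flagged], 23L)
  age_q[!is.na(inel_mode) & inel_mode == "age"] <- 25L
  jitter <- sample(10:200, n, replace = TRUE)
  birth <- qual - round(age_q * 365.25) - jitter
  gender <- sample(c("female", "male"), n, TRUE, prob = c(0.48, 0.52))
  race <- sample(c("caucasian", "african_american", "other"), n, TRUE,
                 prob = c(0.70, 0.20, 0.10))
  urban <- stats::runif(n) < 0.63
  adhd <- stats::runif(n) < 0.53

  persons <- tibble::tibble(person_id = person_id, birth_date = birth,
                            gender = gender, race = race, urban = urban,
                            adhd_dx = adhd)

  # enrollment: continuous around the study period except for the
  # enrollment-gap ineligibles, whose span starts inside the baseline window
  enr_start <- qual - 400L - sample(0:200, n, replace = TRUE)
  gap <- !is.na(inel_mode) & inel_mode == "enrollment_gap"
  enr_start[gap] <- qual[gap] - sample(60:300, sum(gap), replace = TRUE)
  enrollment <- tibble::tibble(person_id = person_id, start_date = enr_start,
                               end_date = qual + 800L)

  # pharmacy: qualifying fill, consecutive refills, occasional non-study
  # fills, and the washout-breaking prior fill
  ap <- stats::runif(n) < config$exposure_mix
  ctl <- sample(setdiff(study_drug_classes(), "antipsychotic"), n, TRUE)
  drug <- ifelse(ap, "antipsychotic", ctl)
  n_refill <- stats::rpois(n, config$mean_refills)
  fills <- tibble::tibble(
    person_id = rep(person_id, n_refill + 1L),
    fill_date = rep(qual, n_refill + 1L) +
      config$days_supply * (sequence(n_refill + 1L) - 1L),
    drug_class = rep(drug, n_refill + 1L),
    days_supply = config$days_supply)
  other <- stats::runif(n) < 0.3
  washout_break <- early
  fills <- dplyr::bind_rows(
    fills,
    tibble::tibble(person_id = person_id[other],
                   fill_date = qual[other] - 100L, drug_class = "other",
                   days_supply = config$days_supply),
    tibble::tibble(person_id = person_id[washout_break],
                   fill_date = qual[washout_break] - 200L,
                   drug_class = drug[washout_break],
                   days_supply = config$days_supply))

  # encounters: baseline outpatient visit for everyone; criterion-specific
  # claims for the tagged ineligibles; the flagging DKA admission (and the
  # optional prior-day emergency diabetes visit)
  base_visit <- tibble::tibble(
    person_id = person_id, setting = "outpatient",
    start_date = qual - sample(30:300, n, replace = TRUE),
    dx_codes = "icd9:V20.2")
  base_visit$end_date <- base_visit$start_date

  excl <- !is.na(inel_mode) & inel_mode == "exclusion_dx"
  excl_enc <- tibble::tibble(
    person_id = person_id[excl], setting = "outpatient",
    start_date = qual[excl] - sample(30:300, sum(excl), replace = TRUE),
    dx_codes = "icd9:295.00")
  excl_enc$end_date <- excl_enc$start_date

  rh <- !is.na(inel_mode) & inel_mode == "recent_hosp"
  rh_enc <- tibble::tibble(
    person_id = person_id[rh], setting = "inpatient",
    start_date = qual[rh] - 15L, end_date = qual[rh] - 10L,
    dx_codes = "icd9:486")

  nf <- sum(flagged)
  admission <- qual[flagged] + sample(45:280, nf, replace = TRUE)
  dka_dx <- sample(c("250.11", "250.13", "250.10"), nf, replace = TRUE)
  secondary <- stats::runif(nf) < config$p_secondary_dx
  dka_enc <- tibble::tibble(
    person_id = person_id[flagged], setting = "inpatient",
    start_date = admission, end_date = admission + 2L,
    dx_codes = ifelse(secondary, paste0("icd9:486;icd9:", dka_dx),
                      paste0("icd9:", dka_dx)))
  er <- stats::runif(nf) < config$p_er_reset
  er_enc <- tibble::tibble(
    person_id = person_id[flagged][er], setting = "emergency",
    start_date = admission[er] - 1L, end_date = admission[er] - 1L,
    dx_codes = "icd9:250.00")

  encounters <- dplyr::bind_rows(base_visit, excl_enc, rh_enc, dka_enc,
                                 er_enc) |>
    dplyr::select("person_id", "setting", "start_date", "end_date",
                  "dx_codes")
  encounters <- encounters |>
    dplyr::mutate(encounter_id = sprintf("E%06d", seq_len(nrow(encounters))),
                  .before = 1L)

  deaths <- tibble::tibble(
    person_id = person_id[dies],
    death_date = qual[dies] + sample(30:200, sum(dies), replace = TRUE))

  is_true <- stats::runif(nf) < config$true_ppv
  mode_names <- names(config$fp_mode_weights)
  error_mode <- rep(NA_character_, nf)
  if (any(!is_true)) {
    error_mode[!is_true] <- sample(mode_names, sum(!is_true), TRUE,
                                   prob = config$fp_mode_weights)
  }
  truth <- tibble::tibble(
    person_id = person_id[flagged],
    admission_date = admission,
    index_date = admission - ifelse(er, 1L, 0L),
    is_true_dka = is_true,
    error_mode = error_mode,
    age_years = age_at(birth[flagged], admission - ifelse(er, 1L, 0L)),
    gender = gender[flagged],
    adhd_dx = adhd[flagged],
    exposure_group = ifelse(ap[flagged], "antipsychotic", "control"))

  list(db = claims_db(persons = persons, enrollment = enrollment,
                      pharmacy = fills, encounters = encounters,
                      deaths = deaths),
       truth = truth,
       ineligible = tibble::tibble(
         person_id = person_id[role == "ineligible"],
         violated_criterion = inel_mode[role == "ineligible"]))
}

empty_truth <- function() {
  tibble::tibble(person_id = character(),
                 admission_date = as.Date(character()),
                 index_date = as.Date(character()),
                 is_true_dka = logical(), error_mode = character(),
                 age_years = integer(), gender = character(),
                 adhd_dx = logical(), exposure_group = character())
}

#' Generate chart-abstraction records for flagged cases
#'
#' Emits one abstraction record per flagged case, consistent with its ground
#' truth: true cases receive glucose above 250 mg/dL plus at least one
#' acidosis laboratory value below threshold (low venous pH, low arterial
#' pH, or low bicarbonate with no pH recorded); `hyperglycemia_no_acidosis`
#' false positives receive glucose above 250 with every recorded pH and
#' bicarbonate above threshold (and a DKA discharge diagnosis — the classic
#' severe-hyperglycemia presentation); `coding_error` false positives receive
#' glucose at or below 250. A fraction `unabstractable_frac` of records is
#' marked unabstractable and carries no laboratory data.
#'
#' @param truth Truth tibble from [simulate_claims()].
#' @param config The matching [sim_config()].
#' @param seed Optional integer seed.
#' @return Abstraction tibble: `person_id`, `abstraction_status`,
#'   `glucose_mg_dl`, `ph_venous`, `ph_arterial`, `ph_capillary`,
#'   `bicarbonate_mmol_l`, `discharge_dx`, `age_years`, `gender`, `adhd_dx`,
#'   `exposure_group`.
#' @export
simulate_abstractions <- function(truth, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(truth)
  if (m == 0L) {
    return(empty_abstractions())
  }
  L <- config$labs
  status <- ifelse(stats::runif(m) < config$unabstractable_frac,
                   sample(c("record_not_located", "facility_refused"), m,
                          TRUE, prob = c(2, 1)),
                   "complete")

  glucose <- ph_v <- ph_a <- ph_c <- bicarb <- rep(NA_real_, m)
  dx <- rep(NA_character_, m)

  tr <- truth$is_true_dka
  ntr <- sum(tr)
  if (ntr) {
    glucose[tr] <- pmax(round(stats::rlnorm(ntr, L$glucose_true_meanlog,
                                            L$glucose_true_sdlog)), 260)
    evidence <- sample(c("venous", "arterial", "bicarb_only"), ntr, TRUE,
                       prob = c(0.5, 0.2, 0.3))
    v <- evidence == "venous"; a <- evidence == "arterial"
    b <- evidence == "bicarb_only"
    ph_v[tr][v] <- round(rtrunc_below(sum(v), L$ph_true_mean, L$ph_true_sd,
                                      7.24), 2)
    ph_a[tr][a] <- round(rtrunc_below(sum(a), L$ph_true_mean + 0.04,
                                      L$ph_true_sd, 7.29), 2)
    bicarb[tr] <- round(rtrunc_below(ntr, L$bicarb_true_mean,
                                     L$bicarb_true_sd, 14.5), 1)
    dx[tr] <- "icd9:250.11"
  }
  hg <- !tr & !is.na(truth$error_mode) &
    truth$error_mode == "hyperglycemia_no_acidosis"
  if (any(hg)) {
    k <- sum(hg)
    glucose[hg] <- pmax(round(stats::rlnorm(k, L$glucose_fp_meanlog,
                                            L$glucose_fp_sdlog)), 255)
    ph_v[hg] <- round(rtrunc_above(k, L$ph_fp_mean, L$ph_fp_sd, 7.26), 2)
    bicarb[hg] <- round(rtrunc_above(k, L$bicarb_fp_mean, L$bicarb_fp_sd,
                                     15.5), 1)
    dx[hg] <- "icd9:250.11"
  }
  ce <- !tr & !is.na(truth$error_mode) & truth$error_mode == "coding_error"
  if (any(ce)) {
    k <- sum(ce)
    glucose[ce] <- round(stats::runif(k, 90, 245))
    ph_v[ce] <- round(rtrunc_above(k, L$ph_fp_mean, L$ph_fp_sd, 7.26), 2)
    bicarb[ce] <- round(rtrunc_above(k, L$bicarb_fp_mean, L$bicarb_fp_sd,
                                     15.5), 1)
    dx[ce] <- "icd9:250.00"
  }

  incomplete <- status != "complete"
  glucose[incomplete] <- NA_real_
  ph_v[incomplete] <- ph_a[incomplete] <- ph_c[incomplete] <- NA_real_
  bicarb[incomplete] <- NA_real_
  dx[incomplete] <- NA_character_

  tibble::tibble(person_id = truth$person_id, abstraction_status = status,
                 glucose_mg_dl = glucose, ph_venous = ph_v,
                 ph_arterial = ph_a, ph_capillary = ph_c,
                 bicarbonate_mmol_l = bicarb, discharge_dx = dx,
                 age_years = truth$age_years, gender = truth$gender,
                 adhd_dx = truth$adhd_dx,
                 exposure_group = truth$exposure_group)
}

empty_abstractions <- function() {
  tibble::tibble(person_id = character(), abstraction_status = character(),
                 glucose_mg_dl = double(), ph_venous = double(),
                 ph_arterial = double(), ph_capillary = double(),
                 bicarbonate_mmol_l = double(), discharge_dx = character(),
                 age_years = integer(), gender = character(),
                 adhd_dx = logical(), exposure_group = character())
}
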