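#' Configuration for new-user cohort construction
#'
#' Collects the tunable parameters of the new-user design: the study window,
#' the study-drug washout, age bounds, baseline and prior-hospitalization
#' windows, the post-use follow-up extension, and the baseline exclusion code
#' sets. Defaults encode a Medicaid cohort of children and youth aged 6-24
#' observed 1996-2007 initiating antipsychotics or control psychotropics.
#'
#' @param study_start,study_end Study window (closed, day granular).
#' @param washout_days Days before a fill that must be free of study-drug
#'   fills for the fill to qualify (strictly-before window).
#' @param age_min,age_max Completed age bounds at the qualifying fill.
#' @param baseline_days Length of the baseline window before the qualifying
#'   fill used for enrollment, utilization and exclusion-diagnosis checks.
#' @param prior_hosp_days No inpatient stay may overlap this many days before
#'   the qualifying fill.
#' @param post_use_days Follow-up extends this many days past the last day of
#'   current study-drug use.
#' @param use_grace_days Grace period when chaining dispensings into use
#'   episodes (0 = a refill must start while prior supply, the post-use
#'   extension, or the grace still covers the person).
#' @param require_baseline_visit Require at least one outpatient encounter in
#'   the baseline window (the operational "adequate health care utilization").
#' @param exclusion_codes Named list of code-set tibbles (see
#'   [default_exclusion_codes()]); a baseline diagnosis matching any set is an
#'   eligibility failure named after the list element.
#' @param er_reset_icd10 Should the emergency-department index-date reset also
#'   match ICD-10 diabetes codes (E10-E14)? Off by default; the reset rule is
#'   defined on ICD-9 250.x.
#' @return A list with class `cohort_config`.
#' @export
cohort_config <- function(study_start = as.Date("1996-01-01"),
                          study_end = as.Date("2007-12-31"),
                          washout_days = 365L,
                          age_min = 6L, age_max = 24L,
                          baseline_days = 365L,
                          prior_hosp_days = 30L,
                          post_use_days = 365L,
                          use_grace_days = 0L,
                          require_baseline_visit = TRUE,
                          exclusion_codes = default_exclusion_codes(),
                          er_reset_icd10 = FALSE) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  stopifnot(study_start < study_end, washout_days > 0, baseline_days > 0,
            prior_hosp_days > 0, post_use_days > 0, use_grace_days >= 0,
            age_min <= age_max, is.list(exclusion_codes))
  structure(list(study_start = study_start, study_end = study_end,
                 washout_days = as.integer(washout_days),
                 age_min = as.integer(age_min), age_max = as.integer(age_max),
                 baseline_days = as.integer(baseline_days),
                 prior_hosp_days = as.integer(prior_hosp_days),
                 post_use_days = as.integer(post_use_days),
                 use_grace_days = as.integer(use_grace_days),
                 require_baseline_visit = isTRUE(require_baseline_visit),
                 exclusion_codes = exclusion_codes,
                 er_reset_icd10 = isTRUE(er_reset_icd10)),
            class = "cohort_config")
}

# Completed age in years at `date`.
age_at <- function(birth_date, date) {
  by <- as.integer(format(birth_date, "%Y"))
  dy <- as.integer(format(date, "%Y"))
  pre <- format(date, "%m%d") < format(birth_date, "%m%d")
  dy - by - as.integer(pre)
}

# Date of the `years`-th birthday; Feb 29 birthdays fall on Mar 1 in
# non-leap years.
birthday <- function(birth_date, years) {
  y <- as.integer(format(birth_date, "%Y")) + years
  md <- format(birth_date, "-%m-%d")
  out <- as.Date(paste0(y, md), format = "%Y-%m-%d")
  fix <- which(is.na(out))
  if (length(fix)) out[fix] <- as.Date(paste0(y[fix], "-03-01"))
  out
}

# Grouped cummax/cumsum on data sorted by group, via the offset trick
# (each group is shifted into its own disjoint value band, so a plain
# cummax/cumsum never leaks across groups).
grouped_cummax <- function(x, new_group, big = 1e9) {
  g <- cumsum(new_group)
  cummax(x + g * big) - g * big
}
grouped_cumsum <- function(x, new_group) {
  cs <- cumsum(x)
  start <- which(new_group)
  base <- rep(cs[start] - x[start], diff(c(start, length(x) + 1L)))
  cs - base
}
grouped_lag <- function(x, new_group) {
  out <- c(x[0][NA], x[-length(x)])
  out[new_group] <- NA
  out
}

# Merge overlapping or adjacent (gap <= 1 day) enrollment spans per person.
normalize_spans <- function(enrollment) {
  if (nrow(enrollment) == 0L) return(enrollment)
  if (!anyDuplicated(enrollment$person_id)) {
    return(dplyr::arrange(enrollment, .data$person_id))
  }
  e <- dplyr::arrange(enrollment, .data$person_id, .data$start_date,
                      .data$end_date)
  new_p <- c(TRUE, e$person_id[-1] != e$person_id[-nrow(e)])
  run_end <- grouped_cummax(as.numeric(e$end_date), new_p)
  prev_end <- grouped_lag(run_end, new_p)
  new_span <- new_p | (is.na(prev_end) | as.numeric(e$start_date) >
                         prev_end + 1)
  span <- cumsum(new_span)
  e |>
    dplyr::mutate(span = span) |>
    dplyr::group_by(.data$person_id, .data$span) |>
    dplyr::summarise(start_date = min(.data$start_date),
                     end_date = max(.data$end_date), .groups = "drop") |>
    dplyr::select("person_id", "start_date", "end_date")
}

#' Find qualifying (new-user) dispensings
#'
#' A study-drug fill qualifies when no study-drug fill for the same person
#' occurs in the `washout_days` days strictly before its date, and the fill
#' date lies within the study window. Fills of class `"other"` neither
#' qualify nor break the washout. Same-day fills do not disqualify each
#' other (the washout window is strictly before the fill date).
#'
#' @param pharmacy A pharmacy claims tibble (`person_id`, `fill_date`,
#'   `drug_class`, `days_supply`).
#' @param config A [cohort_config()].
#' @return Tibble of qualifying fills with an added `exposure_group` column
#'   (`"antipsychotic"` or `"control"`).
#' @export
find_qualifying_fills <- function(pharmacy, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  study <- pharmacy |>
    dplyr::filter(.data$drug_class %in% study_drug_classes()) |>
    dplyr::arrange(.data$person_id, .data$fill_date)
  if (nrow(study) == 0L) {
    return(dplyr::mutate(study, exposure_group = character()))
  }
  # previous distinct study-drug fill date per person: lag over the distinct
  # (person, date) pairs, joined back (same-day fills share the same lag)
  pd <- dplyr::distinct(study, .data$person_id, .data$fill_date)
  new_p <- c(TRUE, pd$person_id[-1] != pd$person_id[-nrow(pd)])
  pd$prev_strict <- as.Date(grouped_lag(as.numeric(pd$fill_date), new_p),
                            origin = "1970-01-01")
  study |>
    dplyr::left_join(pd, by = c("person_id", "fill_date")) |>
    dplyr::filter(
      .data$fill_date >= config$study_start,
      .data$fill_date <= config$study_end,
      is.na(.data$prev_strict) |
        .data$fill_date - .data$prev_strict > config$washout_days) |>
    dplyr::mutate(exposure_group = ifelse(.data$drug_class == "antipsychotic",
                                          "antipsychotic", "control")) |>
    dplyr::select(-"prev_strict")
}

#' Check cohort eligibility at candidate qualifying fills
#'
#' Evaluates every entry criterion at each candidate fill and reports all
#' failures (no short-circuiting): completed age within bounds; continuous
#' enrollment covering the whole baseline window; at least one baseline
#' outpatient visit (if configured); no baseline diagnosis in any exclusion
#' code set; and no inpatient stay overlapping the pre-fill
#' hospitalization-free window.
#'
#' @param candidates Tibble with `person_id` and `fill_date` (one row per
#'   candidate qualifying fill).
#' @param db A [claims_db()].
#' @param config A [cohort_config()].
#' @return `candidates` with columns `eligible` (logical) and
#'   `failed_criteria` (semicolon-joined criterion names, `""` when eligible).
#' @export
check_eligibility <- function(candidates, db, config = cohort_config()) {
  stopifnot(inherits(db, "claims_db"), inherits(config, "cohort_config"))
  missing_p <- setdiff(candidates$person_id, db$persons$person_id)
  if (length(missing_p)) {
    stop("person(s) not in database: ",
         paste(utils::head(missing_p, 5L), collapse = ", "), call. = FALSE)
  }
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, eligible = logical(),
                         failed_criteria = character()))
  }
  cand <- candidates |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::left_join(dplyr::select(db$persons, "person_id", "birth_date"),
                     by = "person_id") |>
    dplyr::mutate(
      base_start = .data$fill_date - config$baseline_days,
      age = age_at(.data$birth_date, .data$fill_date),
      fail_age = .data$age < config$age_min | .data$age > config$age_max)

  spans <- normalize_spans(db$enrollment)
  cov <- cand |>
    dplyr::inner_join(spans, by = "person_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$start_date <= .data$base_start,
                  .data$end_date >= .data$fill_date) |>
    dplyr::distinct(.data$.row)
  cand$fail_enrollment <- !cand$.row %in% cov$.row

  enc <- db$encounters
  if (config$require_baseline_visit) {
    visits <- cand |>
      dplyr::inner_join(
        dplyr::filter(enc, .data$setting == "outpatient") |>
          dplyr::select("person_id", visit_date = "start_date"),
        by = "person_id", relationship = "many-to-many") |>
      dplyr::filter(.data$visit_date >= .data$base_start,
                    .data$visit_date <= .data$fill_date - 1L) |>
      dplyr::distinct(.data$.row)
    cand$fail_baseline_visit <- !cand$.row %in% visits$.row
  } else {
    cand$fail_baseline_visit <- FALSE
  }

  hosp <- cand |>
    dplyr::inner_join(
      dplyr::filter(enc, .data$setting == "inpatient") |>
        dplyr::select("person_id", hosp_start = "start_date",
                      hosp_end = "end_date"),
      by = "person_id", relationship = "many-to-many") |>
    dplyr::filter(.data$hosp_start <= .data$fill_date - 1L,
                  .data$hosp_end >= .data$fill_date - config$prior_hosp_days) |>
    dplyr::distinct(.data$.row)
  cand$fail_recent_hospitalization <- cand$.row %in% hosp$.row

  dx <- dx_unnest(enc)
  excl_fail <- matrix(FALSE, nrow(cand), length(config$exclusion_codes),
                      dimnames = list(NULL, names(config$exclusion_codes)))
  for (set in names(config$exclusion_codes)) {
    hits <- dx[icd_match_any(dx$dx_code, dx$dx_system,
                             config$exclusion_codes[[set]]), ]
    if (nrow(hits) == 0L) next
    rows <- cand |>
      dplyr::inner_join(dplyr::select(hits, "person_id",
                                      dx_date = "start_date"),
                        by = "person_id", relationship = "many-to-many") |>
      dplyr::filter(.data$dx_date >= .data$base_start,
                    .data$dx_date <= .data$fill_date) |>
      dplyr::distinct(.data$.row)
    excl_fail[rows$.row, set] <- TRUE
  }

  fail_cols <- cbind(
    age = cand$fail_age,
    enrollment = cand$fail_enrollment,
    baseline_visit = cand$fail_baseline_visit,
    recent_hospitalization = cand$fail_recent_hospitalization,
    excl_fail)
  colnames(excl_fail) <- paste0("dx_", colnames(excl_fail))
  colnames(fail_cols)[-(1:4)] <- colnames(excl_fail)
  failed <- apply(fail_cols, 1L, function(f) {
    paste(colnames(fail_cols)[f], collapse = ";")
  })
  candidates |>
    dplyr::mutate(eligible = failed == "", failed_criteria = failed)
}

# Last covered day of the "current use" episode anchored at the qualifying
# fill: study-drug fills chain while each next fill starts before the running
# last-use day plus the post-use extension (plus grace); follow-up would still
# be active then, so a later fill resumes use.
last_use_day <- function(members, pharmacy, config) {
  fills <- pharmacy |>
    dplyr::filter(.data$drug_class %in% study_drug_classes()) |>
    dplyr::inner_join(dplyr::select(members, "person_id",
                                    qual_date = "fill_date"),
                      by = "person_id") |>
    dplyr::filter(.data$fill_date >= .data$qual_date) |>
    dplyr::arrange(.data$person_id, .data$fill_date)
  if (nrow(fills) == 0L) {
    return(tibble::tibble(person_id = character(),
                          last_use = as.Date(character())))
  }
  new_p <- c(TRUE, fills$person_id[-1] != fills$person_id[-nrow(fills)])
  supply_end <- as.numeric(fills$fill_date) + fills$days_supply - 1
  run_end <- grouped_cummax(supply_end, new_p)
  prev_end <- grouped_lag(run_end, new_p)
  breaks <- !is.na(prev_end) & as.numeric(fills$fill_date) >
    prev_end + config$post_use_days + config$use_grace_days
  keep <- grouped_cumsum(breaks, new_p) == 0
  le <- supply_end
  le[!keep] <- -Inf
  last_use <- grouped_cummax(le, new_p)
  last_row <- c(new_p[-1], TRUE)  # final row of each person's fill block
  tibble::tibble(person_id = fills$person_id[last_row],
                 last_use = as.Date(last_use[last_row],
                                    origin = "1970-01-01"))
}

#' Compute follow-up end and termination reason
#'
#' Follow-up starts the day after the qualifying fill and ends at the
#' earliest of: study end, the 25th birthday, end of continuous enrollment,
#' death, an exclusion diagnosis appearing on a claim (criteria failure), or
#' `post_use_days` after the last day of current study-drug use. Ties are
#' broken by a fixed reason precedence: death, disenrollment, age_25,
#' criteria_failure, use_lapse, study_end.
#'
#' @param members Tibble with `person_id`, `fill_date` (qualifying fill).
#' @param db A [claims_db()].
#' @param config A [cohort_config()].
#' @return `members` with `followup_start`, `followup_end`, `end_reason`.
#' @export
compute_followup <- function(members, db, config = cohort_config()) {
  stopifnot(inherits(db, "claims_db"), inherits(config, "cohort_config"))
  if (nrow(members) == 0L) {
    return(dplyr::mutate(members, followup_start = as.Date(character()),
                         followup_end = as.Date(character()),
                         end_reason = character()))
  }
  out <- members |>
    dplyr::mutate(followup_start = .data$fill_date + 1L) |>
    dplyr::left_join(dplyr::select(db$persons, "person_id", "birth_date"),
                     by = "person_id") |>
    dplyr::left_join(db$deaths, by = "person_id") |>
    dplyr::mutate(end_age_25 = birthday(.data$birth_date, 25L),
                  end_study = config$study_end)

  spans <- normalize_spans(db$enrollment)
  cover <- out |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::inner_join(spans, by = "person_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$start_date <= .data$followup_start,
                  .data$end_date >= .data$followup_start) |>
    dplyr::arrange(.data$.row, dplyr::desc(.data$end_date)) |>
    dplyr::distinct(.data$.row, .keep_all = TRUE) |>
    dplyr::select(".row", end_enroll = "end_date")
  out$end_enroll <- out$followup_start  # no covering span: ends immediately
  out$end_enroll[cover$.row] <- cover$end_enroll

  use <- last_use_day(members, db$pharmacy, config)
  out <- out |>
    dplyr::left_join(use, by = "person_id") |>
    dplyr::mutate(end_use = .data$last_use + config$post_use_days)

  # exclusion diagnoses during follow-up, evaluated at claim dates
  dx <- dx_unnest(db$encounters)
  excl_any <- rep(FALSE, nrow(dx))
  for (set in config$exclusion_codes) {
    excl_any <- excl_any | icd_match_any(dx$dx_code, dx$dx_system, set)
  }
  fail <- out |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::inner_join(dplyr::select(dx[excl_any, ], "person_id",
                                    dx_date = "start_date"),
                      by = "person_id", relationship = "many-to-many") |>
    dplyr::filter(.data$dx_date >= .data$followup_start) |>
    dplyr::arrange(.data$.row, .data$dx_date) |>
    dplyr::distinct(.data$.row, .keep_all = TRUE) |>
    dplyr::select(".row", end_fail = "dx_date")
  out$end_fail <- as.Date(NA)
  out$end_fail[fail$.row] <- fail$end_fail

  # precedence order for ties (first wins)
  reasons <- c(death = "death_date", disenrollment = "end_enroll",
               age_25 = "end_age_25", criteria_failure = "end_fail",
               use_lapse = "end_use", study_end = "end_study")
  ends <- vapply(reasons, function(col) as.integer(out[[col]]),
                 integer(nrow(out)))
  if (nrow(out) == 1L) ends <- matrix(ends, nrow = 1L,
                                      dimnames = list(NULL, names(reasons)))
  ends[is.na(ends)] <- .Machine$integer.max
  best <- apply(ends, 1L, which.min)
  end_int <- ends[cbind(seq_len(nrow(out)), best)]
  members |>
    dplyr::mutate(
      followup_start = .data$fill_date + 1L,
      followup_end = pmax(as.Date(end_int, origin = "1970-01-01"),
                          .data$followup_start),
      end_reason = names(reasons)[best])
}

#' Build the new-user cohort
#'
#' Composes [find_qualifying_fills()], [check_eligibility()] and
#' [compute_followup()]: each person enters the cohort at their first
#' qualifying fill that passes all eligibility criteria. Output is ordered by
#' `person_id`.
#'
#' @param db A [claims_db()].
#' @param config A [cohort_config()].
#' @return Cohort tibble: `person_id`, `fill_date` (qualifying fill),
#'   `drug_class`, `exposure_group`, `followup_start`, `followup_end`,
#'   `end_reason`.
#' @examples
#' study <- dka_reference_study()
#' cohort <- build_cohort(study$db)
#' nrow(cohort)
#' @export
build_cohort <- function(db, config = cohort_config()) {
  qual <- find_qualifying_fills(db$pharmacy, config)
  if (nrow(qual) == 0L) {
    return(tibble::tibble(person_id = character(),
                          fill_date = as.Date(character()),
                          drug_class = character(),
                          exposure_group = character(),
                          followup_start = as.Date(character()),
                          followup_end = as.Date(character()),
                          end_reason = character()))
  }
  elig <- check_eligibility(qual, db, config)
  members <- elig |>
    dplyr::filter(.data$eligible) |>
    dplyr::arrange(.data$person_id, .data$fill_date, .data$drug_class) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
    dplyr::select("person_id", "fill_date", "drug_class", "exposure_group")
  compute_followup(members, db, config) |>
    dplyr::arrange(.data$person_id)
}
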