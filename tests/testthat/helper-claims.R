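# Small constructors for hand-built test databases.

d <- function(x) as.Date(x)

mk_person <- function(id, birth = "1990-06-15", gender = "male",
                      race = "caucasian", urban = TRUE, adhd = FALSE) {
  tibble::tibble(person_id = id, birth_date = d(birth), gender = gender,
                 race = race, urban = urban, adhd_dx = adhd)
}

mk_enroll <- function(id, start, end) {
  tibble::tibble(person_id = id, start_date = d(start), end_date = d(end))
}

mk_fill <- function(id, date, class = "antipsychotic", supply = 30L) {
  tibble::tibble(person_id = id, fill_date = d(date), drug_class = class,
                 days_supply = as.integer(supply))
}

mk_enc <- function(id, setting, start, end = start, dx = "icd9:V20.2",
                   enc_id = NULL) {
  tibble::tibble(encounter_id = enc_id %||% paste0("enc-", id, "-", start),
                 person_id = id, setting = setting, start_date = d(start),
                 end_date = d(end), dx_codes = dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One eligible person with a qualifying antipsychotic fill on `fill`, a
# baseline outpatient visit, and enrollment around the fill.
mk_simple_db <- function(id = "p1", fill = "2000-06-01", birth = "1990-06-15",
                         class = "antipsychotic", supply = 30L,
                         extra_fills = NULL, extra_enc = NULL,
                         deaths = NULL, enroll_start = NULL,
                         enroll_end = NULL, adhd = FALSE, gender = "male") {
  fill <- d(fill)
  claims_db(
    persons = mk_person(id, birth, gender = gender, adhd = adhd),
    enrollment = mk_enroll(id, enroll_start %||% (fill - 450L),
                           enroll_end %||% (fill + 900L)),
    pharmacy = dplyr::bind_rows(mk_fill(id, fill, class, supply),
                                extra_fills),
    encounters = dplyr::bind_rows(mk_enc(id, "outpatient", fill - 90L),
                                  extra_enc),
    deaths = deaths)
}

# An abstraction row with sensible defaults (confirmed true case).
mk_record <- function(id = "p1", status = "complete", glucose = 480,
                      ph_v = 7.10, ph_a = NA_real_, ph_c = NA_real_,
                      bicarb = NA_real_, dx = "icd9:250.11", age = 12L,
                      gender = "male", adhd = FALSE,
                      exposure = "antipsychotic") {
  tibble::tibble(person_id = id, abstraction_status = status,
                 glucose_mg_dl = glucose, ph_venous = ph_v,
                 ph_arterial = ph_a, ph_capillary = ph_c,
                 bicarbonate_mmol_l = bicarb, discharge_dx = dx,
                 age_years = age, gender = gender, adhd_dx = adhd,
                 exposure_group = exposure)
}
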