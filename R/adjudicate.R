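#' Laboratory evidence of metabolic acidosis
#'
#' A record shows acidosis when any recorded blood pH is below its
#' specimen-specific threshold — 7.25 for venous, 7.30 for arterial or
#' capillary — or the (minimum) blood bicarbonate is below 15 mmol/L. All
#' comparisons are strict; missing laboratory values never count as evidence
#' (a record with no labs at all returns `FALSE`). When several values per
#' specimen were recorded, the table stores the per-specimen minimum, which
#' is equivalent under these any-of semantics.
#'
#' @param records Abstraction tibble with columns `ph_venous`, `ph_arterial`,
#'   `ph_capillary` (minimum recorded pH per specimen, `NA` if none) and
#'   `bicarbonate_mmol_l` (minimum recorded value, `NA` if none).
#' @return Logical vector.
#' @examples
#' meets_acidosis(tibble::tibble(ph_venous = c(7.20, 7.25, NA),
#'                               ph_arterial = NA_real_,
#'                               ph_capillary = NA_real_,
#'                               bicarbonate_mmol_l = c(NA, 18, 12)))
#' @export
meets_acidosis <- function(records) {
  lt <- function(x, thr) !is.na(x) & x < thr
  lt(records$ph_venous, 7.25) |
    lt(records$ph_arterial, 7.30) |
    lt(records$ph_capillary, 7.30) |
    lt(records$bicarbonate_mmol_l, 15)
}

#' Adjudicate abstracted records against the clinical DKA definition
#'
#' Applies the gold-standard confirmation rule to chart-abstraction records:
#' a confirmed case requires a random blood glucose above 250 mg/dL together
#' with laboratory acidosis (see [meets_acidosis()]). A DKA discharge
#' diagnosis is recorded among the criteria met but is never decisive under
#' the default `strict` policy: a record with hyperglycemia and normal pH and
#' bicarbonate is not confirmed even when discharged as DKA. The
#' `dx_fallback` policy additionally confirms records with qualifying
#' glucose, a DKA discharge diagnosis, and *no* pH or bicarbonate recorded at
#' all (acidosis unevaluable rather than absent).
#'
#' Records whose `abstraction_status` is not `"complete"` are not adjudicable
#' and are returned with `adjudicable = FALSE` and `confirmed = NA`.
#'
#' @param records Abstraction tibble; see [simulate_abstractions()] for the
#'   schema.
#' @param policy `"strict"` (default) or `"dx_fallback"`.
#' @return `records` with columns `adjudicable`, `confirmed`, `criteria_met`
#'   (semicolon-joined subset of `glucose`, `ph`, `bicarbonate`,
#'   `discharge_dx`) and `policy` appended.
#' @examples
#' recs <- tibble::tibble(
#'   person_id = c("a", "b"), abstraction_status = "complete",
#'   glucose_mg_dl = c(480, 520), ph_venous = c(7.10, 7.38),
#'   ph_arterial = NA_real_, ph_capillary = NA_real_,
#'   bicarbonate_mmol_l = c(8, 22), discharge_dx = "icd9:250.11")
#' adjudicate(recs)
#' @export
adjudicate <- function(records, policy = c("strict", "dx_fallback")) {
  policy <- match.arg(policy)
  if (nrow(records) == 0L) {
    return(dplyr::mutate(records, adjudicable = logical(),
                         confirmed = logical(), criteria_met = character(),
                         policy = character()))
  }
  complete <- records$abstraction_status == "complete"
  glucose <- !is.na(records$glucose_mg_dl) & records$glucose_mg_dl > 250
  ph_low <- {
    lt <- function(x, thr) !is.na(x) & x < thr
    lt(records$ph_venous, 7.25) | lt(records$ph_arterial, 7.30) |
      lt(records$ph_capillary, 7.30)
  }
  bicarb_low <- !is.na(records$bicarbonate_mmol_l) &
    records$bicarbonate_mmol_l < 15
  dx_dka <- vapply(records$discharge_dx, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    any(vapply(parts, function(p) {
      icd_match(p[2], p[1], "250.1", "icd9") ||
        icd_match(p[2], p[1], "E1x.1", "icd10")
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)

  no_acid_labs <- is.na(records$ph_venous) & is.na(records$ph_arterial) &
    is.na(records$ph_capillary) & is.na(records$bicarbonate_mmol_l)
  confirmed <- glucose & (ph_low | bicarb_low)
  if (policy == "dx_fallback") {
    confirmed <- confirmed | (glucose & no_acid_labs & dx_dka)
  }
  met <- cbind(glucose = glucose, ph = ph_low, bicarbonate = bicarb_low,
               discharge_dx = dx_dka)
  criteria <- apply(met, 1L, function(m) {
    paste(colnames(met)[m], collapse = ";")
  })
  records |>
    dplyr::mutate(adjudicable = complete,
                  confirmed = ifelse(complete, confirmed, NA),
                  criteria_met = ifelse(complete, criteria, NA_character_),
                  policy = policy)
}
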