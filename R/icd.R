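#' Normalize an ICD diagnosis code to canonical dotted form
#'
#' Claims extracts carry ICD codes in both dotted (`"250.11"`) and dotless
#' (`"25011"`) forms. This canonicalizes to the dotted form: uppercase, with a
#' dot inserted after the third character when further characters follow
#' (`"25011"` becomes `"250.11"`, `"E1110"` becomes `"E11.10"`). Codes of three
#' or fewer characters are returned without a dot. The function is idempotent.
#'
#' @param code Character vector of raw ICD code strings.
#' @param system Code system, `"icd9"` or `"icd10"` (recycled). Retained for
#'   interface symmetry; normalization is identical for both systems.
#' @return Character vector of canonical dotted codes.
#' @examples
#' icd_normalize(c("25011", "E1110", "250.11"))
#' @export
icd_normalize <- function(code, system = "icd9") {
  if (length(code) == 0L) return(character())
  code <- toupper(as.character(code))
  bare <- gsub(".", "", code, fixed = TRUE)
  bad <- !grepl("^[A-Z0-9]+$", bare)
  if (any(bad)) {
    stop("malformed ICD code(s): ",
         paste(utils::head(code[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  ifelse(nchar(bare) > 3L,
         paste0(substr(bare, 1L, 3L), ".", substr(bare, 4L, nchar(bare))),
         bare)
}

# Expand a pattern containing the 'x' wildcard (one digit per 'x') into the
# set of literal dotless prefixes it denotes. "E1x.1" -> E101, E111, ..., E191.
icd_expand_pattern <- function(pattern) {
  bare <- gsub(".", "", toupper(pattern), fixed = TRUE)
  if (!grepl("^[A-Z0-9X]+$", bare)) {
    stop("malformed ICD pattern: ", pattern, call. = FALSE)
  }
  pos <- which(strsplit(bare, "")[[1]] == "X")
  if (length(pos) == 0L) return(bare)
  if (length(pos) > 2L) {
    stop("unsupported ICD pattern (too many wildcards): ", pattern,
         call. = FALSE)
  }
  out <- bare
  for (p in pos) {
    out <- as.vector(vapply(out, function(s) {
      vapply(0:9, function(d) {
        substr(s, p, p) <- as.character(d)
        s
      }, character(1))
    }, character(10)))
  }
  out
}

#' Match ICD codes against a diagnosis code pattern
#'
#' Pattern matching follows the convention of claims research code sets: a
#' pattern such as `"250.1"` is a truncated prefix accepting the whole family
#' (`250.1`, `250.10`, `250.11`, ...), and the wildcard `x` stands for any
#' single digit, so `"E1x.1"` accepts `E11.10` and its siblings. Matching is
#' insensitive to dot placement, and a code never matches a pattern from a
#' different code system.
#'
#' @param code Character vector of ICD codes (dotted or dotless).
#' @param system Character vector, `"icd9"` or `"icd10"`, the system of each
#'   code (recycled against `code`).
#' @param pattern A single pattern string.
#' @param pattern_system Code system of the pattern.
#' @return Logical vector, `TRUE` where the code falls under the pattern.
#' @examples
#' icd_match(c("250.11", "250.00"), "icd9", "250.1", "icd9")
#' icd_match("E1110", "icd10", "E1x.1", "icd10")
#' @export
icd_match <- function(code, system, pattern, pattern_system) {
  stopifnot(length(pattern) == 1L, length(pattern_system) == 1L)
  if (length(code) == 0L) return(logical())
  system <- rep_len(system, length(code))
  bare <- gsub(".", "", toupper(icd_normalize(code)), fixed = TRUE)
  prefixes <- icd_expand_pattern(pattern)
  hit <- rep(FALSE, length(bare))
  for (pf in prefixes) {
    hit <- hit | startsWith(bare, pf)
  }
  hit & (system == pattern_system)
}

#' Match codes against a code-set table
#'
#' A code set is a tibble with columns `pattern` and `system`; a code matches
#' the set when it matches any row. This is the vectorized workhorse behind
#' case finding and eligibility exclusions.
#'
#' @param code,system Character vectors as in [icd_match()].
#' @param codeset A data frame with columns `pattern`, `system`.
#' @return Logical vector.
#' @export
icd_match_any <- function(code, system, codeset) {
  stopifnot(is.data.frame(codeset), all(c("pattern", "system") %in% names(codeset)))
  if (length(code) == 0L) return(logical())
  hit <- rep(FALSE, length(code))
  for (i in seq_len(nrow(codeset))) {
    hit <- hit | icd_match(code, system, codeset$pattern[i], codeset$system[i])
  }
  hit
}

#' Diagnosis code sets used by the case definition
#'
#' `dka_codes()` is the code family flagging diabetic ketoacidosis on an
#' inpatient claim: ICD-9 250.1x and ICD-10 E10.1-E14.1 (the `E1x.1`
#' family). `diabetes_codes()` is the broader any-diabetes family used by the
#' index-date reset rule (ICD-9 250.x; ICD-10 E10-E14 available behind
#' `include_icd10 = TRUE` for databases whose emergency claims carry ICD-10).
#'
#' @param include_icd10 For `diabetes_codes()`: include the ICD-10 family.
#' @return A tibble with columns `pattern`, `system`.
#' @export
dka_codes <- function() {
  tibble::tibble(pattern = c("250.1", "E1x.1"),
                 system = c("icd9", "icd10"))
}

#' @rdname dka_codes
#' @export
diabetes_codes <- function(include_icd10 = FALSE) {
  out <- tibble::tibble(pattern = "250", system = "icd9")
  if (include_icd10) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(pattern = "E1x", system = "icd10"))
  }
  out
}

#' Default eligibility-exclusion code sets
#'
#' Named list of code-set tibbles for the baseline exclusion criteria of the
#' new-user cohort: schizophrenia and related psychoses, any diabetes,
#' pregnancy, polycystic ovarian syndrome, and life-threatening illness
#' (malignant neoplasms as the operational stand-in). Each element has the
#' [dka_codes()] shape and can be replaced wholesale in [cohort_config()].
#'
#' @return Named list of tibbles with columns `pattern`, `system`.
#' @export
default_exclusion_codes <- function() {
  list(
    psychosis = tibble::tibble(pattern = c("295", "297", "298"),
                               system = "icd9"),
    diabetes = tibble::tibble(pattern = c("250", "E1x"),
                              system = c("icd9", "icd10")),
    pregnancy = tibble::tibble(pattern = c("63x", "64x", "65x", "66x", "67x", "V22"),
                               system = "icd9"),
    pcos = tibble::tibble(pattern = "256.4", system = "icd9"),
    life_threatening = tibble::tibble(pattern = c("14x", "15x", "16x", "17x",
                                                  "18x", "19x", "20x"),
                                      system = "icd9")
  )
}
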