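#' Assemble a claims database
#'
#' Bundles the five core tables of a Medicaid-like claims extract into a
#' validated container. Referential integrity (every `person_id` in a child
#' table must appear in `persons`) and basic invariants (enrollment
#' `start_date <= end_date`, positive `days_supply`, at most one death per
#' person) are enforced at construction.
#'
#' Expected columns:
#' \describe{
#'   \item{persons}{`person_id`, `birth_date` (Date), `gender`
#'     (`"male"`/`"female"`), `race` (`"caucasian"`/`"african_american"`/
#'     `"other"`), `urban` (logical), `adhd_dx` (logical).}
#'   \item{enrollment}{`person_id`, `start_date`, `end_date` — closed
#'     day-granular coverage spans.}
#'   \item{pharmacy}{`person_id`, `fill_date`, `drug_class` (one of
#'     `r paste0('"', drug_classes(), '"', collapse = ", ")`), `days_supply`.}
#'   \item{encounters}{`encounter_id`, `person_id`, `setting` (`"inpatient"`/
#'     `"outpatient"`/`"emergency"`), `start_date`, `end_date`, `dx_codes`
#'     (semicolon-joined, each code tagged `system:code`, e.g.
#'     `"icd9:250.11;icd9:486"`).}
#'   \item{deaths}{`person_id`, `death_date`.}
#' }
#'
#' @param persons,enrollment,pharmacy,encounters,deaths Data frames as above;
#'   omitted tables default to empty.
#' @return An object of class `claims_db`: a named list of five tibbles.
#' @examples
#' db <- claims_db(persons = tibble::tibble(
#'   person_id = "p1", birth_date = as.Date("2000-06-01"),
#'   gender = "female", race = "caucasian", urban = TRUE, adhd_dx = FALSE))
#' db
#' @export
claims_db <- function(persons = NULL, enrollment = NULL, pharmacy = NULL,
                      encounters = NULL, deaths = NULL) {
  skel <- empty_claims_tables()
  db <- list(
    persons = coerce_table(persons, skel$persons, "persons"),
    enrollment = coerce_table(enrollment, skel$enrollment, "enrollment"),
    pharmacy = coerce_table(pharmacy, skel$pharmacy, "pharmacy"),
    encounters = coerce_table(encounters, skel$encounters, "encounters"),
    deaths = coerce_table(deaths, skel$deaths, "deaths")
  )
  validate_claims_db(db)
  structure(db, class = "claims_db")
}

drug_classes <- function() {
  c("antipsychotic", "mood_stabilizer", "adhd_drug", "antidepressant",
    "benzodiazepine", "other")
}

# Drug classes counted as study drugs (washout-breaking; qualify for entry).
study_drug_classes <- function() {
  setdiff(drug_classes(), "other")
}

empty_claims_tables <- function() {
  d0 <- as.Date(character())
  list(
    persons = tibble::tibble(person_id = character(), birth_date = d0,
                             gender = character(), race = character(),
                             urban = logical(), adhd_dx = logical()),
    enrollment = tibble::tibble(person_id = character(), start_date = d0,
                                end_date = d0),
    pharmacy = tibble::tibble(person_id = character(), fill_date = d0,
                              drug_class = character(),
                              days_supply = integer()),
    encounters = tibble::tibble(encounter_id = character(),
                                person_id = character(), setting = character(),
                                start_date = d0, end_date = d0,
                                dx_codes = character()),
    deaths = tibble::tibble(person_id = character(), death_date = d0)
  )
}

coerce_table <- function(x, skeleton, name) {
  if (is.null(x)) return(skeleton)
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(names(skeleton), names(x))
  if (length(missing_cols)) {
    stop("table '", name, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[names(skeleton)]
  for (col in names(skeleton)) {
    if (inherits(skeleton[[col]], "Date") && !inherits(x[[col]], "Date")) {
      parsed <- as.Date(as.character(x[[col]]), format = "%Y-%m-%d")
      if (anyNA(parsed) && !all(is.na(x[[col]]))) {
        bad <- which(is.na(parsed) & !is.na(x[[col]]))[1]
        stop("table '", name, "', row ", bad, ": unparseable date '",
             x[[col]][bad], "'", call. = FALSE)
      }
      x[[col]] <- parsed
    }
    if (is.integer(skeleton[[col]])) x[[col]] <- as.integer(x[[col]])
    if (is.character(skeleton[[col]])) x[[col]] <- as.character(x[[col]])
    if (is.logical(skeleton[[col]])) x[[col]] <- as.logical(x[[col]])
  }
  x
}

validate_claims_db <- function(db) {
  if (anyDuplicated(db$persons$person_id)) {
    stop("duplicate person_id in persons table", call. = FALSE)
  }
  for (tab in c("enrollment", "pharmacy", "encounters", "deaths")) {
    orphan <- !db[[tab]]$person_id %in% db$persons$person_id
    if (any(orphan)) {
      stop("integrity error: table '", tab, "', row ", which(orphan)[1],
           ": person_id '", db[[tab]]$person_id[which(orphan)[1]],
           "' not present in persons table", call. = FALSE)
    }
  }
  if (any(db$enrollment$start_date > db$enrollment$end_date)) {
    stop("enrollment span with start_date > end_date", call. = FALSE)
  }
  if (any(db$encounters$start_date > db$encounters$end_date)) {
    stop("encounter with start_date > end_date", call. = FALSE)
  }
  if (nrow(db$pharmacy) && any(db$pharmacy$days_supply < 1L)) {
    stop("pharmacy claim with days_supply < 1", call. = FALSE)
  }
  if (anyDuplicated(db$deaths$person_id)) {
    stop("more than one death record for a person", call. = FALSE)
  }
  bad_class <- !db$pharmacy$drug_class %in% drug_classes()
  if (any(bad_class)) {
    stop("unknown drug_class: ", db$pharmacy$drug_class[which(bad_class)[1]],
         call. = FALSE)
  }
  invisible(db)
}

#' @export
print.claims_db <- function(x, ...) {
  cat("<claims_db>\n")
  for (tab in names(x)) {
    cat(sprintf("  %-10s %6d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

# ---- diagnosis-list encoding ------------------------------------------------

#' Encode and decode encounter diagnosis lists
#'
#' Encounter rows store their ordered diagnosis list as a single
#' semicolon-joined string of `system:code` tags (`"icd9:250.11;icd9:486"`).
#' `dx_unnest()` expands an encounter table to one row per diagnosis with
#' columns `dx_system`, `dx_code` and the original `dx_pos` (1 = primary);
#' `dx_encode()` builds the string form from parallel vectors.
#'
#' @param encounters An encounter tibble with a `dx_codes` column.
#' @return `dx_unnest()`: the encounter table in long form.
#' @export
dx_unnest <- function(encounters) {
  if (nrow(encounters) == 0L) {
    return(dplyr::mutate(encounters, dx_pos = integer(),
                         dx_system = character(), dx_code = character()))
  }
  parts <- strsplit(encounters$dx_codes, ";", fixed = TRUE)
  n <- lengths(parts)
  out <- encounters[rep(seq_len(nrow(encounters)), n), ]
  flat <- unlist(parts, use.names = FALSE)
  sys_code <- strsplit(flat, ":", fixed = TRUE)
  out$dx_pos <- unlist(lapply(n, seq_len), use.names = FALSE)
  out$dx_system <- vapply(sys_code, `[`, character(1), 1L)
  out$dx_code <- vapply(sys_code, `[`, character(1), 2L)
  if (anyNA(out$dx_code)) {
    stop("malformed dx_codes entry (expected 'system:code'): ",
         flat[which(is.na(out$dx_code))[1]], call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' @rdname dx_unnest
#' @param system,code Parallel character vectors of code systems and codes.
#' @export
dx_encode <- function(system, code) {
  stopifnot(length(system) == length(code))
  paste(paste(system, code, sep = ":"), collapse = ";")
}

# ---- CSV I/O ----------------------------------------------------------------

claims_csv_files <- function() {
  c(persons = "persons.csv", enrollment = "enrollment.csv",
    pharmacy = "pharmacy.csv", encounters = "encounters.csv",
    deaths = "deaths.csv")
}

#' Read a claims database from a directory of CSV files
#'
#' Reads `persons.csv`, `enrollment.csv`, `pharmacy.csv`, `encounters.csv` and
#' `deaths.csv` (comma-separated, UTF-8, ISO-8601 dates, header row) from
#' `dir` and returns a validated [claims_db()]. Missing child-table files are
#' treated as empty; `persons.csv` is required.
#'
#' @param dir Directory containing the CSV files.
#' @return A `claims_db` object.
#' @seealso [write_claims_db()] for the inverse; the pair round-trips.
#' @export
read_claims_db <- function(dir) {
  files <- claims_csv_files()
  path <- file.path(dir, files["persons"])
  if (!file.exists(path)) {
    stop("missing required file: ", path, call. = FALSE)
  }
  read_one <- function(tab) {
    p <- file.path(dir, files[[tab]])
    if (!file.exists(p)) return(NULL)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  tabs <- lapply(stats::setNames(nm = names(files)), read_one)
  claims_db(persons = tabs$persons, enrollment = tabs$enrollment,
            pharmacy = tabs$pharmacy, encounters = tabs$encounters,
            deaths = tabs$deaths)
}

#' Write a claims database to a directory of CSV files
#'
#' @param db A `claims_db` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_claims_db <- function(db, dir) {
  stopifnot(inherits(db, "claims_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- claims_csv_files()
  for (tab in names(files)) {
    readr::write_csv(db[[tab]], file.path(dir, files[[tab]]), progress = FALSE)
  }
  invisible(dir)
}
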