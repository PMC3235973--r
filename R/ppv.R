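#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson (score) interval, obtained by inverting the normal
#' approximation to the score test, with the exact normal quantile
#' `z = qnorm((1 + conf.level)/2)` and no continuity correction. The interval
#' always contains the point estimate `x/n`, its bounds stay inside [0, 1],
#' and it degenerates gracefully at `x = 0` (lower bound exactly 0) and
#' `x = n` (upper bound exactly 1). Vectorized over `x` and `n`.
#'
#' @param x Number of successes (confirmed cases), `0 <= x <= n`.
#' @param n Number of trials (adjudicated cases), `n >= 1`.
#' @param conf.level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `x`, `n`, `estimate`, `conf.low`,
#'   `conf.high` (all proportions, not percents).
#' @examples
#' wilson_interval(24, 27)
#' wilson_interval(c(0, 17), c(10, 17))
#' @export
wilson_interval <- function(x, n, conf.level = 0.95) {
  stopifnot(length(conf.level) == 1L, conf.level > 0, conf.level < 1)
  if (any(n < 1)) stop("wilson_interval requires n >= 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  k <- vctrs_recycle(x, n)
  x <- k$x; n <- k$n
  z <- stats::qnorm((1 + conf.level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(x = x, n = n, estimate = p,
                 conf.low = pmax(centre - half, 0),
                 conf.high = pmin(centre + half, 1))
}

vctrs_recycle <- function(x, n) {
  len <- max(length(x), length(n))
  list(x = rep_len(x, len), n = rep_len(n, len))
}

# Round half away from zero at `digits` decimals (commercial rounding used
# for reported percentages; base round() rounds half to even).
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Positive predictive value of the case definition
#'
#' Computes the PPV — the proportion of adjudicated potential cases that the
#' gold standard confirmed — with its Wilson confidence interval. Records
#' flagged non-adjudicable (incomplete abstraction) are excluded from both
#' numerator and denominator. Percentages are kept at full precision;
#' [ppv_report()] applies the one-decimal display rounding.
#'
#' @param adjudicated Output of [adjudicate()].
#' @param conf.level Confidence level; default 0.95.
#' @return One-row tibble: `stratum`, `level`, `n` (adjudicated), `x`
#'   (confirmed), `ppv`, `conf.low`, `conf.high` (percent scale).
#' @examples
#' study <- dka_reference_study()
#' adjudicate(study$abstractions) |> compute_ppv()
#' @export
compute_ppv <- function(adjudicated, conf.level = 0.95) {
  adj <- dplyr::filter(adjudicated, .data$adjudicable)
  if (nrow(adj) == 0L) {
    stop("no adjudicable records: PPV undefined", call. = FALSE)
  }
  n <- nrow(adj)
  x <- sum(adj$confirmed)
  wi <- wilson_interval(x, n, conf.level)
  tibble::tibble(stratum = "overall", level = "all", n = n, x = x,
                 ppv = 100 * x / n,
                 conf.low = 100 * wi$conf.low, conf.high = 100 * wi$conf.high)
}

#' Default stratification rules
#'
#' The stratifying variables of the validation analysis: psychotropic drug
#' exposure (antipsychotic vs control-medication initiator), age stratum at
#' the index date (lower, age 10 and below, vs upper, ages 11-24), gender,
#' and presence of an ADHD diagnosis. Each rule is a function mapping the
#' adjudicated tibble to a character vector of stratum levels; rules must
#' partition (no `NA` levels).
#'
#' @return Named list of rule functions.
#' @export
default_strata <- function() {
  list(
    exposure = function(d) {
      ifelse(d$exposure_group == "antipsychotic", "antipsychotic", "control")
    },
    age = function(d) ifelse(d$age_years <= 10, "lower_6_10", "upper_11_24"),
    gender = function(d) d$gender,
    adhd = function(d) ifelse(d$adhd_dx, "yes", "no")
  )
}

#' Stratified positive predictive values
#'
#' Applies each stratification rule to the adjudicated records and computes a
#' PPV with Wilson interval per stratum level. Within every rule the stratum
#' sizes sum to the overall adjudicated count.
#'
#' @param adjudicated Output of [adjudicate()] carrying the strata attributes
#'   (`exposure_group`, `age_years`, `gender`, `adhd_dx` for the defaults).
#' @param strata Named list of rule functions; see [default_strata()].
#' @param conf.level Confidence level; default 0.95.
#' @return Tibble with one row per stratum level, same columns as
#'   [compute_ppv()].
#' @examples
#' study <- dka_reference_study()
#' adjudicate(study$abstractions) |> stratified_ppv()
#' @export
stratified_ppv <- function(adjudicated, strata = default_strata(),
                           conf.level = 0.95) {
  adj <- dplyr::filter(adjudicated, .data$adjudicable)
  if (nrow(adj) == 0L) {
    stop("no adjudicable records: PPV undefined", call. = FALSE)
  }
  purrr::imap(strata, function(rule, name) {
    lev <- rule(adj)
    if (anyNA(lev)) {
      stop("stratification rule '", name, "' produced NA for record(s): ",
           paste(utils::head(adj$person_id[is.na(lev)], 5L), collapse = ", "),
           call. = FALSE)
    }
    adj |>
      dplyr::mutate(level = lev) |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(n = dplyr::n(), x = sum(.data$confirmed),
                       .groups = "drop") |>
      dplyr::mutate(stratum = name)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      ppv = 100 * .data$x / .data$n,
      conf.low = 100 * wilson_interval(.data$x, .data$n, conf.level)$conf.low,
      conf.high = 100 * wilson_interval(.data$x, .data$n, conf.level)$conf.high
    ) |>
    dplyr::select("stratum", "level", "n", "x", "ppv", "conf.low",
                  "conf.high")
}

#' Render the validation report
#'
#' Formats overall and stratified PPV results as the familiar validation
#' table — PPV (%) with its 95% CI per stratum, one decimal place, half-up
#' rounding — and optionally writes a plain-text and a machine-readable CSV
#' version.
#'
#' @param results Tibble of rows from [compute_ppv()] /
#'   [stratified_ppv()] (bind them with `dplyr::bind_rows()`).
#' @param txt_path,csv_path Optional output file paths.
#' @return The display tibble (rounded columns `ppv`, `conf.low`,
#'   `conf.high`), invisibly; the text rendering is attached as attribute
#'   `"text"` and printed when interactive paths are omitted.
#' @export
ppv_report <- function(results, txt_path = NULL, csv_path = NULL) {
  disp <- results |>
    dplyr::mutate(ppv = round_half_up(.data$ppv, 1L),
                  conf.low = round_half_up(.data$conf.low, 1L),
                  conf.high = round_half_up(.data$conf.high, 1L))
  lines <- c(
    "Positive predictive value of the computer case definition",
    sprintf("%-12s %-14s %5s %5s %8s  %s",
            "stratum", "level", "n", "x", "PPV(%)", "95% CI"),
    sprintf("%-12s %-14s %5d %5d %8.1f  %.1f to %.1f",
            disp$stratum, disp$level, disp$n, disp$x, disp$ppv,
            disp$conf.low, disp$conf.high))
  if (!is.null(txt_path)) writeLines(lines, txt_path)
  if (!is.null(csv_path)) readr::write_csv(disp, csv_path, progress = FALSE)
  attr(disp, "text") <- lines
  invisible(disp)
}
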