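#' Validate the case definition end to end
#'
#' Runs the full validation pipeline on a claims database and its
#' chart-abstraction set: builds the new-user cohort, applies the computer
#' case definition to flag potential incident DKA cases, adjudicates the
#' abstraction records of flagged persons against the clinical rule, and
#' computes the overall and stratified positive predictive values with
#' Wilson confidence intervals.
#'
#' @param db A [claims_db()].
#' @param abstractions Abstraction tibble keyed by `person_id`; flagged
#'   persons without a record are treated as not abstracted.
#' @param config A [cohort_config()].
#' @param policy Adjudication policy, `"strict"` (default) or
#'   `"dx_fallback"`; see [adjudicate()].
#' @param strata Stratification rules; see [default_strata()].
#' @param conf.level Confidence level for Wilson intervals.
#' @return An object of class `dka_validation`: a list with the `cohort`,
#'   `cases`, and `adjudicated` tibbles, the `overall` and `strata` result
#'   tibbles, and the counts `n_potential`, `n_adjudicated`, `n_confirmed`.
#' @examples
#' study <- dka_reference_study()
#' fit <- validate_case_definition(study$db, study$abstractions)
#' fit
#' glance(fit)
#' @export
validate_case_definition <- function(db, abstractions,
                                     config = cohort_config(),
                                     policy = c("strict", "dx_fallback"),
                                     strata = default_strata(),
                                     conf.level = 0.95) {
  policy <- match.arg(policy)
  cohort <- build_cohort(db, config)
  cases <- find_potential_cases(cohort, db, config)
  recs <- dplyr::semi_join(abstractions, cases, by = "person_id")
  adjudicated <- adjudicate(recs, policy = policy)
  overall <- compute_ppv(adjudicated, conf.level)
  strat <- stratified_ppv(adjudicated, strata, conf.level)
  structure(list(cohort = cohort, cases = cases, adjudicated = adjudicated,
                 overall = overall, strata = strat, policy = policy,
                 conf.level = conf.level,
                 n_potential = nrow(cases),
                 n_adjudicated = overall$n, n_confirmed = overall$x),
            class = "dka_validation")
}

#' @export
print.dka_validation <- function(x, ...) {
  cat("Claims-based DKA case-definition validation (policy:", x$policy,
      ")\n")
  cat(sprintf("  potential cases: %d; adjudicated: %d; confirmed: %d\n",
              x$n_potential, x$n_adjudicated, x$n_confirmed))
  cat(sprintf("  PPV %.1f%% (%d%% CI %.1f to %.1f)\n",
              round_half_up(x$overall$ppv, 1), round(100 * x$conf.level),
              round_half_up(x$overall$conf.low, 1),
              round_half_up(x$overall$conf.high, 1)))
  invisible(x)
}

#' Tidy a validation result
#'
#' `tidy()` returns one row per stratum level (the overall row first);
#' `glance()` returns a one-row summary of the whole validation.
#'
#' @param x A `dka_validation` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @export
tidy.dka_validation <- function(x, ...) {
  dplyr::bind_rows(x$overall, x$strata)
}

#' @rdname tidy.dka_validation
#' @importFrom generics glance
#' @export
glance.dka_validation <- function(x, ...) {
  tibble::tibble(n_potential = x$n_potential,
                 n_adjudicated = x$n_adjudicated,
                 n_confirmed = x$n_confirmed,
                 ppv = x$overall$ppv, conf.low = x$overall$conf.low,
                 conf.high = x$overall$conf.high,
                 conf.level = x$conf.level, policy = x$policy)
}

#' Forest plot of stratified positive predictive values
#'
#' Dot-and-interval plot of the PPV per stratum level with the overall
#' estimate on top, the standard display for a predictive-value validation.
#'
#' @param object A `dka_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.dka_validation <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(label = paste0(.data$stratum, ": ", .data$level,
                                 " (", .data$x, "/", .data$n, ")"))
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppv, y = .data$label)) +
    ggplot2::geom_vline(xintercept = object$overall$ppv,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(0, 100) +
    ggplot2::labs(x = "Positive predictive value (%)", y = NULL,
                  title = "PPV of the DKA computer case definition",
                  subtitle = sprintf("Wilson %d%% confidence intervals",
                                     round(100 * object$conf.level))) +
    ggplot2::theme_minimal()
}

#' @export
plot.dka_validation <- function(x, ...) print(autoplot(x, ...))
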