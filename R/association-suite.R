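#' Default exposure and covariate sets
#'
#' The structural and compositional exposures analysed one at a time, and
#' the adjustment covariates.
#' @return Character vector of column names.
#' @export
default_exposures <- function() {
  c("degree", "es_class", "constraint", "age_sd", "iqv_sex",
    "iqv_education", "de_facto_diverse", "de_jure_diverse", "iqv_kinship")
}

#' @rdname default_exposures
#' @export
default_covariates <- function() {
  c("age_years", "education", "residence", "coresident_husband",
    "head_sex", "wealth_tercile", "earnings", "maternal_respondent")
}

stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

suite_formula <- function(outcome, exposure, covariates = NULL) {
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  as.formula(paste(outcome, "~", rhs))
}

# rows of the tidy output for the exposure's term(s) of one fit
exposure_rows <- function(fit, exposure, round, statistic) {
  td <- tidy(fit, exponentiate = TRUE)
  td <- td[startsWith(td$term, exposure), , drop = FALSE]
  tibble::tibble(round = round, statistic = statistic, term = td$term,
                 or = td$estimate, conf.low = td$conf.low,
                 conf.high = td$conf.high, p.value = td$p.value,
                 n = fit$n)
}

#' Run the full association suite
#'
#' For each outcome and each exposure, fits (i) the crude and adjusted
#' survey-weighted logistic model within each survey round where the
#' outcome was collected, (ii) the pooled random-intercept (survey round)
#' logistic model, weighted and unweighted, and (iii) the average
#' marginal effect of the exposure from the pooled model. Each exposure
#' is analysed in a separate model; covariates are the standard
#' adjustment set.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @param outcomes Outcome columns (default `mdd_met`, `mmf_met`).
#' @param exposures Exposure columns ([default_exposures()]).
#' @param covariates Adjustment covariates ([default_covariates()]).
#' @param weights,cluster Passed to [fit_weighted_logistic()].
#' @param pooled_weights Weight column for the pooled mixed model
#'   (default the sampling weight, as normalised pseudo-likelihood
#'   scaling); `NULL` for unweighted pooling only.
#' @param nAGQ Quadrature nodes for the pooled fits.
#' @param keep_fits Keep the fitted model objects in the result.
#' @return A `kinfeed_suite`: list with `associations` (tidy tibble:
#'   outcome, exposure, term, round -- one of the rounds or `"overall"` /
#'   `"overall_unweighted"` -- statistic `cor`/`aor`, OR, CI, p, stars),
#'   `marginal_effects`, `unavailable` (outcome-round cells masked by
#'   design) and optionally `fits`.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 400, seed = 5))
#' tab <- build_analysis_table(svy)
#' suite <- run_association_suite(tab, outcomes = "mmf_met",
#'                                exposures = c("degree", "constraint"))
#' suite$associations
run_association_suite <- function(table,
                                  outcomes = c("mdd_met", "mmf_met"),
                                  exposures = default_exposures(),
                                  covariates = default_covariates(),
                                  weights = "weight", cluster = "cluster_id",
                                  pooled_weights = weights, nAGQ = 15,
                                  keep_fits = FALSE) {
  rounds <- sort(unique(as.character(table$round)))
  assoc <- list(); ames <- list(); fits <- list(); unavailable <- list()
  for (outcome in outcomes) {
    avail <- vapply(rounds, function(r) {
      y <- table[[outcome]][table$round == r]
      any(!is.na(y)) && dplyr::n_distinct(y[!is.na(y)]) == 2
    }, logical(1))
    unavailable[[outcome]] <- tibble::tibble(outcome = outcome,
                                             round = rounds[!avail])
    for (exposure in exposures) {
      rows <- list()
      for (r in rounds[avail]) {
        dr <- table[table$round == r, , drop = FALSE]
        crude <- fit_weighted_logistic(dr, suite_formula(outcome, exposure),
                                       weights = weights, cluster = cluster)
        adj <- fit_weighted_logistic(dr, suite_formula(outcome, exposure, covariates),
                                     weights = weights, cluster = cluster)
        rows <- c(rows, list(exposure_rows(crude, exposure, r, "cor"),
                             exposure_rows(adj, exposure, r, "aor")))
      }
      if (sum(avail) >= 2) {
        sub <- table[as.character(table$round) %in% rounds[avail], , drop = FALSE]
        f <- suite_formula(outcome, exposure, covariates)
        pooled_uw <- fit_random_intercept_logistic(sub, f, weights = NULL,
                                                   nAGQ = nAGQ)
        rows <- c(rows, list(exposure_rows(pooled_uw, exposure,
                                           "overall_unweighted", "aor")))
        pooled <- if (!is.null(pooled_weights)) {
          fit_random_intercept_logistic(sub, f, weights = pooled_weights,
                                        nAGQ = nAGQ)
        } else {
          pooled_uw
        }
        rows <- c(rows, list(exposure_rows(pooled, exposure, "overall", "aor")))
        ame <- average_marginal_effect(pooled, exposure)
        ames[[paste(outcome, exposure)]] <-
          dplyr::mutate(ame, outcome = outcome, .before = 1)
        if (keep_fits) fits[[paste(outcome, exposure)]] <- pooled
      }
      assoc[[paste(outcome, exposure)]] <-
        dplyr::bind_rows(rows) |>
        dplyr::mutate(outcome = outcome, exposure = exposure, .before = 1)
    }
  }
  res <- list(associations = dplyr::bind_rows(assoc) |>
                dplyr::mutate(stars = stars(.data$p.value)),
              marginal_effects = dplyr::bind_rows(ames),
              unavailable = dplyr::bind_rows(unavailable),
              rounds = rounds)
  if (keep_fits) res$fits <- fits
  structure(res, class = "kinfeed_suite")
}

#' @export
print.kinfeed_suite <- function(x, ...) {
  cat("<kinfeed_suite>", dplyr::n_distinct(x$associations$exposure),
      "exposures x", dplyr::n_distinct(x$associations$outcome),
      "outcomes; rounds:", paste(x$rounds, collapse = ", "), "\n")
  print(format_association_table(x), ...)
  invisible(x)
}

#' Render the association results as a publication-style table
#'
#' One row per exposure term, columns for each round's crude and adjusted
#' odds ratios, the overall (pooled random-intercept) adjusted odds
#' ratio, and the average marginal effect, formatted as
#' `OR (low, high)` with significance stars (* p<0.05, ** p<0.01,
#' *** p<0.001). Cells for outcome-rounds masked by design are `"-"`.
#'
#' @param suite A `kinfeed_suite`.
#' @param digits Decimal places for odds ratios.
#' @return A tibble per outcome, bound with an `outcome` column.
#' @export
format_association_table <- function(suite, digits = 2) {
  fmt <- function(or, lo, hi, st) {
    sprintf("%.*f%s (%.*f, %.*f)", digits, or, st, digits, lo, digits, hi)
  }
  long <- suite$associations |>
    dplyr::filter(.data$round != "overall_unweighted") |>
    dplyr::mutate(cell = fmt(.data$or, .data$conf.low, .data$conf.high, .data$stars),
                  col = ifelse(.data$round == "overall", "overall_aor",
                               paste0(.data$round, "_", .data$statistic))) |>
    dplyr::select("outcome", "exposure", "term", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell",
                       values_fill = "-")
  me <- suite$marginal_effects |>
    dplyr::mutate(term = ifelse(is.na(.data$level), .data$variable,
                                paste0(.data$variable, .data$level)),
                  me = sprintf("%.2f (%.2f, %.2f)", .data$estimate,
                               .data$conf.low, .data$conf.high)) |>
    dplyr::select(outcome = "outcome", exposure = "variable", term = "term",
                  marginal_effect_pct = "me")
  dplyr::left_join(long, me, by = c("outcome", "exposure", "term"))
}
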