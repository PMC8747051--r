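#' Respondent (ego) covariates per household
#'
#' Extracts the woman-level and household-level covariates used for
#' adjustment: her age and education, urban/rural residence, earnings
#' type, wealth tercile, sex of the household head, coresidence with the
#' husband, and whether the respondent is the child's mother.
#'
#' @param rosters Roster tibble ([roster-dialect]).
#' @return Tibble with one row per household and the covariate columns,
#'   categorical covariates as factors with the conventional reference
#'   levels (no education, rural, not working, poor, male head).
#' @export
ego_covariates <- function(rosters) {
  heads <- rosters |>
    dplyr::filter(.data$relationship_to_head == "head") |>
    dplyr::distinct(.data$household_id, head_sex = .data$sex)
  rosters |>
    dplyr::filter(.data$is_respondent) |>
    dplyr::left_join(heads, by = "household_id") |>
    dplyr::transmute(
      household_id = .data$household_id,
      age_years = .data$age_years,
      education = factor(.data$education, levels = c("none", "primary_or_above")),
      residence = factor(.data$residence, levels = c("rural", "urban")),
      earnings = factor(.data$earnings, levels = c("not_working", "unpaid", "paid")),
      wealth_tercile = factor(.data$wealth_tercile, levels = c("poor", "middle", "rich")),
      head_sex = factor(dplyr::coalesce(.data$head_sex, .data$sex),
                        levels = c("male", "female")),
      coresident_husband = .data$coresident_husband,
      maternal_respondent = .data$maternal_respondent)
}

#' Assemble the per-child analysis table
#'
#' Joins the eligible cohort with the structural and compositional
#' network metrics, the ego covariates and the coded IYCF outcomes
#' (round availability applied), and adds the median-split diversity
#' flags. This is the table the association models consume.
#'
#' @param survey A list with elements `rosters` and `children` (e.g. from
#'   [simulate_survey()]), or pass the two tibbles separately.
#' @param children Child-record tibble (if `survey` is a roster tibble).
#' @param min_age_months,max_age_months Eligibility window
#'   ([select_eligible()]).
#' @param kinship_K,es_cutoff,marriage_ties,alters Metric options.
#' @param mask Outcome availability ([apply_round_availability()]).
#' @param flags_by Median-split grouping ([diversity_flags()]).
#' @return Tibble, one row per eligible child, carrying identifiers and
#'   design columns, all metrics, covariates and outcomes; the
#'   eligibility flow is preserved in attribute `exclusion_flow`.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 100, seed = 1))
#' tab <- build_analysis_table(svy)
#' dplyr::glimpse(tab)
build_analysis_table <- function(survey, children = NULL,
                                 min_age_months = 6, max_age_months = 23,
                                 kinship_K = 12, es_cutoff = 3,
                                 marriage_ties = FALSE,
                                 alters = c("de_jure", "de_facto"),
                                 mask = list(mdd_met = "2000", mmf_met = "2005"),
                                 flags_by = c("round", "pooled")) {
  alters <- match.arg(alters)
  flags_by <- match.arg(flags_by)
  if (is.null(children)) {
    rosters <- survey$rosters
    children <- survey$children
  } else {
    rosters <- survey
  }
  cohort <- select_eligible(rosters, children, min_age_months, max_age_months)
  flow <- attr(cohort, "exclusion_flow")
  hh_ids <- unique(cohort$household_id)
  rosters_used <- rosters[rosters$household_id %in% hh_ids, , drop = FALSE]
  out <- cohort |>
    dplyr::left_join(structural_metrics(rosters_used, alters = alters,
                                        marriage_ties = marriage_ties,
                                        es_cutoff = es_cutoff),
                     by = "household_id") |>
    dplyr::left_join(composition_metrics(rosters_used, kinship_K = kinship_K),
                     by = "household_id") |>
    dplyr::left_join(ego_covariates(rosters_used), by = "household_id",
                     suffix = c("_child", "")) |>
    code_outcomes(mask = mask) |>
    diversity_flags(by = flags_by)
  attr(out, "exclusion_flow") <- flow
  out
}
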