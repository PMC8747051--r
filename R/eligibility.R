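#' Select the analysis cohort of eligible children
#'
#' Applies the eligibility cascade: children must match a surveyed
#' household with a completed woman respondent, be the last-born child,
#' and be aged between `min_age_months` and `max_age_months` completed
#' months (default 6--23, the complementary-feeding window whose upper
#' band the meal-frequency indicator uses). Exclusions are counted per
#' filter, in cascade order, so that
#' `retained + sum(exclusions) == nrow(children)`.
#'
#' @param rosters Roster tibble ([roster-dialect]).
#' @param children Child-record tibble.
#' @param min_age_months,max_age_months Inclusive age window in completed
#'   months (defaults 6 and 23).
#' @return A tibble of eligible children joined with their household's
#'   `round`, `cluster_id` and `weight`, with attribute `exclusion_flow`
#'   (also via [eligibility_flow()]).
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 50, seed = 1))
#' cohort <- select_eligible(svy$rosters, svy$children)
#' eligibility_flow(cohort)
select_eligible <- function(rosters, children,
                            min_age_months = 6, max_age_months = 23) {
  hh <- dplyr::distinct(rosters, .data$household_id, .data$cluster_id,
                        .data$round, .data$weight, .data$residence,
                        .data$wealth_tercile)
  unmatched <- setdiff(children$household_id, hh$household_id)
  if (length(unmatched)) {
    stop("child record(s) without matching household: ",
         paste(utils::head(unmatched, 10), collapse = ", "))
  }
  n_in <- nrow(children)
  keep <- rep(TRUE, n_in)
  flow <- list()
  step <- function(name, drop) {
    flow[[name]] <<- sum(keep & drop)
    keep <<- keep & !drop
  }
  # respondent completion is a roster invariant here, but kept as an
  # explicit (zero-count) stage so the flow mirrors real survey accounting
  resp_hh <- unique(rosters$household_id[rosters$is_respondent])
  step("no_completed_respondent", !children$household_id %in% resp_hh)
  step("not_last_born", !children$is_last_born)
  step("age_below_window", children$age_months < min_age_months)
  step("age_above_window", children$age_months > max_age_months)
  out <- dplyr::inner_join(children[keep, , drop = FALSE], hh,
                           by = "household_id")
  flow_tbl <- tibble::tibble(
    stage = c("input", names(flow), "retained"),
    n = c(n_in, unlist(flow, use.names = FALSE), sum(keep)))
  attr(out, "exclusion_flow") <- flow_tbl
  out
}

#' Exclusion-flow accounting for a selected cohort
#'
#' @param cohort Result of [select_eligible()].
#' @return Tibble with columns `stage` and `n`: the input count, one row
#'   per exclusion filter, and the retained count.
#' @export
eligibility_flow <- function(cohort) {
  flow <- attr(cohort, "exclusion_flow")
  if (is.null(flow)) stop("no exclusion flow attached; was this cohort built by select_eligible()?")
  flow
}
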