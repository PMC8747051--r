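#' Weighted descriptive summary of the analysis cohort
#'
#' Participant-characteristics table: per survey round, weighted mean and
#' standard error for approximately normal continuous variables
#' (respondent age), weighted median with quartiles for skewed ones (the
#' network metrics), and weighted percentages for categorical variables.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @return Tidy tibble with `round`, `variable`, `category`, `statistic`
#'   (`mean_se`, `median_q1_q3` or `n_pct`), `value1`, `value2`, `value3`
#'   (mean/SE, median/Q1/Q3, or n/%).
#' @export
describe_cohort <- function(table) {
  wq <- function(x, w, p) {
    o <- order(x); x <- x[o]; w <- w[o]
    x[which(cumsum(w) >= p * sum(w))[1]]
  }
  one_round <- function(d) {
    w <- d$weight
    cont_norm <- "age_years"
    cont_skew <- c("degree", "effective_size", "constraint", "age_sd",
                   "iqv_sex", "iqv_education", "iqv_kinship")
    cats <- c("education", "residence", "head_sex", "earnings",
              "wealth_tercile", "es_class", "de_jure_diverse",
              "de_facto_diverse", "mdd_met", "mmf_met")
    out <- list()
    for (v in intersect(cont_norm, names(d))) {
      mu <- weighted.mean(d[[v]], w, na.rm = TRUE)
      se <- sqrt(weighted.mean((d[[v]] - mu)^2, w, na.rm = TRUE) / sum(!is.na(d[[v]])))
      out[[v]] <- tibble::tibble(variable = v, category = NA_character_,
                                 statistic = "mean_se",
                                 value1 = mu, value2 = se, value3 = NA_real_)
    }
    for (v in intersect(cont_skew, names(d))) {
      out[[v]] <- tibble::tibble(variable = v, category = NA_character_,
                                 statistic = "median_q1_q3",
                                 value1 = wq(d[[v]], w, 0.5),
                                 value2 = wq(d[[v]], w, 0.25),
                                 value3 = wq(d[[v]], w, 0.75))
    }
    for (v in intersect(cats, names(d))) {
      x <- d[[v]]
      if (all(is.na(x))) {
        out[[v]] <- tibble::tibble(variable = v, category = "unavailable",
                                   statistic = "n_pct", value1 = NA_real_,
                                   value2 = NA_real_, value3 = NA_real_)
        next
      }
      lev <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
      out[[v]] <- dplyr::bind_rows(lapply(lev, function(l) {
        sel <- !is.na(x) & x == l
        tibble::tibble(variable = v, category = as.character(l),
                       statistic = "n_pct", value1 = sum(sel),
                       value2 = 100 * sum(w[sel]) / sum(w[!is.na(x)]),
                       value3 = NA_real_)
      }))
    }
    dplyr::bind_rows(out)
  }
  table |>
    dplyr::group_by(round = as.character(.data$round)) |>
    dplyr::group_modify(~ one_round(.x)) |>
    dplyr::ungroup()
}

#' Run the full pipeline and write its report bundle
#'
#' Orchestrates generate (or ingest) -> eligibility -> metrics ->
#' outcomes -> models -> report. Writes five artifacts to `out_dir`:
#' `cohort_description.csv` (participant characteristics),
#' `associations.csv` and `association_table.csv` (tidy and formatted
#' model results), `marginal_effects.csv`, `exclusion_flow.csv`, plus a
#' machine-readable `manifest.json` recording the configuration, seed,
#' row counts and output checksums. Identical configuration and seed
#' give identical tables.
#'
#' @param config A [generator_config()] to simulate from, or a list with
#'   `roster_path` and `children_path` pointing at tables on disk.
#' @param out_dir Output directory (created if needed).
#' @param outcomes,exposures,covariates Passed to
#'   [run_association_suite()].
#' @param ... Further options for [build_analysis_table()].
#' @return Invisibly, a list with the analysis `table`, `suite`,
#'   `description`, `flow`, and the `manifest`.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(generator_config(n_households = 300, seed = 9),
#'                     out_dir = tempfile(),
#'                     outcomes = "mmf_met", exposures = "constraint")
#' out$manifest$n_eligible
#' }
run_pipeline <- function(config, out_dir,
                         outcomes = c("mdd_met", "mmf_met"),
                         exposures = default_exposures(),
                         covariates = default_covariates(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(config, "generator_config")) {
    svy <- simulate_survey(config)
    rosters <- svy$rosters; children <- svy$children
    cfg_json <- unclass(config)
  } else {
    rosters <- read_rosters(config$roster_path)
    children <- read_children(config$children_path)
    cfg_json <- config
  }
  table <- build_analysis_table(rosters, children, ...)
  flow <- eligibility_flow(table)
  desc <- describe_cohort(table)
  suite <- run_association_suite(table, outcomes = outcomes,
                                 exposures = exposures,
                                 covariates = covariates)
  paths <- c(cohort_description = "cohort_description.csv",
             associations = "associations.csv",
             association_table = "association_table.csv",
             marginal_effects = "marginal_effects.csv",
             exclusion_flow = "exclusion_flow.csv")
  readr::write_csv(desc, file.path(out_dir, paths["cohort_description"]))
  readr::write_csv(suite$associations, file.path(out_dir, paths["associations"]))
  readr::write_csv(format_association_table(suite),
                   file.path(out_dir, paths["association_table"]))
  readr::write_csv(suite$marginal_effects,
                   file.path(out_dir, paths["marginal_effects"]))
  readr::write_csv(flow, file.path(out_dir, paths["exclusion_flow"]))
  manifest <- list(
    package_version = as.character(utils::packageVersion("kinfeed")),
    config = cfg_json,
    n_households = dplyr::n_distinct(rosters$household_id),
    n_children = nrow(children),
    n_eligible = nrow(table),
    outcomes = outcomes, exposures = exposures, covariates = covariates,
    artifacts = as.list(paths),
    checksums = lapply(as.list(paths), function(p) {
      unname(tools::md5sum(file.path(out_dir, p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(table = table, suite = suite, description = desc,
                 flow = flow, manifest = manifest))
}
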