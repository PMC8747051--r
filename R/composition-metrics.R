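#' Index of qualitative variation
#'
#' The IQV is the probability that a randomly selected pair of
#' observations falls in different categories, normalised so that its
#' maximum possible value (an even split over the `K` codebook categories)
#' is 1: `IQV = K/(K-1) * (1 - sum(p_k^2))`. `K` is the number of
#' *possible* categories from the codebook, not the number observed --
#' this makes diversity comparable across attributes with different
#' category counts and keeps single-category households defined (IQV 0).
#' Values are clamped to \[0, 1\] (when more than `K` categories are
#' observed the unclamped value can marginally exceed 1).
#'
#' @param x Vector of category labels (the multiset); `NA` dropped.
#' @param K Number of possible categories, `>= 2`.
#' @return IQV in \[0, 1\]; `NA` if `x` has no non-missing values.
#' @export
#' @examples
#' iqv(c("f", "f", "f", "f"), K = 2)      # no diversity: 0
#' iqv(c("m", "m", "f", "f"), K = 2)      # even split: 1
#' iqv(c("a", "a", "b", "c"), K = 3)      # 0.9375
iqv <- function(x, K) {
  if (K < 2) stop("K must be at least 2")
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  p <- as.numeric(table(x)) / length(x)
  val <- K / (K - 1) * (1 - sum(p^2))
  min(max(val, 0), 1)
}

#' Age diversity of alters
#'
#' Sample standard deviation (denominator n-1) of the alters' ages in
#' years; a single alter gives 0 by convention.
#'
#' @param ages Numeric ages in years; `NA` dropped.
#' @return SD in years; `NA` if no ages are known.
#' @export
age_diversity <- function(ages) {
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) return(NA_real_)
  if (length(ages) == 1) return(0)
  sd(ages)
}

#' Compositional metrics for every household
#'
#' Computes the alter-attribute diversity variables per household: IQV of
#' sex (K = 2), of educational status (K = 2) and of kinship category
#' (K = `kinship_K`), the age SD, and the residence-turnover IQVs --
#' de jure diversity (usual resident vs visitor, over all listed members)
#' and de facto diversity (slept here vs away, over usual residents). The
#' respondent's own attributes are excluded: these describe her network,
#' not her.
#'
#' @param rosters Roster tibble ([roster-dialect]).
#' @param kinship_K Codebook category count for the kinship IQV
#'   (default 12, the distinct alter relationship categories).
#' @return Tibble: `household_id`, `iqv_sex`, `iqv_education`,
#'   `iqv_kinship`, `age_sd`, `iqv_de_jure`, `iqv_de_facto`.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 20, seed = 1))
#' composition_metrics(svy$rosters)
composition_metrics <- function(rosters, kinship_K = 12) {
  rosters |>
    dplyr::filter(!.data$is_respondent) |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(
      iqv_sex = iqv(.data$sex, 2),
      iqv_education = iqv(.data$education, 2),
      iqv_kinship = iqv(.data$relationship_to_head, kinship_K),
      age_sd = age_diversity(.data$age_years),
      iqv_de_jure = iqv(ifelse(.data$de_jure, "usual", "visitor"), 2),
      iqv_de_facto = iqv(ifelse(.data$de_jure,
                                ifelse(.data$de_facto, "slept", "away"),
                                NA_character_), 2),
      .groups = "drop")
}

#' Weighted median
#'
#' Lower weighted median: the smallest value at which the cumulative
#' weight reaches half the total.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (default equal).
#' @return The weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  ok <- !is.na(x) & !is.na(w)
  x <- x[ok]; w <- w[ok]
  o <- order(x)
  x <- x[o]; w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1]]
}

#' Median-split diversity flags for the residence IQVs
#'
#' Dichotomises `iqv_de_jure` and `iqv_de_facto` into diversity
#' present/absent by a weighted median split computed on the analysis
#' cohort, by default within each survey round.
#'
#' @param metrics Tibble holding `household_id`, `iqv_de_jure`,
#'   `iqv_de_facto` plus `round` and `weight` (e.g. the joined analysis
#'   table).
#' @param by Grouping for the split: `"round"` (default) or `"pooled"`.
#' @return `metrics` with factor columns `de_jure_diverse` and
#'   `de_facto_diverse` (levels `absent`, `present`; flag present iff the
#'   IQV exceeds the group's weighted median).
#' @export
diversity_flags <- function(metrics, by = c("round", "pooled")) {
  by <- match.arg(by)
  grp <- if (by == "round") dplyr::group_by(metrics, .data$round) else metrics
  out <- dplyr::mutate(grp,
    de_jure_diverse = factor(
      ifelse(.data$iqv_de_jure > weighted_median(.data$iqv_de_jure, .data$weight),
             "present", "absent"), levels = c("absent", "present")),
    de_facto_diverse = factor(
      ifelse(.data$iqv_de_facto > weighted_median(.data$iqv_de_facto, .data$weight),
             "present", "absent"), levels = c("absent", "present")))
  dplyr::ungroup(out)
}
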