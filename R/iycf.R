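#' Code Minimum Dietary Diversity (MDD)
#'
#' Sums the eight previous-day food-group flags into a dietary-diversity
#' score (0--8) and dichotomises it: the MDD recommendation is met when 5
#' or more of the 8 groups were consumed (updated WHO criterion; breast
#' milk counts as a group). With `n_groups = 7` the pre-2017 7-group
#' variant (no breast-milk group, threshold 4) is coded instead.
#'
#' Records with any missing flag get a missing score and indicator; they
#' are excluded downstream and counted.
#'
#' @param children Child-record tibble ([roster-dialect]).
#' @param n_groups 8 (default) or 7.
#' @return `children` with columns `dd_score` (integer) and `mdd_met`
#'   (logical).
#' @export
#' @examples
#' rec <- tibble::tibble(child_id = "c", fg_breastmilk = 1, fg_grains = 1,
#'   fg_legumes = 1, fg_dairy = 1, fg_eggs = 1, fg_flesh = 0,
#'   fg_vitamin_a = 0, fg_other_fruit_veg = 0)
#' code_mdd(rec)  # 5 groups: met
code_mdd <- function(children, n_groups = 8) {
  stopifnot(n_groups %in% c(7, 8))
  cols <- food_group_cols()
  if (n_groups == 7) cols <- setdiff(cols, "fg_breastmilk")
  check_columns(children, cols, "child")
  fg <- as.matrix(children[cols])
  score <- as.integer(rowSums(fg))        # NA if any flag missing
  threshold <- if (n_groups == 8) 5L else 4L
  dplyr::mutate(children, dd_score = score, mdd_met = score >= threshold)
}

#' Code Minimum Meal Frequency (MMF)
#'
#' Applies the age- and breastfeeding-specific minimum daily feeding
#' frequencies for children 6--23 months: breastfed children must have
#' been fed solid/semi-solid/soft foods at least twice (6--8 months) or
#' three times (9--23 months); non-breastfed children at least four times
#' counting milk feeds, of which at least one solid/semi-solid/soft feed.
#'
#' @param children Child-record tibble with `age_months`, `breastfed`,
#'   `feed_count`, `solid_feed_count`.
#' @return `children` with logical column `mmf_met`.
#' @export
#' @examples
#' kids <- tibble::tibble(age_months = c(7, 12, 10),
#'   breastfed = c(TRUE, TRUE, FALSE),
#'   feed_count = c(2, 2, 4), solid_feed_count = c(2, 2, 0))
#' code_mmf(kids)$mmf_met  # TRUE, FALSE, FALSE
code_mmf <- function(children) {
  if (any(children$age_months < 6 | children$age_months > 23, na.rm = TRUE)) {
    stop("MMF is defined for ages 6-23 completed months only")
  }
  dplyr::mutate(children, mmf_met = dplyr::case_when(
    is.na(.data$breastfed) | is.na(.data$feed_count) ~ NA,
    .data$breastfed & .data$age_months <= 8 ~ .data$feed_count >= 2,
    .data$breastfed ~ .data$feed_count >= 3,
    TRUE ~ .data$feed_count >= 4 & .data$solid_feed_count >= 1))
}

#' Mask outcomes not collected in a survey round
#'
#' The questionnaire items needed for MDD were not fielded in the 2000
#' round, and those for MMF not in 2005; the corresponding indicators are
#' set missing for those rounds. The masking map is configurable.
#'
#' @param outcomes Tibble with `round`, `mdd_met`, `mmf_met` (and
#'   optionally `dd_score`).
#' @param mask Named list mapping outcome column to the rounds in which it
#'   is unavailable.
#' @param rounds Valid round labels; an unknown `round` value is a
#'   configuration error.
#' @return `outcomes` with masked entries set to `NA`.
#' @export
#' @examples
#' x <- tibble::tibble(round = c("2000", "2005", "2016"),
#'                     mdd_met = TRUE, mmf_met = TRUE)
#' apply_round_availability(x)
apply_round_availability <- function(outcomes,
                                     mask = list(mdd_met = "2000",
                                                 mmf_met = "2005"),
                                     rounds = c("2000", "2005", "2011", "2016")) {
  unknown <- setdiff(unique(as.character(outcomes$round)), rounds)
  if (length(unknown)) {
    stop("unknown survey round(s): ", paste(unknown, collapse = ", "))
  }
  for (col in names(mask)) {
    if (!col %in% names(outcomes)) next
    hit <- as.character(outcomes$round) %in% mask[[col]]
    outcomes[[col]][hit] <- NA
    if (col == "mdd_met" && "dd_score" %in% names(outcomes)) {
      outcomes$dd_score[hit] <- NA_integer_
    }
  }
  outcomes
}

#' Code both IYCF outcomes and apply round availability
#'
#' Convenience wrapper: [code_mdd()] then [code_mmf()] then
#' [apply_round_availability()] (the latter only if a `round` column is
#' present).
#'
#' @inheritParams code_mdd
#' @inheritParams apply_round_availability
#' @return `children` with `dd_score`, `mdd_met`, `mmf_met`.
#' @export
code_outcomes <- function(children, n_groups = 8,
                          mask = list(mdd_met = "2000", mmf_met = "2005")) {
  out <- code_mmf(code_mdd(children, n_groups))
  if ("round" %in% names(out)) out <- apply_round_availability(out, mask)
  out
}
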