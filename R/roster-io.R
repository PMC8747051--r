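#' @name roster-dialect
#' @title The roster and child-record table dialect
#'
#' @description
#' Tables move through the package as tibbles in a documented
#' DHS-recode-like dialect, one row per household member (roster) or per
#' child feeding recall (children). On disk they are CSV or Parquet,
#' selected by file extension.
#'
#' **Roster columns** (one row per member):
#' \describe{
#'   \item{household_id, cluster_id, round, weight}{survey identifiers;
#'     `weight` is the positive household sampling weight.}
#'   \item{residence, wealth_tercile}{household-level covariates
#'     (`urban`/`rural`; `poor`/`middle`/`rich`), repeated on every row.}
#'   \item{member_id}{identifier unique within household.}
#'   \item{relationship_to_head}{one of [relationship_codes()].}
#'   \item{sex, age_years, education}{`male`/`female`; non-negative years;
#'     `none`/`primary_or_above`.}
#'   \item{de_jure, de_facto}{logical: usual resident / slept in the
#'     household last night. At least one must be TRUE.}
#'   \item{is_respondent}{logical; exactly one TRUE per household (the
#'     interviewed woman, the ego).}
#'   \item{earnings, coresident_husband, maternal_respondent}{respondent-only
#'     fields (`not_working`/`unpaid`/`paid`; logical; logical), NA on other
#'     rows.}
#' }
#'
#' **Child columns** (one row per child): `child_id`, `household_id`,
#' `age_months` (0--59), `is_last_born`, `breastfed`, the eight food-group
#' flags `fg_breastmilk`, `fg_grains`, `fg_legumes`, `fg_dairy`, `fg_eggs`,
#' `fg_flesh`, `fg_vitamin_a`, `fg_other_fruit_veg`, and `feed_count`,
#' `solid_feed_count` (previous-day feeds; solid/semi-solid/soft feeds,
#' `solid_feed_count <= feed_count`).
NULL

roster_required_cols <- function() {
  c("household_id", "cluster_id", "round", "weight", "residence",
    "wealth_tercile", "member_id", "relationship_to_head", "sex",
    "age_years", "education", "de_jure", "de_facto", "is_respondent",
    "earnings", "coresident_husband", "maternal_respondent")
}

child_required_cols <- function() {
  c("child_id", "household_id", "age_months", "is_last_born", "breastfed",
    food_group_cols(), "feed_count", "solid_feed_count")
}

#' Names of the eight food-group flag columns
#' @return Character vector of length 8.
#' @export
food_group_cols <- function() {
  c("fg_breastmilk", "fg_grains", "fg_legumes", "fg_dairy", "fg_eggs",
    "fg_flesh", "fg_vitamin_a", "fg_other_fruit_veg")
}

read_table_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet requires the 'arrow' package")
    }
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    # read as character and convert via strtod so that doubles written in
    # shortest round-trip notation re-parse bit-exactly
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
    x[] <- lapply(x, function(col) utils::type.convert(col, as.is = TRUE))
    x
  }
}

write_table_any <- function(x, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("writing Parquet requires the 'arrow' package")
    }
    arrow::write_parquet(x, path)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

check_columns <- function(x, required, what) {
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("missing mandatory ", what, " column(s): ", paste(miss, collapse = ", "))
  }
}

#' Read household rosters
#'
#' Reads a member-level roster table (CSV or Parquet) in the dialect of
#' [roster-dialect], validates it, and returns it as a tibble. Relationship
#' codes outside the closed enumeration are retained as `"unspecified"`;
#' the number of such rows is attached as attribute `n_recoded` and
#' reported in a warning.
#'
#' @param path File path (`.csv` or `.parquet`).
#' @return A tibble of members, validated per [validate_rosters()].
#' @seealso [write_rosters()], [read_children()]
#' @export
read_rosters <- function(path) {
  x <- read_table_any(path)
  check_columns(x, roster_required_cols(), "roster")
  x <- dplyr::mutate(x,
    dplyr::across(c("de_jure", "de_facto", "is_respondent"), as.logical),
    dplyr::across(c("household_id", "cluster_id", "member_id",
                    "relationship_to_head", "sex", "education", "residence",
                    "wealth_tercile"), as.character),
    round = as.character(.data$round))
  bad <- !x$relationship_to_head %in% relationship_codes()
  if (any(bad)) {
    warning(sum(bad), " relationship code(s) outside the enumeration; coded 'unspecified'")
    x$relationship_to_head[bad] <- "unspecified"
  }
  x <- validate_rosters(x)
  attr(x, "n_recoded") <- sum(bad)
  x
}

#' Validate a roster tibble
#'
#' Enforces the roster invariants: no duplicate (household_id, member_id),
#' positive weights, at least one of de_jure/de_facto per member, households
#' of at least two members, exactly one respondent per household.
#'
#' @param rosters Member-level tibble per [roster-dialect].
#' @return The input, invisibly validated (returned unchanged).
#' @export
validate_rosters <- function(rosters) {
  dup <- duplicated(rosters[c("household_id", "member_id")])
  if (any(dup)) {
    stop("duplicate (household_id, member_id): ",
         paste(utils::head(paste(rosters$household_id[dup],
                                 rosters$member_id[dup], sep = "/"), 5),
               collapse = ", "))
  }
  if (any(rosters$weight <= 0)) stop("sampling weights must be positive")
  if (any(!(rosters$de_jure | rosters$de_facto))) {
    stop("every member must be de jure and/or de facto")
  }
  hh <- dplyr::summarise(dplyr::group_by(rosters, .data$household_id),
                         n = dplyr::n(),
                         n_resp = sum(.data$is_respondent), .groups = "drop")
  if (any(hh$n < 2)) {
    stop("household(s) with fewer than 2 members: ",
         paste(utils::head(hh$household_id[hh$n < 2], 5), collapse = ", "))
  }
  if (any(hh$n_resp != 1)) {
    stop("household(s) without exactly one respondent: ",
         paste(utils::head(hh$household_id[hh$n_resp != 1], 5), collapse = ", "))
  }
  rosters
}

#' Write household rosters
#' @param rosters Roster tibble.
#' @param path Output path (`.csv` or `.parquet`).
#' @return The path, invisibly.
#' @export
write_rosters <- function(rosters, path) {
  check_columns(rosters, roster_required_cols(), "roster")
  write_table_any(rosters, path)
}

#' Read child feeding-recall records
#'
#' @param path File path (`.csv` or `.parquet`).
#' @return A tibble of child records; food-group flags coerced to integer
#'   0/1, with `solid_feed_count <= feed_count` enforced.
#' @export
read_children <- function(path) {
  x <- read_table_any(path)
  check_columns(x, child_required_cols(), "child")
  x <- dplyr::mutate(x,
    dplyr::across(c("child_id", "household_id"), as.character),
    dplyr::across(c("is_last_born", "breastfed"), as.logical),
    dplyr::across(c("age_months", "feed_count", "solid_feed_count"), as.integer),
    dplyr::across(dplyr::all_of(food_group_cols()), as.integer))
  fg <- as.matrix(x[food_group_cols()])
  if (any(!is.na(fg) & !(fg %in% c(0L, 1L)))) stop("food-group flags must be 0/1")
  if (any(x$age_months < 0 | x$age_months > 59, na.rm = TRUE)) {
    stop("age_months must lie in [0, 59]")
  }
  if (any(x$solid_feed_count > x$feed_count, na.rm = TRUE)) {
    stop("solid_feed_count may not exceed feed_count")
  }
  x
}

#' Write child feeding-recall records
#' @param children Child-record tibble.
#' @param path Output path (`.csv` or `.parquet`).
#' @return The path, invisibly.
#' @export
write_children <- function(children, path) {
  check_columns(children, child_required_cols(), "child")
  write_table_any(children, path)
}
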