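#' Relationship-to-head codes
#'
#' The closed enumeration of household relationship-to-head codes used
#' throughout the package, following the DHS household-recode convention.
#' Any code outside this set is mapped to `"unspecified"` on read.
#'
#' @return Character vector of the 13 recognised codes.
#' @export
#' @examples
#' relationship_codes()
relationship_codes <- function() {
  c("head", "spouse", "child", "child_in_law", "grandchild", "parent",
    "parent_in_law", "sibling", "adopted", "other_relative", "niece_nephew",
    "non_relative", "unspecified")
}

.kinfeed_env <- new.env(parent = emptyenv())

#' Pairwise coefficient-of-relatedness rule table
#'
#' Returns the symmetric lookup table mapping every unordered pair of
#' relationship-to-head codes to a coefficient of relatedness
#' r in \{0.5, 0.25, 0.125, 0\}: 0.5 for parent--child and full siblings,
#' 0.25 for grandparent--grandchild, 0.125 for nephew/niece-type links and
#' zero for pairs not related by blood. Because the DHS roster records each
#' member's relation to the *head* only, some pairs (e.g. a child of the
#' head with a grandchild of the head) are under-determined; those resolve
#' through published defaults in the shipped rule table
#' (`inst/extdata/relatedness_v1.csv`), which can be overridden by passing
#' a file of the same layout.
#'
#' Pairs involving `non_relative`, `adopted` (adopted/foster/step) or
#' `unspecified` score 0: ties are blood-only by default. Spouse pairs that
#' the codes identify (head--spouse, child--child_in_law) can optionally be
#' given full tie weight via `marriage_ties` in [build_ego_network()].
#'
#' @param path Optional path to an alternative rule-table CSV with columns
#'   `code_a`, `code_b`, `r`.
#' @return A tibble with columns `code_a`, `code_b`, `r` covering all 91
#'   unordered pairs of the 13 codes.
#' @export
#' @examples
#' relatedness_table()
relatedness_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.kinfeed_env$relatedness)) return(.kinfeed_env$relatedness)
    path <- system.file("extdata", "relatedness_v1.csv", package = "kinfeed")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           code_a = readr::col_character(),
                           code_b = readr::col_character(),
                           r = readr::col_double()))
  codes <- relationship_codes()
  stopifnot(all(tab$code_a %in% codes), all(tab$code_b %in% codes),
            all(tab$r %in% c(0.5, 0.25, 0.125, 0)))
  if (nrow(tab) != choose(length(codes), 2) + length(codes)) {
    stop("relatedness table must enumerate all unordered code pairs")
  }
  .kinfeed_env$relatedness <- tab
  tab
}

# dense 13x13 matrix form of the rule table, cached
relatedness_matrix <- function(table = NULL) {
  if (is.null(table) && !is.null(.kinfeed_env$relatedness_mat)) {
    return(.kinfeed_env$relatedness_mat)
  }
  tab <- if (is.null(table)) relatedness_table() else table
  codes <- relationship_codes()
  m <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
  m[cbind(tab$code_a, tab$code_b)] <- tab$r
  m[cbind(tab$code_b, tab$code_a)] <- tab$r
  if (is.null(table)) .kinfeed_env$relatedness_mat <- m
  m
}

#' Coefficient of relatedness between two household members
#'
#' Looks up the pairwise coefficient of relatedness for two members from
#' their relationship-to-head codes. Vectorised over both arguments;
#' unknown codes resolve to 0 and are tallied in the `"unresolved"`
#' attribute.
#'
#' @param code_a,code_b Relationship-to-head codes (character).
#' @param table Optional rule table as returned by [relatedness_table()].
#' @return Numeric vector of coefficients in \{0.5, 0.25, 0.125, 0\}, with
#'   attribute `unresolved` counting pairs that fell outside the enumeration.
#' @export
#' @examples
#' pairwise_relatedness("head", "child")       # parent-child: 0.5
#' pairwise_relatedness("head", "grandchild")  # grandparent: 0.25
#' pairwise_relatedness("spouse", "non_relative")
pairwise_relatedness <- function(code_a, code_b, table = NULL) {
  m <- relatedness_matrix(table)
  codes <- rownames(m)
  bad <- !(code_a %in% codes) | !(code_b %in% codes)
  a <- ifelse(code_a %in% codes, code_a, "unspecified")
  b <- ifelse(code_b %in% codes, code_b, "unspecified")
  r <- m[cbind(a, b)]
  r[bad] <- 0
  attr(r, "unresolved") <- sum(bad)
  r
}
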