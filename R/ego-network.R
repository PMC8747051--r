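#' Build the ego network of a household's woman respondent
#'
#' The interviewed woman (ego) is tied to every other household member
#' (alter) with weight 1. Alter--alter ties carry the pairwise coefficient
#' of relatedness inferred from the two members' relationship-to-head
#' codes, normalised by 0.5 so the strongest kin tie (parent--child,
#' sibling) has weight 1; grandparent-type links weigh 0.5 and
#' nephew/niece-type links 0.25. The alter--alter half matrix is computed
#' once over unordered pairs and mirrored, giving a symmetric, undirected,
#' zero-diagonal tie matrix.
#'
#' @param roster Member-level tibble for a *single* household (one row per
#'   member, exactly one `is_respondent`).
#' @param alters Which members count as alters: `"de_jure"` (usual
#'   residents, default) or `"de_facto"` (those who slept in the household).
#'   The ego is always excluded.
#' @param marriage_ties If `TRUE`, the spouse pairs identifiable from the
#'   codes (head--spouse, child--child_in_law) are additionally tied at
#'   weight 1; default `FALSE` (blood ties only).
#' @param table Optional relatedness rule table ([relatedness_table()]).
#' @return An object of class `ego_network`: a list with `ego` (tibble
#'   row), `alters` (tibble), and `Z`, the (1+n) x (1+n) symmetric tie
#'   matrix with the ego first.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 5, seed = 1))
#' hh <- dplyr::filter(svy$rosters, household_id == household_id[1])
#' build_ego_network(hh)
build_ego_network <- function(roster, alters = c("de_jure", "de_facto"),
                              marriage_ties = FALSE, table = NULL) {
  alters <- match.arg(alters)
  if (length(unique(roster$household_id)) != 1) {
    stop("build_ego_network() expects a single household")
  }
  ego <- roster[roster$is_respondent, , drop = FALSE]
  if (nrow(ego) != 1) stop("roster must contain exactly one respondent")
  others <- roster[!roster$is_respondent, , drop = FALSE]
  others <- others[others[[alters]], , drop = FALSE]
  if (nrow(others) == 0) {
    stop("degenerate network: the respondent has no alters under the '",
         alters, "' membership rule")
  }
  n <- nrow(others)
  w <- alter_tie_matrix(others$relationship_to_head, marriage_ties, table)
  Z <- matrix(0, n + 1, n + 1)
  Z[1, -1] <- 1
  Z[-1, 1] <- 1
  Z[-1, -1] <- w
  ids <- c(ego$member_id, others$member_id)
  dimnames(Z) <- list(ids, ids)
  structure(list(ego = ego, alters = others, Z = Z,
                 household_id = roster$household_id[[1]]),
            class = "ego_network")
}

# symmetric n x n normalized tie matrix from relationship codes
alter_tie_matrix <- function(codes, marriage_ties = FALSE, table = NULL) {
  n <- length(codes)
  w <- matrix(0, n, n)
  if (n > 1) {
    idx <- which(upper.tri(w), arr.ind = TRUE)
    r <- pairwise_relatedness(codes[idx[, 1]], codes[idx[, 2]], table)
    wt <- as.numeric(r) / 0.5
    if (marriage_ties) {
      a <- codes[idx[, 1]]; b <- codes[idx[, 2]]
      sp <- (a == "head" & b == "spouse") | (a == "spouse" & b == "head") |
        (a == "child" & b == "child_in_law") | (a == "child_in_law" & b == "child")
      wt[sp] <- 1
    }
    w[idx] <- wt
    w <- w + t(w)
  }
  w
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network> household", x$household_id,
      "| degree", nrow(x$alters), "\n")
  cat("alters:", paste(x$alters$relationship_to_head, collapse = ", "), "\n")
  invisible(x)
}

#' Build ego networks for every household in a roster table
#'
#' @inheritParams build_ego_network
#' @param rosters Multi-household roster tibble.
#' @return A named list of `ego_network` objects, one per household.
#' @export
ego_networks <- function(rosters, alters = c("de_jure", "de_facto"),
                         marriage_ties = FALSE, table = NULL) {
  alters <- match.arg(alters)
  split(rosters, rosters$household_id) |>
    purrr::map(build_ego_network, alters = alters,
               marriage_ties = marriage_ties, table = table)
}
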