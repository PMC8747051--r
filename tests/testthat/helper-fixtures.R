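# Fixture builders: rosters and networks constructed in code.

# wrap an alter-alter weight matrix as an ego_network
make_net <- function(w) {
  n <- nrow(w)
  Z <- matrix(0, n + 1, n + 1)
  Z[1, -1] <- 1
  Z[-1, 1] <- 1
  Z[-1, -1] <- w
  ids <- c("ego", paste0("a", seq_len(n)))
  dimnames(Z) <- list(ids, ids)
  structure(list(ego = tibble::tibble(member_id = "ego"),
                 alters = tibble::tibble(member_id = ids[-1],
                                         relationship_to_head = "unspecified"),
                 Z = Z, household_id = "fixture"),
            class = "ego_network")
}

# a roster tibble from relationship codes; the respondent is marked by
# position (default: the spouse if present, else the first member)
make_roster <- function(codes, respondent = NULL, household_id = "hh1",
                        round = "2016", weight = 1, cluster_id = "c1",
                        sexes = NULL, ages = NULL,
                        de_jure = TRUE, de_facto = TRUE) {
  n <- length(codes)
  if (is.null(respondent)) {
    respondent <- if ("spouse" %in% codes) which(codes == "spouse")[1] else 1
  }
  tibble::tibble(
    household_id = household_id, cluster_id = cluster_id, round = round,
    weight = weight, residence = "rural", wealth_tercile = "middle",
    member_id = paste0("m", seq_len(n)),
    relationship_to_head = codes,
    sex = if (is.null(sexes)) rep(c("female", "male"), length.out = n) else sexes,
    age_years = if (is.null(ages)) seq(20, by = 5, length.out = n) else ages,
    education = "none",
    de_jure = rep_len(de_jure, n), de_facto = rep_len(de_facto, n),
    is_respondent = seq_len(n) == respondent,
    earnings = ifelse(seq_len(n) == respondent, "not_working", NA),
    coresident_husband = ifelse(seq_len(n) == respondent, TRUE, NA),
    maternal_respondent = ifelse(seq_len(n) == respondent, TRUE, NA))
}

# ego (spouse of head) + husband + two shared children: a nuclear roster
# whose alters form a complete kin clique
nuclear_roster <- function(...) {
  make_roster(c("head", "spouse", "child", "child"), respondent = 2, ...)
}

# a child feeding record with named food groups set
make_child <- function(child_id = "c1", household_id = "hh1", age_months = 12,
                       is_last_born = TRUE, breastfed = TRUE,
                       groups = character(), feed_count = 3,
                       solid_feed_count = feed_count) {
  rec <- tibble::tibble(child_id = child_id, household_id = household_id,
                        age_months = age_months, is_last_born = is_last_born,
                        breastfed = breastfed)
  for (g in food_group_cols()) rec[[g]] <- as.integer(g %in% groups)
  rec$feed_count <- feed_count
  rec$solid_feed_count <- solid_feed_count
  rec
}
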