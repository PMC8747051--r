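#' Configuration for the synthetic survey generator
#'
#' Bundles the knobs of the DHS-like household generator. Defaults
#' emulate a four-round national survey of households with a 6--23-month
#' last-born child: round sizes proportional to the survey's analytic
#' samples, round-specific urbanisation, an archetype mix of nuclear,
#' three-generation extended and non-relative-containing households that
#' differs by residence (rural households predominantly three-generation;
#' urban predominantly nuclear), member-level visitor/away rates, and a
#' per-outcome logistic model on standardised exposures with
#' round-specific intercepts matched to the published indicator
#' prevalences.
#'
#' @param n_households Number of households.
#' @param rounds Named numeric vector of round proportions (must sum
#'   to 1).
#' @param urban_fraction Named per-round urban fraction.
#' @param archetype_mix Named list with numeric vectors `rural` and
#'   `urban` giving probabilities for `nuclear`, `extended`,
#'   `non_relative` archetypes (each summing to 1).
#' @param visitor_rate,away_rate Per-member probabilities of being a
#'   visitor (de facto only) or a usual resident away last night.
#' @param outcome_model List with elements `mdd` and `mmf`, each a list
#'   of `intercepts` (named per-round log-odds), `beta` (named log-odds
#'   per 1-SD of exposure), and `re_sd` (extra round-level random
#'   intercept SD).
#' @param weight_sdlog SD of the log-normal sampling weights (mean 1).
#' @param cluster_size Households per sampling cluster.
#' @param seed Mandatory integer seed.
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_households = 100, seed = 42)
generator_config <- function(
    n_households = 2000,
    rounds = c("2000" = 0.30, "2005" = 0.13, "2011" = 0.28, "2016" = 0.29),
    urban_fraction = c("2000" = 0.066, "2005" = 0.376, "2011" = 0.158,
                       "2016" = 0.194),
    archetype_mix = list(
      rural = c(nuclear = 0.22, extended = 0.68, non_relative = 0.10),
      urban = c(nuclear = 0.62, extended = 0.23, non_relative = 0.15)),
    visitor_rate = 0.025, away_rate = 0.032,
    outcome_model = list(
      mdd = list(intercepts = c("2000" = qlogis(0.045),
                                "2005" = qlogis(0.0514),
                                "2011" = qlogis(0.0424),
                                "2016" = qlogis(0.124)),
                 beta = c(constraint = 0.18, degree = 0.05, age_sd = 0.10),
                 re_sd = 0),
      mmf = list(intercepts = c("2000" = qlogis(0.435),
                                "2005" = qlogis(0.47),
                                "2011" = qlogis(0.502),
                                "2016" = qlogis(0.489)),
                 beta = c(constraint = 0.28, degree = -0.10),
                 re_sd = 0)),
    weight_sdlog = 0.35, cluster_size = 25, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(abs(sum(rounds) - 1) < 1e-8,
            abs(sum(archetype_mix$rural) - 1) < 1e-8,
            abs(sum(archetype_mix$urban) - 1) < 1e-8,
            n_households >= 1)
  structure(list(n_households = n_households, rounds = rounds,
                 urban_fraction = urban_fraction,
                 archetype_mix = archetype_mix,
                 visitor_rate = visitor_rate, away_rate = away_rate,
                 outcome_model = outcome_model,
                 weight_sdlog = weight_sdlog, cluster_size = cluster_size,
                 seed = as.integer(seed)),
            class = "generator_config")
}

rcat <- function(n, probs) {
  names(probs)[1 + findInterval(runif(n), cumsum(probs), left.open = TRUE)]
}

# one household's member rows (data.frame) + index-child descriptor
make_household <- function(hid, archetype, round, urban) {
  edu_p <- if (urban) 0.60 else 0.22
  adult_edu <- function(n) ifelse(runif(n) < edu_p, "primary_or_above", "none")
  ego_age <- round(runif(1, 18, 38))
  child_age_m <- sample(6:23, 1)
  rows <- function(relationship, sex, age, education, respondent = FALSE) {
    data.frame(relationship_to_head = relationship, sex = sex,
               age_years = as.integer(age), education = education,
               is_respondent = respondent)
  }
  # peripheral members common in DHS rosters (fostered relatives'
  # children, nieces/nephews, step children, hired help); they carry weak
  # or absent kin ties and create the structural holes typical of
  # surveyed households
  peripherals <- function(n) {
    if (n == 0) return(NULL)
    rel <- sample(c("niece_nephew", "other_relative", "adopted",
                    "child_in_law", "non_relative"), n, TRUE,
                  prob = c(0.30, 0.30, 0.15, 0.15, 0.10))
    age <- ifelse(rel %in% c("niece_nephew", "adopted"),
                  sample(3:15, n, TRUE), round(runif(n, 16, 45)))
    rows(rel, sample(c("male", "female"), n, TRUE), age, adult_edu(n))
  }
  if (archetype == "extended") {
    # three generations: eldest couple, their sons, sons' wives (one of
    # whom is the respondent), unmarried daughters, grandchildren, and
    # peripheral members
    head_age <- ego_age + round(runif(1, 18, 28))
    n_sons <- 1 + rpois(1, 0.4)
    n_daughters <- rbinom(1, 1, 0.45)
    n_grandkids <- rpois(1, 0.5)
    hh <- rbind(
      rows("head", "male", head_age, adult_edu(1)),
      rows("spouse", "female", head_age - round(runif(1, 2, 8)), adult_edu(1)),
      rows("child_in_law", "female", ego_age, adult_edu(1), respondent = TRUE),
      rows("child", "male", ego_age + round(runif(n_sons, 1, 6)), adult_edu(n_sons)),
      if (n_daughters) rows("child", "female", round(runif(1, 12, 19)), adult_edu(1)),
      rows("grandchild", sample(c("male", "female"), 1), 0, "none"),
      if (n_grandkids) rows("grandchild",
                            sample(c("male", "female"), n_grandkids, TRUE),
                            sample(2:9, n_grandkids, TRUE), "none"),
      peripherals(rpois(1, 0.8)))
    child_rel <- "grandchild"
  } else {
    # nuclear couple (respondent is the head's wife) and their children,
    # plus unrelated members (e.g. domestic workers) for the
    # non-relative-containing archetype
    n_kids_older <- rpois(1, 1.6)
    hh <- rbind(
      rows("head", "male", ego_age + round(runif(1, 2, 9)), adult_edu(1)),
      rows("spouse", "female", ego_age, adult_edu(1), respondent = TRUE),
      rows("child", sample(c("male", "female"), 1), 0, "none"),
      if (n_kids_older) rows("child",
                             sample(c("male", "female"), n_kids_older, TRUE),
                             2 + 3 * seq_len(n_kids_older), "none"))
    if (archetype == "non_relative") {
      # unrelated members plus the occasional peripheral relative; the
      # pure nuclear archetype stays a complete kin clique
      n_nr <- sample(1:2, 1)
      hh <- rbind(hh, rows("non_relative",
                           sample(c("male", "female"), n_nr, TRUE),
                           round(runif(n_nr, 14, 40)), adult_edu(n_nr)),
                  peripherals(rbinom(1, 2, 0.3)))
    }
    child_rel <- "child"
  }
  hh$household_id <- hid
  hh$member_id <- sprintf("m%02d", seq_len(nrow(hh)))
  # the index child is the first row with the child's relationship and age 0
  idx <- which(hh$relationship_to_head == child_rel & hh$age_years == 0)[1]
  list(members = hh, index_member = hh$member_id[idx],
       child_age_m = child_age_m)
}

#' Generate synthetic households, children and weights
#'
#' Draws the household rosters (one eligible last-born child aged 6--23
#' months per household), the child feeding-recall shells (feeding
#' columns unfilled until [generate_outcomes()]), cluster ids in blocks,
#' and log-normal sampling weights. Identical seeds give identical
#' output.
#'
#' @param config A [generator_config()].
#' @return List with tibbles `rosters` and `children` (feeding columns
#'   `NA`), in the dialect of [roster-dialect].
#' @export
generate_households <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_households
  round_lab <- rcat(n, config$rounds)
  urban <- unname(runif(n) < config$urban_fraction[round_lab])
  archetype <- character(n)
  for (res in c("rural", "urban")) {
    sel <- if (res == "urban") urban else !urban
    archetype[sel] <- rcat(sum(sel), config$archetype_mix[[res]])
  }
  hids <- sprintf("hh%05d", seq_len(n))
  built <- purrr::pmap(list(hids, archetype, round_lab, urban), make_household)
  members <- dplyr::bind_rows(purrr::map(built, "members"))
  m <- nrow(members)
  # residence turnover: visitors are de facto only; some usual residents
  # (never the respondent or the index child) were away last night
  visitor <- runif(m) < config$visitor_rate
  away <- runif(m) < config$away_rate
  protected <- members$is_respondent | members$age_years == 0
  visitor[protected] <- FALSE
  away[protected | visitor] <- FALSE
  ord <- order(match(members$household_id, hids))
  weights <- rlnorm(n, meanlog = 0, sdlog = config$weight_sdlog)
  weights <- weights / mean(weights)
  hh_tbl <- tibble::tibble(
    household_id = hids, round = round_lab,
    residence = ifelse(urban, "urban", "rural"),
    cluster_id = paste0(round_lab, "_c",
                        sprintf("%04d", stats::ave(seq_len(n), round_lab,
                          FUN = function(i) (seq_along(i) - 1) %/% config$cluster_size + 1))),
    weight = weights,
    wealth_tercile = rcat(n, c(poor = 1, middle = 1, rich = 1) / 3),
    earnings = rcat(n, c(not_working = 0.55, unpaid = 0.15, paid = 0.30)),
    coresident_husband = runif(n) < 0.90,
    maternal_respondent = runif(n) < 0.88)
  rosters <- tibble::as_tibble(members[ord, , drop = FALSE]) |>
    dplyr::mutate(de_jure = !visitor[ord], de_facto = !away[ord]) |>
    dplyr::left_join(hh_tbl, by = "household_id") |>
    dplyr::mutate(
      earnings = ifelse(.data$is_respondent, .data$earnings, NA_character_),
      coresident_husband = ifelse(.data$is_respondent, .data$coresident_husband, NA),
      maternal_respondent = ifelse(.data$is_respondent, .data$maternal_respondent, NA)) |>
    dplyr::select(dplyr::all_of(roster_required_cols()))
  children <- tibble::tibble(
    child_id = paste0("c_", hids),
    household_id = hids,
    age_months = vapply(built, `[[`, integer(1), "child_age_m"),
    is_last_born = TRUE,
    breastfed = runif(n) < 0.95 - 0.012 *
      (vapply(built, `[[`, integer(1), "child_age_m") - 6))
  for (col in food_group_cols()) children[[col]] <- NA_integer_
  children$feed_count <- NA_integer_
  children$solid_feed_count <- NA_integer_
  list(rosters = rosters, children = children)
}

#' Draw IYCF outcomes through a configured logistic model
#'
#' Computes the structural and compositional exposures on the generated
#' rosters, standardises them, draws each child's MDD and MMF status from
#' the configured logistic model (round intercepts plus optional
#' round-level random intercepts), and back-fills food-group flags, feed
#' counts and solid-feed counts consistent with the drawn indicator so
#' that re-coding the records through [code_outcomes()] reproduces it
#' exactly.
#'
#' @param rosters,children Output of [generate_households()].
#' @param config The same [generator_config()].
#' @param exposures Optional precomputed per-household exposure tibble
#'   (the joined [structural_metrics()] and [composition_metrics()]
#'   output); supplying it lets outcome draws be replicated on a fixed
#'   household design without recomputing the network metrics.
#' @return The `children` tibble with feeding columns filled and the
#'   latent `mdd_true`, `mmf_true` indicators attached.
#' @export
generate_outcomes <- function(rosters, children, config, exposures = NULL) {
  set.seed(config$seed + 1L)
  expo <- if (is.null(exposures)) {
    dplyr::left_join(structural_metrics(rosters),
                     composition_metrics(rosters), by = "household_id")
  } else {
    exposures
  }
  hh <- dplyr::distinct(rosters, .data$household_id, .data$round)
  d <- children |>
    dplyr::left_join(expo, by = "household_id") |>
    dplyr::left_join(hh, by = "household_id")
  zscore <- function(x) (x - mean(x)) / ifelse(sd(x) > 0, sd(x), 1)
  draw <- function(model) {
    eta <- unname(model$intercepts[d$round])
    for (v in names(model$beta)) {
      eta <- eta + model$beta[[v]] * zscore(d[[v]])
    }
    if (model$re_sd > 0) {
      u <- rnorm(length(model$intercepts), 0, model$re_sd)
      names(u) <- names(model$intercepts)
      eta <- eta + unname(u[d$round])
    }
    runif(nrow(d)) < plogis(eta)
  }
  mdd <- draw(config$outcome_model$mdd)
  mmf <- draw(config$outcome_model$mmf)
  n <- nrow(d)
  # back-fill dietary recall: met -> 5-8 groups, not met -> 0-4 (breast
  # milk listed first for breastfed children)
  dd_score <- ifelse(mdd, sample(5:8, n, TRUE),
                     sample(0:4, n, TRUE, prob = c(.1, .25, .3, .25, .1)))
  fg <- matrix(0L, n, 8, dimnames = list(NULL, food_group_cols()))
  for (i in seq_len(n)) {
    k <- dd_score[i]
    if (k > 0) {
      first <- if (children$breastfed[i]) 1L else sample(8, 1)
      picks <- c(first, sample(setdiff(1:8, first), k - 1))
      fg[i, picks[seq_len(k)]] <- 1L
    }
  }
  # back-fill meal frequency consistent with the age/breastfeeding rule
  need <- ifelse(children$breastfed,
                 ifelse(children$age_months <= 8, 2L, 3L), 4L)
  feed <- integer(n); solid <- integer(n)
  for (i in seq_len(n)) {
    if (mmf[i]) {
      feed[i] <- need[i] + sample(0:3, 1)
      solid[i] <- if (children$breastfed[i]) feed[i] else sample(seq_len(feed[i]), 1)
    } else if (children$breastfed[i]) {
      feed[i] <- sample(0:(need[i] - 1), 1)
      solid[i] <- feed[i]
    } else {
      # non-breastfed misses by too few feeds or by no solid feed
      if (runif(1) < 0.8) {
        feed[i] <- sample(0:3, 1)
        solid[i] <- if (feed[i] > 0) sample(0:feed[i], 1) else 0L
      } else {
        feed[i] <- sample(4:6, 1)
        solid[i] <- 0L
      }
    }
  }
  out <- children
  out[, food_group_cols()] <- tibble::as_tibble(fg)
  out$feed_count <- feed
  out$solid_feed_count <- solid
  out$mdd_true <- mdd
  out$mmf_true <- mmf
  out
}

#' Generate a complete synthetic survey
#'
#' [generate_households()] followed by [generate_outcomes()].
#'
#' @param config A [generator_config()].
#' @return List with `rosters`, `children` (feeding columns filled) and
#'   the `config`.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 50, seed = 1))
#' nrow(svy$children)
simulate_survey <- function(config) {
  hh <- generate_households(config)
  children <- generate_outcomes(hh$rosters, hh$children, config)
  list(rosters = hh$rosters, children = children, config = config)
}
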