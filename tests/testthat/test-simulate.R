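test_that("identical seeds give identical surveys", {
  a <- simulate_survey(generator_config(n_households = 80, seed = 99))
  b <- simulate_survey(generator_config(n_households = 80, seed = 99))
  expect_identical(a$rosters, b$rosters)
  expect_identical(a$children, b$children)
  c <- simulate_survey(generator_config(n_households = 80, seed = 100))
  expect_false(identical(a$children, c$children))
  expect_error(generator_config(n_households = 10), "seed")
})

test_that("every household holds one eligible last-born child and valid rosters", {
  svy <- simulate_survey(generator_config(n_households = 150, seed = 7))
  expect_silent(validate_rosters(svy$rosters))
  expect_equal(nrow(svy$children), 150)
  expect_true(all(svy$children$is_last_born))
  expect_true(all(dplyr::between(svy$children$age_months, 6, 23)))
  cohort <- select_eligible(svy$rosters, svy$children)
  expect_equal(nrow(cohort), 150)
  # weights are positive with mean one; clusters group households in blocks
  w <- dplyr::distinct(svy$rosters, household_id, weight)$weight
  expect_true(all(w > 0))
  expect_equal(mean(w), 1, tolerance = 1e-9)
  expect_gt(min(table(dplyr::distinct(svy$rosters, household_id,
                                      cluster_id)$cluster_id)), 1)
})

test_that("re-coding back-filled records reproduces the drawn indicators exactly", {
  svy <- simulate_survey(generator_config(n_households = 250, seed = 12))
  coded <- code_mmf(code_mdd(svy$children))
  expect_equal(coded$mdd_met, svy$children$mdd_true)
  expect_equal(coded$mmf_met, svy$children$mmf_true)
})

test_that("a null outcome model returns the intercept prevalence", {
  cfg <- generator_config(
    n_households = 1500, seed = 41,
    outcome_model = list(
      mdd = list(intercepts = c("2000" = qlogis(0.1), "2005" = qlogis(0.1),
                                "2011" = qlogis(0.1), "2016" = qlogis(0.1)),
                 beta = c(), re_sd = 0),
      mmf = list(intercepts = c("2000" = qlogis(0.5), "2005" = qlogis(0.5),
                                "2011" = qlogis(0.5), "2016" = qlogis(0.5)),
                 beta = c(), re_sd = 0)))
  svy <- simulate_survey(cfg)
  expect_equal(mean(svy$children$mdd_true), 0.1, tolerance = 0.25)
  expect_equal(mean(svy$children$mmf_true), 0.5, tolerance = 0.06)
})

test_that("round-specific intercepts land near the published prevalence pattern", {
  svy <- simulate_survey(generator_config(n_households = 2500, seed = 19))
  tab <- dplyr::left_join(svy$children,
                          dplyr::distinct(svy$rosters, household_id, round),
                          by = "household_id")
  prev <- tapply(tab$mdd_true, tab$round, mean)
  expect_true(dplyr::between(prev[["2011"]], 0.02, 0.07))
  expect_true(dplyr::between(prev[["2016"]], 0.09, 0.16))
  prev_mmf <- tapply(tab$mmf_true, tab$round, mean)
  expect_true(all(dplyr::between(prev_mmf, 0.38, 0.57)))
})

test_that("a nuclear-only mix produces complete kin cliques", {
  cfg <- generator_config(
    n_households = 120, seed = 9,
    archetype_mix = list(rural = c(nuclear = 1, extended = 0, non_relative = 0),
                         urban = c(nuclear = 1, extended = 0, non_relative = 0)))
  sm <- structural_metrics(generate_households(cfg)$rosters)
  expect_true(all(sm$constraint == 1))
  expect_true(all(sm$effective_size == 1))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_households = 10, seed = 1,
                                rounds = c("2000" = 0.6, "2016" = 0.6)))
  expect_error(generator_config(
    n_households = 10, seed = 1,
    archetype_mix = list(rural = c(nuclear = 0.5, extended = 0.2,
                                   non_relative = 0.1),
                         urban = c(nuclear = 1, extended = 0,
                                   non_relative = 0))))
})
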