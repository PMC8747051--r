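test_that("MDD over all 256 food-group patterns matches exhaustive enumeration", {
  flags <- expand.grid(rep(list(0:1), 8))
  names(flags) <- food_group_cols()
  rec <- tibble::as_tibble(flags)
  coded <- code_mdd(rec)
  expect_equal(coded$dd_score, as.integer(rowSums(flags)))
  expected <- apply(flags, 1, oracle_mdd)
  expect_equal(coded$mdd_met, expected)
  # anchors: 5 groups met, 4 not, 0 scores 0
  expect_true(coded$mdd_met[rowSums(flags) == 5][1])
  expect_false(coded$mdd_met[rowSums(flags) == 4][1])
  expect_equal(coded$dd_score[rowSums(flags) == 0], 0L)
})

test_that("the 7-group MDD variant drops breast milk and uses the 4-group cut", {
  rec <- make_child(groups = c("fg_grains", "fg_legumes", "fg_dairy",
                               "fg_eggs"))
  expect_false(code_mdd(rec)$mdd_met)
  expect_true(code_mdd(rec, n_groups = 7)$mdd_met)
})

test_that("a missing food-group flag yields a missing outcome", {
  rec <- make_child(groups = food_group_cols())
  rec$fg_dairy <- NA_integer_
  coded <- code_mdd(rec)
  expect_true(is.na(coded$dd_score))
  expect_true(is.na(coded$mdd_met))
})

test_that("MMF matches the rule oracle over every age/breastfeeding/feed cell", {
  cells <- expand.grid(age_months = 6:23, breastfed = c(TRUE, FALSE),
                       feed_count = 0:6, solid_count = 0:3)
  cells <- cells[cells$solid_count <= cells$feed_count, ]
  rec <- tibble::tibble(age_months = cells$age_months,
                        breastfed = cells$breastfed,
                        feed_count = cells$feed_count,
                        solid_feed_count = cells$solid_count)
  got <- code_mmf(rec)$mmf_met
  want <- mapply(oracle_mmf, cells$age_months, cells$breastfed,
                 cells$feed_count, cells$solid_count)
  expect_equal(got, unname(want))
  # monotone in feed counts
  wide <- tidyr::expand_grid(age_months = c(7, 12), breastfed = c(TRUE, FALSE),
                             feed_count = 0:6)
  wide$solid_feed_count <- wide$feed_count
  m <- code_mmf(wide)
  for (g in split(m, paste(m$age_months, m$breastfed))) {
    expect_true(all(diff(g$mmf_met[order(g$feed_count)]) >= 0))
  }
})

test_that("MMF anchors from the feeding guideline hold", {
  expect_true(code_mmf(make_child(age_months = 7, breastfed = TRUE,
                                  feed_count = 2))$mmf_met)
  expect_false(code_mmf(make_child(age_months = 12, breastfed = TRUE,
                                   feed_count = 2))$mmf_met)
  expect_false(code_mmf(make_child(age_months = 10, breastfed = FALSE,
                                   feed_count = 4, solid_feed_count = 0))$mmf_met)
  expect_true(code_mmf(make_child(age_months = 10, breastfed = FALSE,
                                  feed_count = 4, solid_feed_count = 1))$mmf_met)
  expect_error(code_mmf(make_child(age_months = 30)), "6-23")
})

test_that("round availability masks MDD in 2000 and MMF in 2005", {
  x <- tibble::tibble(round = c("2000", "2005", "2011", "2016"),
                      dd_score = 6L, mdd_met = TRUE, mmf_met = TRUE)
  m <- apply_round_availability(x)
  expect_true(is.na(m$mdd_met[m$round == "2000"]))
  expect_true(is.na(m$dd_score[m$round == "2000"]))
  expect_true(is.na(m$mmf_met[m$round == "2005"]))
  expect_false(anyNA(m$mdd_met[m$round %in% c("2005", "2011", "2016")]))
  expect_false(anyNA(m$mmf_met[m$round %in% c("2000", "2011", "2016")]))
  expect_error(apply_round_availability(tibble::tibble(round = "1995",
                                                       mdd_met = TRUE)),
               "unknown survey round")
  # the masking map is configurable
  m2 <- apply_round_availability(x, mask = list())
  expect_false(anyNA(m2$mdd_met))
})
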