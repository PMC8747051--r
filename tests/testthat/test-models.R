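sim_tab <- function(n = 500, seed = 1) {
  svy <- simulate_survey(generator_config(n_households = n, seed = seed))
  build_analysis_table(svy)
}

test_that("equal weights reproduce the unweighted fit", {
  tab <- sim_tab(400, seed = 21)
  tab$weight <- 2.5
  f <- mmf_met ~ constraint + age_years + education
  wfit <- fit_weighted_logistic(tab, f)
  ufit <- glm(f, family = binomial(), data = tab)
  expect_equal(unname(coef(wfit$model)), unname(coef(ufit)), tolerance = 1e-8)
})

test_that("duplicating a record equals giving it weight two", {
  tab <- sim_tab(200, seed = 22)
  dup <- dplyr::bind_rows(tab, tab[7, ])
  wts <- tab
  wts$weight <- 1
  wts$weight[7] <- 2
  dup$weight <- 1
  f <- mmf_met ~ constraint + degree
  fit_dup <- fit_weighted_logistic(dup, f)
  fit_wt <- fit_weighted_logistic(wts, f)
  expect_equal(coef(fit_dup$model), coef(fit_wt$model), tolerance = 1e-8)
})

test_that("listwise deletion is counted and the outcome must be binary", {
  withr::with_seed(23, {
    d <- tibble::tibble(y = runif(150) < 0.5, x = rnorm(150), weight = 1,
                        cluster_id = rep(1:15, 10))
  })
  d$x[1:5] <- NA
  fit <- fit_weighted_logistic(d, y ~ x)
  expect_equal(fit$n_dropped, 5)
  expect_equal(fit$n, 145)
  d$bad <- runif(150)
  expect_error(fit_weighted_logistic(d, bad ~ x), "binary")
})

test_that("separation is flagged rather than silently reported", {
  withr::with_seed(3, {
    d <- tibble::tibble(y = rep(c(FALSE, TRUE), each = 30),
                        x = rep(c(0, 1), each = 30) + rnorm(60, sd = 1e-4),
                        weight = 1, cluster_id = rep(1:6, 10))
  })
  fit <- suppressWarnings(fit_weighted_logistic(d, y ~ x))
  expect_true(fit$separation)
})

test_that("known exposure effects are recovered without bias", {
  # fixed household design; outcomes redrawn per replicate through the
  # generator's logistic model; fit on the same standardised scale
  cfg <- generator_config(n_households = 500, seed = 77)
  hh <- generate_households(cfg)
  expo <- dplyr::left_join(structural_metrics(hh$rosters),
                           composition_metrics(hh$rosters),
                           by = "household_id")
  truth <- cfg$outcome_model$mmf$beta[["constraint"]]
  est <- vapply(1:60, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    kids <- generate_outcomes(hh$rosters, hh$children, cfg_i, exposures = expo)
    d <- dplyr::left_join(kids, expo, by = "household_id") |>
      dplyr::left_join(dplyr::distinct(hh$rosters, household_id, round,
                                       weight, cluster_id),
                       by = "household_id") |>
      dplyr::mutate(z_con = as.numeric(scale(constraint)),
                    z_deg = as.numeric(scale(degree)))
    fit <- fit_weighted_logistic(d, mmf_true ~ z_con + z_deg + factor(round))
    coef(fit$model)[["z_con"]]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3.5 * mc_se + 0.02)
})

test_that("a null exposure rejects near the nominal rate", {
  cfg <- generator_config(n_households = 400, seed = 78)
  hh <- generate_households(cfg)
  expo <- dplyr::left_join(structural_metrics(hh$rosters),
                           composition_metrics(hh$rosters),
                           by = "household_id")
  design <- dplyr::distinct(hh$rosters, household_id, round, weight, cluster_id)
  p_reject <- vapply(1:150, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    cfg_i$outcome_model$mmf$beta <- c(constraint = 0)
    kids <- generate_outcomes(hh$rosters, hh$children, cfg_i, exposures = expo)
    d <- dplyr::left_join(kids, expo, by = "household_id") |>
      dplyr::left_join(design, by = "household_id")
    fit <- fit_weighted_logistic(d, mmf_true ~ constraint + factor(round))
    tidy(fit)$p.value[2] < 0.05
  }, logical(1))
  expect_lte(mean(p_reject), 0.12)
})

test_that("zero between-round variance collapses to the plain logistic", {
  withr::with_seed(44, {
    d <- tibble::tibble(round = rep(c("2000", "2011", "2016"), each = 250),
                        x = rnorm(750))
    d$y <- runif(750) < plogis(-0.4 + 0.6 * d$x)
  })
  fit <- suppressMessages(fit_random_intercept_logistic(d, y ~ x))
  expect_true(fit$re_boundary)
  plain <- glm(y ~ x, family = binomial(), data = d)
  expect_equal(unname(lme4::fixef(fit$model)), unname(coef(plain)),
               tolerance = 1e-3)
})

test_that("quadrature log-likelihood matches dense-grid integration on a small fixture", {
  withr::with_seed(55, {
    u <- c(-0.5, 0.2, 0.6)
    d <- tibble::tibble(round = rep(c("2005", "2011", "2016"), each = 30),
                        x = rnorm(90))
    d$y <- runif(90) < plogis(-0.3 + 0.5 * d$x + u[match(d$round, unique(d$round))])
  })
  fit <- fit_random_intercept_logistic(d, y ~ x, nAGQ = 15)
  ll_grid <- marginal_loglik_grid(lme4::fixef(fit$model), fit$re_sd, d, y ~ x)
  expect_equal(as.numeric(logLik(fit$model)), ll_grid, tolerance = 1e-4)
})

test_that("a single round is rejected with advice", {
  d <- tibble::tibble(round = "2016", x = rnorm(50), y = runif(50) < 0.5)
  expect_error(fit_random_intercept_logistic(d, y ~ x), "per round")
})

test_that("a simulated round-intercept SD is recovered on average", {
  truth <- 0.5
  ests <- vapply(1:25, function(i) {
    withr::with_seed(500 + i, {
      u <- rnorm(4, 0, truth)
      d <- tibble::tibble(round = rep(c("2000", "2005", "2011", "2016"),
                                      each = 150),
                          x = rnorm(600))
      d$y <- runif(600) < plogis(-0.2 + 0.4 * d$x +
                                   u[match(d$round, unique(d$round))])
    })
    fit_random_intercept_logistic(d, y ~ x, nAGQ = 9)$re_sd
  }, numeric(1))
  # with 4 clusters the SD is noisy and boundary-prone; the mean should
  # still sit near the truth
  expect_lt(abs(mean(ests) - truth), 0.2)
})

test_that("tidy and glance expose odds ratios and fit diagnostics", {
  tab <- sim_tab(300, seed = 25)
  fit <- fit_weighted_logistic(tab, mmf_met ~ constraint + age_years)
  td <- tidy(fit, exponentiate = TRUE)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$conf.low <= td$conf.high))
  expect_equal(td$estimate, exp(tidy(fit)$estimate))
  g <- glance(fit)
  expect_equal(g$n, fit$n)
  pooled <- fit_random_intercept_logistic(tab, mmf_met ~ constraint)
  expect_true("re_sd" %in% names(glance(pooled)))
})
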