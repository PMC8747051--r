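#' Average marginal effect on the probability scale
#'
#' Average marginal effect (AME) of one explanatory variable on the
#' predicted outcome probability, in percentage points. For a continuous
#' variable the effect of a discrete shift of one (weighted) standard
#' deviation above each observation's value is averaged over the sample:
#' `AME = 100 * mean_w[ P(y=1 | x_i, v_i + SD) - P(y=1 | x_i, v_i) ]`.
#' For a categorical variable the effect is the average discrete change
#' from the reference level to each other level. Confidence intervals use
#' the delta method with the fit's (cluster-robust or model-based)
#' coefficient variance; for pooled mixed fits predictions are at the
#' median round (random intercept 0).
#'
#' @param fit A `kinfeed_fit`.
#' @param variable Name of a model variable.
#' @param data Data over which to average (default: the fit's estimation
#'   sample).
#' @param shift Size of the continuous shift in SD units (default 1).
#' @param conf.level Confidence level.
#' @return Tibble with `variable`, `level` (`NA` for continuous),
#'   `scaling`, `estimate` (percentage points), `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 300, seed = 3))
#' tab <- build_analysis_table(svy)
#' fit <- fit_weighted_logistic(tab, mmf_met ~ constraint + age_years)
#' average_marginal_effect(fit, "constraint")
average_marginal_effect <- function(fit, variable, data = NULL, shift = 1,
                                    conf.level = 0.95) {
  if (is.null(data)) data <- fit$data
  if (!variable %in% all.vars(fit$formula)) {
    stop("variable '", variable, "' is not in the model")
  }
  cv <- fit_coef_vcov(fit)
  rhs_formula <- if (fit$type == "mixed_logistic") {
    lme4::nobars(stats::update(fit$formula, NULL ~ .))
  } else {
    stats::update(fit$formula, NULL ~ .)
  }
  w <- if (!is.null(fit$weights_col) && fit$weights_col %in% names(data)) {
    data[[fit$weights_col]]
  } else {
    rep(1, nrow(data))
  }
  q <- qnorm(1 - (1 - conf.level) / 2)
  v <- data[[variable]]

  ame_pair <- function(d_base, d_alt) {
    X1 <- model.matrix(rhs_formula, d_base)
    X2 <- model.matrix(rhs_formula, d_alt)
    eta1 <- drop(X1 %*% cv$beta)
    eta2 <- drop(X2 %*% cv$beta)
    est <- 100 * weighted.mean(plogis(eta2) - plogis(eta1), w)
    grad <- 100 * (colSums(w * dlogis(eta2) * X2) -
                   colSums(w * dlogis(eta1) * X1)) / sum(w)
    se <- sqrt(drop(grad %*% cv$V %*% grad))
    c(est = est, se = se)
  }

  if (is.numeric(v)) {
    delta <- shift * sqrt(weighted.mean((v - weighted.mean(v, w))^2, w))
    alt <- data
    alt[[variable]] <- v + delta
    r <- ame_pair(data, alt)
    out <- tibble::tibble(variable = variable, level = NA_character_,
                          scaling = "per_sd_above_mean",
                          estimate = unname(r["est"]), std.error = unname(r["se"]))
  } else {
    lev <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
    base <- data
    base[[variable]] <- factor(lev[1], levels = lev)
    out <- purrr::map(lev[-1], function(l) {
      alt <- data
      alt[[variable]] <- factor(l, levels = lev)
      r <- ame_pair(base, alt)
      tibble::tibble(variable = variable, level = l,
                     scaling = "discrete_from_reference",
                     estimate = unname(r["est"]), std.error = unname(r["se"]))
    })
    out <- dplyr::bind_rows(out)
  }
  dplyr::mutate(out,
                conf.low = .data$estimate - q * .data$std.error,
                conf.high = .data$estimate + q * .data$std.error)
}
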