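#' Survey-weighted logistic regression with cluster-robust errors
#'
#' Fits a logistic regression by iteratively reweighted least squares with
#' sampling weights normalised to sum to the sample size, and computes
#' robust (sandwich) standard errors clustered on the primary sampling
#' unit -- the standard design-based analysis for two-stage household
#' surveys. Rows with missing values in the model frame are dropped
#' listwise and counted.
#'
#' @param data Analysis tibble.
#' @param formula Model formula, e.g. `mdd_met ~ constraint + age_years`.
#' @param weights Name of the sampling-weight column (default `"weight"`);
#'   `NULL` for equal weights.
#' @param cluster Name of the clustering column (default `"cluster_id"`);
#'   `NULL` for heteroskedasticity-robust errors without clustering.
#' @param max_iter Maximum IRLS iterations.
#' @return A `kinfeed_fit` object; see [tidy.kinfeed_fit()] and
#'   [glance.kinfeed_fit()].
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 200, seed = 7))
#' tab <- build_analysis_table(svy)
#' fit <- fit_weighted_logistic(tab, mmf_met ~ constraint + age_years)
#' tidy(fit, exponentiate = TRUE)
fit_weighted_logistic <- function(data, formula, weights = "weight",
                                  cluster = "cluster_id", max_iter = 100) {
  vars <- all.vars(formula)
  keep_cols <- unique(c(vars, weights, cluster))
  keep_cols <- intersect(keep_cols, names(data))
  cc <- complete.cases(data[keep_cols])
  n_dropped <- sum(!cc)
  d <- data[cc, , drop = FALSE]
  y <- d[[vars[1]]]
  if (!all(y %in% c(0, 1, TRUE, FALSE))) stop("outcome must be binary")
  # categorical covariates with a single observed level in this sample
  # (common in small per-round subsets) cannot enter the design matrix;
  # drop them and record the reduction
  degenerate <- vars[-1][vapply(vars[-1], function(v) {
    x <- d[[v]]
    !is.numeric(x) && dplyr::n_distinct(x[!is.na(x)]) < 2
  }, logical(1))]
  if (length(degenerate)) {
    formula <- stats::update(formula,
      as.formula(paste(". ~ . -", paste(degenerate, collapse = " - "))))
  }
  w <- if (is.null(weights)) rep(1, nrow(d)) else d[[weights]]
  w <- w / mean(w)                      # normalise to sum to n
  d$.w <- w
  fit <- glm(formula, family = quasibinomial(), data = d, weights = .w,
             control = list(maxit = max_iter))
  if (!fit$converged) stop("IRLS did not converge after ", max_iter,
                           " iterations; final deviance ", round(fit$deviance, 3))
  separation <- any(abs(coef(fit)) > 15, na.rm = TRUE)
  V <- if (!is.null(cluster)) {
    sandwich::vcovCL(fit, cluster = d[[cluster]])
  } else {
    sandwich::sandwich(fit)
  }
  structure(list(model = fit, vcov = V, n = nrow(d), n_dropped = n_dropped,
                 dropped_terms = if (length(degenerate)) degenerate else character(),
                 formula = formula, data = d, weights_col = weights,
                 cluster_col = cluster, separation = separation,
                 converged = fit$converged, type = "weighted_logistic"),
            class = "kinfeed_fit")
}

#' @export
print.kinfeed_fit <- function(x, ...) {
  cat("<kinfeed_fit>", x$type, "| n =", x$n)
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped)", sep = "")
  if (isTRUE(x$separation)) cat(" | possible separation")
  cat("\n")
  print(tidy(x, exponentiate = TRUE), ...)
  invisible(x)
}

fit_coef_vcov <- function(x) {
  if (x$type == "mixed_logistic") {
    list(beta = lme4::fixef(x$model), V = as.matrix(vcov(x$model)))
  } else {
    list(beta = coef(x$model), V = x$vcov)
  }
}

#' Tidy a fitted association model
#'
#' broom-style one-row-per-term summary using the fit's robust (weighted
#' logistic) or model-based (mixed logistic) variance.
#'
#' @param x A `kinfeed_fit`.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.kinfeed_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  cv <- fit_coef_vcov(x)
  se <- sqrt(diag(cv$V))
  z <- cv$beta / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(cv$beta), estimate = unname(cv$beta), std.error = se,
    statistic = unname(z), p.value = 2 * pnorm(-abs(z)),
    conf.low = unname(cv$beta - q * se), conf.high = unname(cv$beta + q * se))
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' Model-level summary of a fitted association model
#'
#' @param x A `kinfeed_fit`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `n_dropped`, `converged`,
#'   `separation`, and for pooled fits the random-intercept SD
#'   (`re_sd`), its boundary flag and the integration method.
#' @export
glance.kinfeed_fit <- function(x, ...) {
  out <- tibble::tibble(n = x$n, n_dropped = x$n_dropped,
                        converged = isTRUE(x$converged),
                        separation = isTRUE(x$separation),
                        type = x$type)
  if (x$type == "mixed_logistic") {
    out$re_sd <- x$re_sd
    out$re_boundary <- x$re_boundary
    out$nAGQ <- x$nAGQ
    out$logLik <- as.numeric(logLik(x$model))
  }
  out
}
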