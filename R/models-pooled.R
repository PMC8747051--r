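#' Pooled logistic regression with a random survey-round intercept
#'
#' Fits a multilevel mixed-effects logistic regression with a random
#' intercept per survey round, pooling rounds into one overall
#' association. The marginal likelihood is integrated by adaptive
#' Gauss--Hermite quadrature (default 15 nodes); if quadrature fails the
#' fit falls back to the Laplace approximation with a warning. Sampling
#' weights, when supplied, enter as normalised pseudo-likelihood scaling.
#' With only a handful of rounds the variance component is boundary-prone;
#' a fit with the random-intercept SD estimated at (near) zero is reported
#' with `re_boundary = TRUE` rather than failing.
#'
#' @param data Analysis tibble containing a `round` column (>= 2 rounds).
#' @param formula Fixed-effects formula, e.g. `mmf_met ~ constraint +
#'   age_years`; the `(1 | round)` term is appended automatically.
#' @param weights Name of the sampling-weight column, or `NULL` (default)
#'   for an unweighted fit.
#' @param nAGQ Number of adaptive Gauss--Hermite quadrature nodes.
#' @return A `kinfeed_fit` of type `"mixed_logistic"` with elements
#'   `re_sd` (random-intercept SD), `re_var`, `re_boundary`, `nAGQ`.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 300, seed = 2))
#' tab <- build_analysis_table(svy)
#' fit <- fit_random_intercept_logistic(tab, mmf_met ~ constraint)
#' glance(fit)
fit_random_intercept_logistic <- function(data, formula, weights = NULL,
                                          nAGQ = 15) {
  if (!"round" %in% names(data)) stop("data must contain a 'round' column")
  vars <- all.vars(formula)
  keep_cols <- intersect(unique(c(vars, "round", weights)), names(data))
  cc <- complete.cases(data[keep_cols])
  d <- data[cc, , drop = FALSE]
  if (length(unique(d$round)) < 2) {
    stop("fewer than 2 survey rounds; use fit_weighted_logistic() per round")
  }
  d$.w <- if (is.null(weights)) rep(1, nrow(d)) else d[[weights]] / mean(d[[weights]])
  degenerate <- vars[-1][vapply(vars[-1], function(v) {
    x <- d[[v]]
    !is.numeric(x) && dplyr::n_distinct(x[!is.na(x)]) < 2
  }, logical(1))]
  if (length(degenerate)) {
    formula <- stats::update(formula,
      as.formula(paste(". ~ . -", paste(degenerate, collapse = " - "))))
  }
  f <- stats::update(formula, . ~ . + (1 | round))
  fit_with <- function(q) {
    withCallingHandlers(
      lme4::glmer(f, data = d, family = binomial(), weights = .w, nAGQ = q),
      warning = function(w) {
        # pseudo-likelihood weight scaling makes successes non-integer
        if (grepl("non-integer", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  used_nAGQ <- nAGQ
  fit <- tryCatch(fit_with(nAGQ), error = function(e) {
    warning("adaptive quadrature failed (", conditionMessage(e),
            "); falling back to Laplace")
    used_nAGQ <<- 1
    fit_with(1)
  })
  re_sd <- sqrt(as.numeric(lme4::VarCorr(fit)$round))
  conv <- length(fit@optinfo$conv$lme4) == 0
  structure(list(model = fit, vcov = as.matrix(vcov(fit)), n = nrow(d),
                 n_dropped = sum(!cc),
                 dropped_terms = if (length(degenerate)) degenerate else character(),
                 formula = formula, data = d,
                 weights_col = weights, cluster_col = NULL,
                 separation = any(abs(lme4::fixef(fit)) > 15),
                 converged = conv, re_sd = re_sd, re_var = re_sd^2,
                 re_boundary = re_sd < 1e-4, nAGQ = used_nAGQ,
                 type = "mixed_logistic"),
            class = "kinfeed_fit")
}

#' Marginal log-likelihood of a random-intercept logistic model
#'
#' Evaluates the marginal log-likelihood of a logistic model with a
#' normal random intercept per group by direct numerical integration over
#' a dense trapezoid grid. Provided for diagnostics and cross-checking of
#' the quadrature-based fit.
#'
#' @param beta Named fixed-effect coefficients (matching the design
#'   matrix columns of `formula` on `data`).
#' @param sigma Random-intercept SD (>= 0).
#' @param data Data containing the model variables and `group`.
#' @param formula Fixed-effects formula.
#' @param group Name of the grouping column (default `"round"`).
#' @param grid_half_width Integration range in units of `sigma` (default
#'   8), with `grid_n` equally spaced nodes.
#' @param grid_n Number of grid nodes (default 2001).
#' @param weights Optional per-observation likelihood weights.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik_grid <- function(beta, sigma, data, formula, group = "round",
                                 grid_half_width = 8, grid_n = 2001,
                                 weights = NULL) {
  X <- model.matrix(formula, data)
  stopifnot(ncol(X) == length(beta))
  y <- as.numeric(model.frame(formula, data)[[1]])
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  eta0 <- drop(X %*% beta)
  g <- data[[group]]
  if (sigma < 1e-10) {
    return(sum(w * (y * eta0 - log1p(exp(eta0)))))
  }
  u <- seq(-grid_half_width * sigma, grid_half_width * sigma, length.out = grid_n)
  du <- u[2] - u[1]
  total <- 0
  for (gi in unique(g)) {
    idx <- g == gi
    # log f(y_g | u) + log phi(u) on the grid
    lp <- vapply(u, function(ui) {
      eta <- eta0[idx] + ui
      sum(w[idx] * (y[idx] * eta - log1p(exp(eta))))
    }, numeric(1)) + stats::dnorm(u, sd = sigma, log = TRUE)
    m <- max(lp)
    total <- total + m + log(sum(exp(lp - m)) * du)
  }
  total
}
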