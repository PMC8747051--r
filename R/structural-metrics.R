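#' Structural ego-network measures
#'
#' Burt's structural-hole measures computed on the woman's household ego
#' network, where ties are weighted by normalised kinship relatedness.
#' All measures are restricted to the alters (household members excluding
#' the respondent):
#'
#' * **degree** -- number of alters.
#' * **density** -- mean alter--alter tie weight over the n(n-1)/2 pairs.
#' * **effective size** -- `sum_j (1 - sum_q p_iq m_jq)` over alters j,
#'   with `p` the row-proportional tie strengths of the ego i, and
#'   `m_jq` alter j's tie to q divided by j's strongest tie. Ranges from 1
#'   (all alters fully related: complete redundancy) to the degree (no
#'   alter pair related).
#' * **efficiency** -- effective size / degree.
#' * **constraint** -- Burt's aggregate constraint
#'   `C = sum_j (p_ij + sum_q p_iq p_qj)^2`. The raw value does not reach
#'   the conventional 0/1 endpoints (an empty alter graph gives 1/n), so
#'   a per-degree affine rescaling is applied:
#'   `C' = (C - C_empty(n)) / (C_complete(n) - C_empty(n))`, clamped to
#'   \[0, 1\], where `C_empty`/`C_complete` are the raw constraints of the
#'   same-degree network with no alter ties and with an all-ones alter
#'   clique. Under this contract all-unrelated alters score 0 and a
#'   complete nuclear-family clique scores 1. Conventions: degree 1 gives
#'   constraint 1; for degree 2 the raw constraint is invariant to the
#'   single alter--alter tie, so the rescaled value is defined as that
#'   tie's weight (which meets both endpoints).
#' * **hierarchy** -- Coleman--Theil concentration of the dyadic
#'   constraints `c_j`: `sum_j (c_j/mean(c)) log(c_j/mean(c)) / (N log N)`;
#'   0 when all dyadic constraints are equal, and by convention 0 for
#'   degree 1.
#'
#' @param net An `ego_network` from [build_ego_network()].
#' @name structural-measures
NULL

# row-proportional tie strengths; zero rows stay zero
prop_matrix <- function(Z) {
  rs <- rowSums(Z)
  rs[rs == 0] <- 1
  Z / rs
}

#' @rdname structural-measures
#' @return `ego_degree()`: integer count of alters.
#' @export
ego_degree <- function(net) {
  nrow(net$alters)
}

#' @rdname structural-measures
#' @return `effective_size()`: numeric in \[1, degree\].
#' @export
effective_size <- function(net) {
  Z <- net$Z
  n <- nrow(Z) - 1
  if (n == 1) return(1)
  P <- prop_matrix(Z)
  mx <- apply(Z, 1, max)
  mx[mx == 0] <- 1
  M <- Z / mx
  # redundancy of alter j: sum_q p_iq * m_jq, q != i, j (diagonals are 0)
  red <- as.vector(M[-1, , drop = FALSE] %*% P[1, ])
  # clamp to the theoretical range; snap floating-point drift at the
  # endpoints so the printed contracts (clique -> 1, empty -> degree) are
  # exact
  es <- min(max(sum(1 - red), 1), n)
  if (abs(es - 1) < 1e-10) es <- 1
  if (abs(es - n) < 1e-10) es <- n
  es
}

# raw Burt aggregate constraint and its dyadic terms, ego = row 1
burt_constraint_raw <- function(Z) {
  n <- nrow(Z) - 1
  P <- prop_matrix(Z)
  ind <- as.vector(P[1, ] %*% P)        # sum_q p_iq p_qj (diagonals 0)
  c_j <- (P[1, -1] + ind[-1])^2
  list(C = sum(c_j), dyadic = c_j)
}

#' @rdname structural-measures
#' @return `burt_constraint()`: a list with `raw` (Burt's aggregate
#'   constraint) and `rescaled` (the \[0, 1\] per-degree affine rescaling).
#' @export
burt_constraint <- function(net) {
  Z <- net$Z
  n <- nrow(Z) - 1
  raw <- burt_constraint_raw(Z)$C
  if (n == 1) return(list(raw = raw, rescaled = 1))
  if (n == 2) {
    # raw constraint is blind to the single alter pair at degree 2
    return(list(raw = raw, rescaled = Z[2, 3]))
  }
  empty <- Z; empty[-1, -1] <- 0
  full <- Z; full[-1, -1] <- 1; diag(full) <- 0
  c0 <- burt_constraint_raw(empty)$C
  c1 <- burt_constraint_raw(full)$C
  resc <- (raw - c0) / (c1 - c0)
  list(raw = raw, rescaled = min(max(resc, 0), 1))
}

#' @rdname structural-measures
#' @return `ego_density()`: mean alter--alter weight in \[0, 1\] (0 for
#'   degree 1).
#' @export
ego_density <- function(net) {
  w <- net$Z[-1, -1, drop = FALSE]
  n <- nrow(w)
  if (n < 2) return(0)
  sum(w[upper.tri(w)]) / (n * (n - 1) / 2)
}

#' @rdname structural-measures
#' @return `ego_efficiency()`: effective size divided by degree, in (0, 1\].
#' @export
ego_efficiency <- function(net) {
  effective_size(net) / ego_degree(net)
}

#' @rdname structural-measures
#' @return `ego_hierarchy()`: Coleman--Theil concentration in \[0, 1\].
#' @export
ego_hierarchy <- function(net) {
  n <- nrow(net$Z) - 1
  if (n < 2) return(0)
  c_j <- burt_constraint_raw(net$Z)$dyadic
  ratio <- c_j / mean(c_j)
  sum(ratio * log(ratio)) / (n * log(n))
}

#' Dichotomise effective size
#'
#' Effective size is split at its cohort median of 3 into low (<= cutoff)
#' and high (> cutoff) kinship non-redundancy.
#'
#' @param es Numeric vector of effective sizes (>= 1).
#' @param cutoff Split point; default 3.
#' @return Factor with levels `low`, `high` (reference `low`).
#' @export
#' @examples
#' classify_effective_size(c(1, 3, 3.01))
classify_effective_size <- function(es, cutoff = 3) {
  stopifnot(all(es >= 1, na.rm = TRUE))
  factor(ifelse(es > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Structural metrics for every household
#'
#' Builds each household's ego network and computes the six structural
#' variables plus the effective-size dichotomy.
#'
#' @inheritParams ego_networks
#' @param es_cutoff Passed to [classify_effective_size()].
#' @return Tibble with one row per household: `household_id`, `degree`,
#'   `density`, `effective_size`, `efficiency`, `constraint_raw`,
#'   `constraint` (rescaled), `hierarchy`, `es_class`.
#' @export
#' @examples
#' svy <- simulate_survey(generator_config(n_households = 20, seed = 1))
#' structural_metrics(svy$rosters)
structural_metrics <- function(rosters, alters = c("de_jure", "de_facto"),
                               marriage_ties = FALSE, table = NULL,
                               es_cutoff = 3) {
  alters <- match.arg(alters)
  nets <- ego_networks(rosters, alters = alters,
                       marriage_ties = marriage_ties, table = table)
  out <- purrr::map(nets, function(net) {
    con <- burt_constraint(net)
    es <- effective_size(net)
    tibble::tibble(
      household_id = net$household_id,
      degree = ego_degree(net),
      density = ego_density(net),
      effective_size = es,
      efficiency = es / ego_degree(net),
      constraint_raw = con$raw,
      constraint = con$rescaled,
      hierarchy = ego_hierarchy(net))
  })
  out <- dplyr::bind_rows(out)
  out$es_class <- classify_effective_size(out$effective_size, es_cutoff)
  out
}

#' Reduce the structural variable set by principal components
#'
#' The six structural variables overlap (efficiency is effective size over
#' degree; density and constraint both track relatedness), so a principal
#' component analysis on their correlation matrix is used to choose a
#' representative subset: for each component with eigenvalue above 1
#' (Kaiser criterion) the variable with the highest absolute loading is
#' retained, ties broken by the fixed order of `vars`. Constant columns
#' are excluded with a warning. When no component passes the criterion
#' (uncorrelated inputs carry no structure to summarise), the retained
#' set falls back to the conventional trio
#' `c("degree", "effective_size", "constraint")`.
#'
#' @param metrics Tibble of per-household metrics ([structural_metrics()]).
#' @param vars Candidate columns, in tie-break priority order.
#' @return List with `retained` (character), `loadings` (matrix),
#'   `eigenvalues` (numeric) and `dropped_constant` (character).
#' @export
reduce_structural_set <- function(metrics,
                                  vars = c("degree", "effective_size",
                                           "constraint", "density",
                                           "efficiency", "hierarchy")) {
  x <- metrics[, intersect(vars, names(metrics)), drop = FALSE]
  if (ncol(x) < 3 || nrow(x) < 10) {
    stop("need at least 3 metric columns and 10 rows")
  }
  const <- vapply(x, function(v) sd(v) == 0, logical(1))
  if (any(const)) {
    warning("constant column(s) excluded: ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  keep_comp <- which(eig > 1 + 1e-8)
  fallback <- c("degree", "effective_size", "constraint")
  if (length(keep_comp) == 0) {
    retained <- intersect(fallback, names(x))
  } else {
    pri <- match(rownames(pc$rotation), vars)  # tie-break priority
    retained <- unique(vapply(keep_comp, function(k) {
      load <- abs(pc$rotation[, k])
      top <- which(load == max(load))
      rownames(pc$rotation)[top[order(pri[top])][1]]
    }, character(1)))
  }
  list(retained = retained, loadings = pc$rotation, eigenvalues = eig,
       dropped_constant = names(const)[const])
}
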