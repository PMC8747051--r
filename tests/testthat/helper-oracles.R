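# Independent brute-force oracles: literal summations over explicit loops,
# sharing no code with the package implementation.

# Burt effective size: ES = sum_j [1 - sum_q p_iq * m_jq], q != i, j
oracle_effective_size <- function(Z, ego = 1) {
  n <- nrow(Z)
  p <- function(a, b) {
    tot <- sum(Z[a, ] + Z[, a])
    if (tot == 0) 0 else (Z[a, b] + Z[b, a]) / tot
  }
  es <- 0
  for (j in setdiff(seq_len(n), ego)) {
    red <- 0
    for (q in setdiff(seq_len(n), c(ego, j))) {
      mjq <- if (max(Z[j, ]) == 0) 0 else Z[j, q] / max(Z[j, ])
      red <- red + p(ego, q) * mjq
    }
    es <- es + (1 - red)
  }
  es
}

# Burt aggregate constraint: C = sum_j (p_ij + sum_q p_iq p_qj)^2
oracle_constraint_raw <- function(Z, ego = 1) {
  n <- nrow(Z)
  p <- function(a, b) {
    tot <- sum(Z[a, ] + Z[, a])
    if (tot == 0) 0 else (Z[a, b] + Z[b, a]) / tot
  }
  C <- 0
  dyadic <- numeric(0)
  for (j in setdiff(seq_len(n), ego)) {
    ind <- 0
    for (q in setdiff(seq_len(n), c(ego, j))) ind <- ind + p(ego, q) * p(q, j)
    cj <- (p(ego, j) + ind)^2
    dyadic <- c(dyadic, cj)
    C <- C + cj
  }
  list(C = C, dyadic = dyadic)
}

# affine per-degree rescaling of constraint via the same literal oracle
oracle_constraint_rescaled <- function(Z, ego = 1) {
  n <- nrow(Z) - 1
  if (n == 1) return(1)
  if (n == 2) return(Z[setdiff(seq_len(3), ego)[1], setdiff(seq_len(3), ego)[2]])
  C <- oracle_constraint_raw(Z, ego)$C
  Ze <- Z; Ze[-ego, -ego] <- 0
  Zf <- Z; Zf[-ego, -ego] <- 1; diag(Zf) <- 0
  c0 <- oracle_constraint_raw(Ze, ego)$C
  c1 <- oracle_constraint_raw(Zf, ego)$C
  min(max((C - c0) / (c1 - c0), 0), 1)
}

# Coleman-Theil hierarchy from the dyadic constraints
oracle_hierarchy <- function(Z, ego = 1) {
  n <- nrow(Z) - 1
  if (n < 2) return(0)
  cj <- oracle_constraint_raw(Z, ego)$dyadic
  s <- 0
  for (c in cj) s <- s + (c / mean(cj)) * log(c / mean(cj))
  s / (n * log(n))
}

# IQV by explicit pair counting: ordered pairs (with replacement) that
# differ, normalised by the even-split maximum 1 - 1/K
oracle_iqv <- function(x, K) {
  x <- x[!is.na(x)]
  n <- length(x)
  diff_pairs <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (x[a] != x[b]) diff_pairs <- diff_pairs + 1
  }
  val <- (diff_pairs / n^2) / (1 - 1 / K)
  min(max(val, 0), 1)
}

# WHO IYCF rules restated independently
oracle_mdd <- function(flags, n_groups = 8) {
  if (any(is.na(flags))) return(NA)
  sum(flags) >= if (n_groups == 8) 5 else 4
}
oracle_mmf <- function(age, breastfed, feed, solid) {
  if (breastfed) {
    if (age >= 6 && age <= 8) feed >= 2 else feed >= 3
  } else {
    feed >= 4 && solid >= 1
  }
}

# a random weighted ego network: alter ties drawn from the normalised
# relatedness support {0, 0.25, 0.5, 1}
random_ego_network <- function(degree, p_tie = 0.5) {
  w <- matrix(0, degree, degree)
  if (degree > 1) {
    idx <- which(upper.tri(w))
    vals <- sample(c(0, 0.25, 0.5, 1), length(idx), replace = TRUE,
                   prob = c(1 - p_tie, p_tie / 4, p_tie / 4, p_tie / 2))
    w[idx] <- vals
    w <- w + t(w)
  }
  make_net(w)
}
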