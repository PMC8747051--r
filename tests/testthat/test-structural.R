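test_that("effective size hits its printed endpoints", {
  # complete clique: full redundancy, ES = 1 regardless of size
  for (n in 2:6) expect_equal(effective_size(make_net(matrix(1, n, n) - diag(n))), 1)
  # mutually unrelated alters: ES = degree
  expect_equal(effective_size(make_net(matrix(0, 4, 4))), 4)
  expect_equal(effective_size(make_net(matrix(0, 1, 1))), 1)
})

test_that("a partially tied network matches the literal-summation oracle", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1          # single tie, one isolate
  net <- make_net(w)
  expect_equal(effective_size(net), oracle_effective_size(net$Z))
  expect_equal(burt_constraint(net)$raw, oracle_constraint_raw(net$Z)$C)
})

test_that("rescaled constraint meets the 0/1 contract", {
  expect_equal(burt_constraint(build_ego_network(nuclear_roster()))$rescaled, 1)
  expect_equal(burt_constraint(make_net(matrix(0, 4, 4)))$rescaled, 0)
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 1
  mid <- burt_constraint(make_net(w))$rescaled
  expect_gt(mid, 0); expect_lt(mid, 1)
  expect_equal(mid, oracle_constraint_rescaled(make_net(w)$Z))
})

test_that("degenerate degrees follow the documented conventions", {
  one <- make_net(matrix(0, 1, 1))
  expect_equal(effective_size(one), 1)
  expect_equal(burt_constraint(one)$rescaled, 1)
  expect_equal(ego_hierarchy(one), 0)
  expect_equal(ego_density(one), 0)
  # degree 2: rescaled constraint is the single alter-alter tie weight
  w <- matrix(c(0, .5, .5, 0), 2)
  expect_equal(burt_constraint(make_net(w))$rescaled, 0.5)
})

test_that("density, efficiency and hierarchy behave at their anchors", {
  clique <- make_net(matrix(1, 4, 4) - diag(4))
  empty <- make_net(matrix(0, 4, 4))
  expect_equal(ego_density(clique), 1)
  expect_equal(ego_density(empty), 0)
  expect_equal(ego_efficiency(empty), 1)
  # symmetric networks have equal dyadic constraints, hence hierarchy 0
  expect_equal(ego_hierarchy(clique), 0)
  expect_equal(ego_hierarchy(empty), 0)
})

test_that("structural measures equal the brute-force oracles on random networks", {
  withr::with_seed(101, {
    for (i in 1:200) {
      net <- random_ego_network(sample(1:8, 1), p_tie = runif(1, 0.2, 0.9))
      expect_equal(effective_size(net), oracle_effective_size(net$Z),
                   tolerance = 1e-10)
      expect_equal(burt_constraint(net)$raw, oracle_constraint_raw(net$Z)$C,
                   tolerance = 1e-10)
      expect_equal(burt_constraint(net)$rescaled,
                   oracle_constraint_rescaled(net$Z), tolerance = 1e-10)
      expect_equal(ego_hierarchy(net), oracle_hierarchy(net$Z),
                   tolerance = 1e-10)
    }
  })
})

test_that("ego constraint agrees with igraph on weighted random networks", {
  skip_if_not_installed("igraph")
  withr::with_seed(7, {
    for (i in 1:25) {
      net <- random_ego_network(sample(2:7, 1), p_tie = 0.6)
      g <- igraph::graph_from_adjacency_matrix(net$Z, mode = "undirected",
                                               weighted = TRUE)
      expect_equal(unname(igraph::constraint(g)[1]), burt_constraint(net)$raw,
                   tolerance = 1e-8)
    }
  })
})

test_that("tightening kin ties raises constraint and lowers effective size", {
  withr::with_seed(31, {
    for (i in 1:60) {
      n <- sample(3:8, 1)
      net <- random_ego_network(n, p_tie = 0.4)
      w <- net$Z[-1, -1]
      open <- which(upper.tri(w) & w < 1, arr.ind = TRUE)
      if (nrow(open) == 0) next
      pick <- open[sample(nrow(open), 1), ]
      w2 <- w
      w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- 1
      net2 <- make_net(w2)
      expect_lte(effective_size(net2), effective_size(net) + 1e-12)
      expect_gte(burt_constraint(net2)$rescaled,
                 burt_constraint(net)$rescaled - 1e-12)
      expect_true(effective_size(net) >= 1 && effective_size(net) <= n)
      expect_true(dplyr::between(burt_constraint(net)$rescaled, 0, 1))
    }
  })
})

test_that("effective size dichotomises at the median cutoff of 3", {
  expect_equal(as.character(classify_effective_size(c(1, 3, 3.01, 5.2))),
               c("low", "low", "high", "high"))
  expect_equal(levels(classify_effective_size(2)), c("low", "high"))
  expect_equal(as.character(classify_effective_size(3.2, cutoff = 4)), "low")
})

test_that("PCA reduction drops algebraically redundant companions", {
  withr::with_seed(5, {
    sm <- structural_metrics(
      generate_households(generator_config(n_households = 250, seed = 5))$rosters)
  })
  red <- reduce_structural_set(sm)
  # efficiency = ES/degree: never retain the ratio with both its parents
  expect_false(all(c("efficiency", "effective_size", "degree") %in% red$retained))
  expect_true(length(red$retained) >= 1)
  expect_equal(ncol(red$loadings), length(red$eigenvalues))
})

test_that("PCA reduction falls back to the conventional trio without correlation structure", {
  withr::with_seed(8, {
    raw <- matrix(rnorm(60 * 6), 60, 6)
    # orthogonalise so the sample correlation is exactly the identity
    orth <- qr.Q(qr(scale(raw, scale = FALSE)))
  })
  x <- tibble::as_tibble(as.data.frame(orth))
  names(x) <- c("degree", "effective_size", "constraint", "density",
                "efficiency", "hierarchy")
  red <- reduce_structural_set(x)
  expect_setequal(red$retained, c("degree", "effective_size", "constraint"))
  expect_true(all(abs(red$eigenvalues - 1) < 1e-8))
})

test_that("constant metric columns are excluded with a warning", {
  x <- tibble::tibble(degree = rnorm(20), effective_size = rnorm(20),
                      constraint = rnorm(20), density = 1)
  expect_warning(red <- reduce_structural_set(x), "density")
  expect_false("density" %in% rownames(red$loadings))
})
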