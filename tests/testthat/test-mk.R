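test_that("Newick round-trips preserve topology, lengths and polytomies", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_equal(ape::Ntip(tr), 2)
  expect_setequal(tr$tip.label, c("A", "B"))
  rt <- read_newick(write_newick(tr))
  expect_equal(ape::Ntip(rt), 2)
  expect_equal(sort(rt$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)

  poly <- read_newick("(A:1,B:1,C:1):0;")
  expect_equal(poly$Nnode, 1)
  expect_equal(read_newick(write_newick(poly))$Nnode, 1)

  expect_error(read_newick("(A:1,B:1"), class = "parse_error")
})

test_that("transition matrix has the closed form and matches expm", {
  expect_equal(mk_transition_matrix(0.3, 0.7, 0), diag(2))
  expect_equal(mk_transition_matrix(0, 0, 5), diag(2))
  r <- 0.4; t <- 1.3
  expect_equal(mk_transition_matrix(r, r, t)[1, 1],
               0.5 + 0.5 * exp(-2 * r * t), tolerance = 1e-14)
  set.seed(8)
  for (i in 1:50) {
    q01 <- runif(1, 0, 2); q10 <- runif(1, 0, 2); t <- runif(1, 0, 10)
    P <- mk_transition_matrix(q01, q10, t)
    expect_equal(P, expm_P(q01, q10, t), tolerance = 1e-12)
    expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_error(mk_transition_matrix(-1, 0, 1), class = "invalid_argument")
})

test_that("two-tip likelihood matches the closed form", {
  tr <- read_newick("(A:1.5,B:0.7);")
  mod <- partition_model(tr, rates = c(0.2, 0.4))
  states <- c(A = 0, B = 0)
  pi1 <- 0.2 / 0.6
  P1 <- expm_P(0.2, 0.4, 1.5); P2 <- expm_P(0.2, 0.4, 0.7)
  L <- (1 - pi1) * P1[1, 1] * P2[1, 1] + pi1 * P1[2, 1] * P2[2, 1]
  expect_equal(tree_loglik(tr, states, mod), log(L), tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(3:5, 1)
    tr <- random_binary_tree(n)
    states <- stats::setNames(sample(0:1, n, replace = TRUE),
                              tr$tip.label)
    q01 <- runif(1, 0.05, 1); q10 <- runif(1, 0.05, 1)
    mod <- partition_model(tr, rates = c(q01, q10))
    pi1 <- q01 / (q01 + q10)
    expect_equal(tree_loglik(tr, states, mod),
                 enum_loglik(tr, states, q01, q10, c(1 - pi1, pi1)),
                 tolerance = 1e-10)
    # fixed root prior route
    expect_equal(tree_loglik(tr, states, mod, root = "fixed",
                             root_p1 = 0.05),
                 enum_loglik(tr, states, q01, q10, c(0.95, 0.05)),
                 tolerance = 1e-10)
  }
})

test_that("likelihood limits and invariances hold", {
  tr <- random_binary_tree(6)
  states <- stats::setNames(rep(0, 6), tr$tip.label)
  mod <- partition_model(tr, rates = c(0, 0))
  expect_equal(tree_loglik(tr, states, mod, root = "fixed", root_p1 = 0),
               0, tolerance = 1e-12)

  # invariance to tip enumeration order
  set.seed(31)
  st <- stats::setNames(sample(0:1, 6, replace = TRUE), tr$tip.label)
  mod2 <- partition_model(tr, rates = c(0.3, 0.6))
  expect_equal(tree_loglik(tr, st, mod2),
               tree_loglik(tr, st[sample(names(st))], mod2),
               tolerance = 1e-14)

  # rerooting along the root edge is neutral under the stationary prior
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick("((A:1,B:1):1.6,(C:1,D:1):0.4);")
  stx <- c(A = 1, B = 0, C = 0, D = 1)
  expect_equal(tree_loglik(t1, stx, partition_model(t1, rates = c(0.3, 0.5))),
               tree_loglik(t2, stx, partition_model(t2, rates = c(0.3, 0.5))),
               tolerance = 1e-10)
})

test_that("ML rates hit bounds and dominate the truth in likelihood", {
  tr <- simulate_yule_tree(80, 0.15, seed = 41)
  all0 <- stats::setNames(rep(0, 80), tr$tip.label)
  fit0 <- fit_rates_ml(tr, all0, partition_model(tr))
  expect_lte(fit0$rates[1, 1], 1e-7)

  for (i in 1:5) {
    sim <- simulate_discrete_history(
      tr, partition_model(tr, rates = c(0.05, 0.1)), 0, seed = 50 + i)
    if (length(unique(sim$states)) < 2) next
    fit <- fit_rates_ml(tr, sim$states, partition_model(tr))
    truth <- partition_model(tr, rates = c(0.05, 0.1))
    expect_gte(attr(fit, "loglik") + 1e-8,
               tree_loglik(tr, sim$states, truth))
  }
})

test_that("whole-tree symmetric rate agrees with a constrained oracle", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(60, 0.15, seed = 61)
  sim <- simulate_discrete_history(
    tr, partition_model(tr, rates = c(0.04, 0.04)), 0.5, seed = 62)
  r <- whole_tree_symmetric_rate(tr, sim$states)
  fm <- phytools::fitMk(tr, stats::setNames(as.character(sim$states),
                                            names(sim$states)),
                        model = "ER", pi = c(0.5, 0.5))
  expect_equal(r, unname(fm$rates[1]), tolerance = 1e-4)
})

test_that("Fitch parsimony matches enumeration and known cases", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_parsimony(tr, c(A = 0, B = 0, C = 0, D = 0))$changes,
               0)
  expect_equal(fitch_parsimony(tr, c(A = 1, B = 1, C = 0, D = 0))$changes,
               1)
  set.seed(71)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    trr <- ape::rtree(n)
    if (i %% 3 == 0) trr <- ape::di2multi(trr, tol = 0.5) # polytomies too
    states <- stats::setNames(sample(0:1, n, replace = TRUE),
                              trr$tip.label)
    f <- fitch_parsimony(trr, states)
    expect_equal(f$changes, enum_parsimony(trr, states))
    # the returned labelling achieves the minimal count
    ns <- f$node_states
    realized <- sum(ns[trr$edge[, 1]] != ns[trr$edge[, 2]])
    expect_equal(realized, f$changes)
  }
})

test_that("Fitch count lower-bounds the true simulated change count", {
  for (i in 1:10) {
    tr <- simulate_yule_tree(30, 0.25, seed = 80 + i)
    sim <- simulate_discrete_history(
      tr, partition_model(tr, rates = c(0.08, 0.15)), 0.3, seed = 90 + i)
    expect_lte(fitch_parsimony(tr, sim$states)$changes,
               nrow(sim$map$events))
  }
})
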