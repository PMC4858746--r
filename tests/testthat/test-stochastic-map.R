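test_that("sampled maps always reproduce the observed tip states", {
  tr <- simulate_yule_tree(30, 0.2, seed = 1)
  sim <- simulate_discrete_history(
    tr, partition_model(tr, rates = c(0.05, 0.1)), 0, seed = 2)
  mod <- partition_model(tr, rates = c(0.06, 0.12))
  for (i in 1:10) {
    m <- sample_stochastic_map(tr, sim$states, mod, seed = 10 + i)
    expect_identical(unname(map_tip_states(m)), unname(sim$states))
    expect_true(validate_character_map(m, tr))
  }
})

test_that("irreversible rates produce only gains", {
  tr <- simulate_yule_tree(25, 0.2, seed = 3)
  gen <- partition_model(tr, rates = c(0.3, 0))
  sim <- simulate_discrete_history(tr, gen, 0, seed = 4)
  for (i in 1:5) {
    m <- sample_stochastic_map(tr, sim$states, gen,
                               root = "fixed", root_p1 = 0, seed = 20 + i)
    expect_true(all(m$events$to_state == 1L))
  }
})

test_that("per-branch parity links event counts to endpoint states", {
  tr <- simulate_yule_tree(30, 0.2, seed = 5)
  sim <- simulate_discrete_history(
    tr, partition_model(tr, rates = c(0.1, 0.2)), 0.5, seed = 6)
  mod <- partition_model(tr, rates = c(0.1, 0.2))
  ens <- sample_map_ensemble(tr, sim$states, mod, n_maps = 30, seed = 7)
  for (m in ens$maps) {
    cnt <- mimicry:::map_event_counts(m, nrow(tr$edge))
    parity <- m$node_states[tr$edge[, 2]] - m$node_states[tr$edge[, 1]]
    expect_equal(cnt$gains - cnt$losses, parity)
  }
})

test_that("endpoint-conditioned event counts match the analytic oracle", {
  cases <- list(c(0.3, 0.2, 2, 0, 0), c(0.3, 0.2, 2, 0, 1),
                c(0.8, 0.1, 1.5, 1, 0))
  for (cs in cases) {
    q01 <- cs[1]; q10 <- cs[2]; t <- cs[3]; a <- cs[4]; b <- cs[5]
    n_draw <- 4000
    counts <- mimicry:::with_seed(99, vapply(seq_len(n_draw), function(i)
      length(mimicry:::sample_ctmc_path(q01, q10, t, a, b)$time),
      numeric(1)))
    expected <- cond_expected_events(q01, q10, t, a, b)
    se <- stats::sd(counts) / sqrt(n_draw)
    expect_lt(abs(mean(counts) - expected), 3 * se)
  }
})

test_that("frequency-through-time is anchored at tips and consistent", {
  tr <- simulate_yule_tree(40, 0.2, seed = 8)
  sim <- simulate_discrete_history(
    tr, partition_model(tr, rates = c(0.05, 0.08)), 0, seed = 9)
  mod <- fit_rates_ml(tr, sim$states, partition_model(tr))
  ens <- sample_map_ensemble(tr, sim$states, mod, n_maps = 40, seed = 10)
  s1 <- summarize_ensemble(ens, n_time = 101)
  expect_equal(nrow(s1$freq_through_time), 101)
  expect_equal(s1$freq_through_time$freq1[101], mean(sim$states == 1))
  # doubling the grid leaves shared time points unchanged
  s2 <- summarize_ensemble(ens, n_time = 201)
  shared <- seq(1, 201, by = 2)
  expect_equal(s2$freq_through_time$freq1[shared],
               s1$freq_through_time$freq1, tolerance = 1e-12)
  # per-map totals are bookkept
  expect_equal(nrow(s1$per_map), 40)
  expect_true(s1$credible_index %in% seq_len(40))
  expect_identical(s1$credible_map, ens$maps[[s1$credible_index]])
})

test_that("root-state marginal matches the analytic root posterior", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = 1, B = 0, C = 0, D = 0)
  mod <- partition_model(tr, rates = c(0.3, 0.4))
  pr <- mimicry:::tree_partials(tr, states, mod, root = "stationary")
  rootnode <- 5
  pi1 <- 0.3 / 0.7
  w <- c(1 - pi1, pi1) * pr$partials[rootnode, ]
  p1 <- w[2] / sum(w)
  n_map <- 600
  ens <- sample_map_ensemble(tr, states, mod, n_maps = n_map, seed = 11)
  roots <- vapply(ens$maps, function(m) m$node_states[rootnode],
                  integer(1))
  se <- sqrt(p1 * (1 - p1) / n_map)
  expect_lt(abs(mean(roots) - p1), 3 * se)
})

test_that("ensemble mean event count approaches the posterior expectation", {
  # tiny tree, fixed rates: expected total events = sum over branches of
  # the endpoint-marginalized conditional expectation
  tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
  states <- c(A = 1, B = 0, C = 0)
  mod <- partition_model(tr, rates = c(0.4, 0.3))
  n_map <- 800
  ens <- sample_map_ensemble(tr, states, mod, n_maps = n_map, seed = 12)
  totals <- vapply(ens$maps, function(m) nrow(m$events), numeric(1))
  # oracle: enumerate joint node states with pruning-free arithmetic
  pi1 <- 0.4 / 0.7
  exp_total <- 0; norm <- 0
  for (root_s in 0:1) for (int_s in 0:1) {
    p <- c(1 - pi1, pi1)[root_s + 1] *
      expm_P(0.4, 0.3, 0.5)[root_s + 1, int_s + 1] *
      expm_P(0.4, 0.3, 1)[int_s + 1, states[["A"]] + 1] *
      expm_P(0.4, 0.3, 1)[int_s + 1, states[["B"]] + 1] *
      expm_P(0.4, 0.3, 1.5)[root_s + 1, states[["C"]] + 1]
    ev <- cond_expected_events(0.4, 0.3, 0.5, root_s, int_s) +
      cond_expected_events(0.4, 0.3, 1, int_s, states[["A"]]) +
      cond_expected_events(0.4, 0.3, 1, int_s, states[["B"]]) +
      cond_expected_events(0.4, 0.3, 1.5, root_s, states[["C"]])
    exp_total <- exp_total + p * ev
    norm <- norm + p
  }
  exp_total <- exp_total / norm
  se <- stats::sd(totals) / sqrt(n_map)
  expect_lt(abs(mean(totals) - exp_total), 3 * se)
})
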