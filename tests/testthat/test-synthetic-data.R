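test_that("Yule trees have the right shape and are seed-reproducible", {
  tr2 <- simulate_yule_tree(2, 0.5, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(ape::Ntip(tr2) + tr2$Nnode, 3)

  tr <- simulate_yule_tree(50, 0.2, seed = 2)
  expect_equal(ape::Ntip(tr) + tr$Nnode, 99)
  expect_equal(nrow(tr$edge), 98)
  expect_true(ape::is.binary(tr))
  expect_true(all(tr$edge.length > 0))

  expect_identical(write_newick(simulate_yule_tree(20, 0.1, seed = 7)),
                   write_newick(simulate_yule_tree(20, 0.1, seed = 7)))
  expect_false(identical(
    write_newick(simulate_yule_tree(20, 0.1, seed = 7)),
    write_newick(simulate_yule_tree(20, 0.1, seed = 8))))
  expect_error(simulate_yule_tree(1, 0.1, seed = 1),
               class = "invalid_argument")
})

test_that("discrete histories honor degenerate rate limits", {
  tr <- simulate_yule_tree(30, 0.2, seed = 3)
  h0 <- simulate_discrete_history(tr, partition_model(tr, rates = c(0, 0)),
                                  root_state_prob = 0, seed = 4)
  expect_true(all(h0$states == 0))
  expect_equal(nrow(h0$map$events), 0)

  habs <- simulate_discrete_history(
    tr, partition_model(tr, rates = c(50, 0)), 0, seed = 5)
  expect_true(all(habs$states == 1))
  expect_true(all(habs$map$events$to_state == 1))
})

test_that("event count at stationarity matches rate x tree length", {
  tr <- simulate_yule_tree(40, 0.2, seed = 6)
  r <- 0.05
  mod <- partition_model(tr, rates = c(r, r))
  n_rep <- 1000
  counts <- vapply(seq_len(n_rep), function(i)
    nrow(simulate_discrete_history(tr, mod, 0.5, seed = 1000 + i)
         $map$events), numeric(1))
  expected <- r * sum(tr$edge.length)
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("tip frequency converges to the stationary frequency", {
  st <- star_tree(1000, 200)
  mod <- partition_model(st, rates = c(0.04, 0.06))
  h <- simulate_discrete_history(st, mod, 0, seed = 11)
  p1 <- 0.04 / 0.10
  se <- sqrt(p1 * (1 - p1) / 1000)
  expect_lt(abs(mean(h$states) - p1), 3 * se)
})

test_that("simulated character maps always validate", {
  for (i in 1:15) {
    tr <- simulate_yule_tree(25, 0.3, seed = 40 + i)
    mod <- partition_model(tr, rates = c(0.1, 0.2))
    h <- simulate_discrete_history(tr, mod, 0.3, seed = 70 + i)
    expect_true(validate_character_map(h$map, tr))
    expect_identical(unname(map_tip_states(h$map)), unname(h$states))
  }
})

test_that("Brownian latitudes match the BM variance and covariance", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  z <- simulate_bm_latitude(tr, root_value = 5, sigma2 = 0, seed = 1)
  expect_true(all(z$tip_latitudes == 5))
  expect_error(simulate_bm_latitude(tr, 0, -1, seed = 1),
               class = "invalid_argument")

  s2 <- 2.5
  reps <- vapply(seq_len(1000), function(i) {
    v <- simulate_bm_latitude(tr, 0, s2, seed = 2000 + i)$tip_latitudes
    c(v[["A"]], v[["B"]])
  }, numeric(2))
  # tip variance = s2 * depth(2); sister covariance = s2 * shared path (1)
  expect_equal(stats::var(reps[1, ]), s2 * 2, tolerance = 0.15)
  expect_equal(stats::cov(reps[1, ], reps[2, ]), s2 * 1, tolerance = 0.2)
})

test_that("virtual biogeography is contained, tagged and reproducible", {
  sim <- simulate_virtual_biogeography(n_model = 5, n_other = 8,
                                       b_model = 1, n_mimic = 10,
                                       seed = 21)
  pts <- cbind(sim$occurrences$lon, sim$occurrences$lat)
  expect_true(all(mimicry:::point_in_mosaic(pts, sim$continent,
                                            tol = 1e-6)))
  expect_setequal(unique(sim$species$tag), c("model", "other", "mimic"))
  expect_false(any(duplicated(sim$species$species)))

  sim2 <- simulate_virtual_biogeography(n_model = 5, n_other = 8,
                                        b_model = 1, n_mimic = 10,
                                        seed = 21)
  expect_identical(sim$occurrences, sim2$occurrences)
  expect_error(
    simulate_virtual_biogeography(continent = cbind(c(0, 5, 5, 0),
                                                    c(0, 0, 5, 5)),
                                  seed = 1),
    class = "generation_failure")
})
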