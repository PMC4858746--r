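test_that("BM ancestral estimates match symmetry cases and oracles", {
  t2 <- read_newick("(A:1,B:1);")
  a2 <- bm_ancestral_latitudes(t2, c(A = 10, B = 20))
  expect_equal(unname(a2$node_latitudes), 15)

  st <- star_tree(6, 2)
  vals <- stats::setNames(c(3, 5, 7, 9, 11, 13), st$tip.label)
  expect_equal(unname(bm_ancestral_latitudes(st, vals)$node_latitudes),
               mean(vals))

  skip_if_not_installed("phytools")
  set.seed(2)
  for (i in 1:5) {
    tr <- random_binary_tree(sample(5:8, 1))
    y <- stats::setNames(rnorm(ape::Ntip(tr), 0, 10), tr$tip.label)
    mine <- bm_ancestral_latitudes(tr, y)$node_latitudes
    fa <- phytools::fastAnc(tr, y)
    expect_equal(unname(mine), unname(as.numeric(fa)), tolerance = 1e-6)
    # brute-force restricted-likelihood maximization over node values
    obj <- function(v) {
      all <- c(unname(y[tr$tip.label]), v)
      sum((all[tr$edge[, 1]] - all[tr$edge[, 2]])^2 / tr$edge.length)
    }
    opt <- stats::optim(rep(mean(y), tr$Nnode), obj, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 2000))
    expect_equal(unname(mine), opt$par, tolerance = 1e-6)
  }
})

test_that("event latitude interpolation follows the delta convention", {
  expect_equal(interpolate_event_latitude(10, 20, 0.5), 15)
  expect_equal(interpolate_event_latitude(10, 20, 0.1), 11)
  expect_equal(interpolate_event_latitude(10, 20, 0), 10)
  expect_equal(interpolate_event_latitude(10, 20, 1), 20)
  # exact-linear symmetry: swapping endpoints and delta -> 1 - delta
  expect_equal(interpolate_event_latitude(10, 20, 0.3),
               interpolate_event_latitude(20, 10, 0.7))
  expect_error(interpolate_event_latitude(0, 1, 1.2),
               class = "invalid_argument")
})

make_small_ensemble <- function(seed = 5) {
  tr <- simulate_yule_tree(30, 0.2, seed = seed)
  sim <- simulate_discrete_history(
    tr, partition_model(tr, rates = c(0.08, 0.15)), 0.5, seed = seed + 1)
  mod <- partition_model(tr, rates = c(0.08, 0.15))
  ens <- sample_map_ensemble(tr, sim$states, mod, n_maps = 25,
                             seed = seed + 2)
  lat <- simulate_bm_latitude(tr, 0, 20, seed = seed + 3)
  list(tr = tr, ens = ens, lat = lat)
}

test_that("locate_events conserves counts and bounds latitudes", {
  x <- make_small_ensemble()
  anc <- bm_ancestral_latitudes(x$tr, x$lat$tip_latitudes)
  ev <- locate_events(x$ens, anc$all)
  expect_equal(nrow(ev),
               sum(vapply(x$ens$maps, function(m) nrow(m$events),
                          numeric(1))))
  lo <- pmin(ev$parent_lat, ev$child_lat)
  hi <- pmax(ev$parent_lat, ev$child_lat)
  expect_true(all(ev$latitude >= lo - 1e-12 & ev$latitude <= hi + 1e-12))
  expect_true(all(ev$delta >= 0 & ev$delta <= 1))
  expect_true(all(ev$age_mya >= -1e-9))

  # degenerate interpolation: equal endpoints pin the latitude
  flat <- rep(7, ape::Ntip(x$tr) + x$tr$Nnode)
  ev2 <- locate_events(x$ens, flat)
  expect_true(all(ev2$latitude == 7))

  # empty ensemble region
  empty_map <- character_map(x$tr,
                             rep(0L, ape::Ntip(x$tr) + x$tr$Nnode),
                             tibble::tibble(edge = integer(0),
                                            time = numeric(0),
                                            to_state = integer(0)))
  ev3 <- locate_events(list(maps = list(empty_map), tree = x$tr),
                       anc$all)
  expect_equal(nrow(ev3), 0)
})

test_that("event latitude KDE normalizes and mirrors symmetric data", {
  ev <- tibble::tibble(type = "loss",
                       latitude = c(-20, -10, -5, 5, 10, 20))
  d <- event_latitude_density(ev, "loss")
  expect_equal(trapz(d$latitude, d$density), 1, tolerance = 1e-3)
  mirror <- stats::approx(d$latitude, d$density, xout = -d$latitude)$y
  expect_equal(d$density, mirror, tolerance = 1e-6)
  single <- event_latitude_density(
    tibble::tibble(type = "gain", latitude = 0), "gain", bandwidth = 2)
  expect_equal(single$latitude[which.max(single$density)], 0,
               tolerance = 0.1)
  expect_error(event_latitude_density(ev, "gain"),
               class = "empty_density")
})

test_that("time x latitude grid scales jointly to one and conserves", {
  ev <- tibble::tibble(
    type = c(rep("gain", 6), rep("loss", 3)),
    latitude = c(-10, -10, 5, 5, 5, 30, -15, -15, 28),
    age_mya = c(2, 2, 8, 8, 8, 2, 12, 12, 18))
  g <- time_latitude_grid(ev, n_maps = 3,
                          time_breaks = c(0, 10, 20),
                          lat_breaks = c(-23, 0, 23, 35))
  expect_equal(max(c(g$gain, g$loss)), 1)
  un <- attr(g, "unscaled")
  expect_equal(sum(un$gain) * 3, 6)
  expect_equal(sum(un$loss) * 3, 3)
})

test_that("zone loss ratio handles planted, equal and degenerate cases", {
  mk_ev <- function(lats) tibble::tibble(type = "loss", latitude = lats)
  eq <- zone_loss_ratio(mk_ev(c(0, 10, 25, 30)), n_maps = 2)
  expect_equal(eq$ratio, 1)
  none <- zone_loss_ratio(mk_ev(c(0, 0)), n_maps = 1)
  expect_true(none$undefined)
  expect_true(is.na(none$ratio))
  # planted 3:1 tropical excess
  set.seed(9)
  lats <- c(runif(600, -20, 20), runif(200, 24, 34))
  r3 <- zone_loss_ratio(mk_ev(lats), n_maps = 50)
  expect_gt(r3$ratio, 2.5)
  expect_lt(r3$ratio, 3.5)
})

test_that("contrast variance detects latitudinal conservatism", {
  sub <- function(p) paste0("(", paste0(p, 1:8, ":1", collapse = ","), ")")
  tr <- read_newick(paste0("(", sub("a"), ":10,", sub("b"), ":10);"))
  lat <- mimicry:::with_seed(42,
    stats::setNames(c(rnorm(8, 20, 0.5), rnorm(8, -20, 0.5)),
                    tr$tip.label))
  res <- suppressWarnings(
    pic_conservatism(tr, lat, n_perm = 199, seed = 1))
  expect_lt(res$z, -3)
  expect_lt(res$p, 0.05)
  expect_error(
    pic_conservatism(tr, stats::setNames(rep(1, 16), tr$tip.label),
                     n_perm = 99),
    class = "zero_variance")
})

test_that("pre-permuted latitudes give null z scores", {
  ok <- 0
  for (i in 1:50) {
    tr <- simulate_yule_tree(25, 0.3, seed = 500 + i)
    lat <- mimicry:::with_seed(600 + i,
      stats::setNames(rnorm(25, 0, 10), tr$tip.label))
    z <- pic_conservatism(tr, lat, n_perm = 199, seed = 700 + i)$z
    ok <- ok + (abs(z) < 2)
  }
  expect_gte(ok, 45)
})

test_that("two-tip contrast test is flagged degenerate", {
  t2 <- read_newick("(A:1,B:1);")
  res <- pic_conservatism(t2, c(A = 3, B = 9), n_perm = 99, seed = 1)
  expect_true(res$degenerate)
  expect_true(is.na(res$z))
})
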