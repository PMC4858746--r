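test_that("neighbour weights respect threshold, style and feasibility", {
  cells <- tibble::tibble(x = c(0, 0), y = c(0, 0.9)) # ~100 km apart
  w <- build_neighbor_weights(cells, 150, "binary")
  expect_equal(w$W, matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(build_neighbor_weights(cells, 50, "binary"),
               class = "infeasible_threshold")
  expect_equal(min_feasible_threshold(cells),
               mimicry:::haversine_km(0, 0, 0, 0.9))
})

test_that("inverse-distance weights match an independent haversine", {
  skip_if_not_installed("geosphere")
  set.seed(4)
  cells <- tibble::tibble(x = runif(8, -70, -60), y = runif(8, -10, 10))
  w <- build_neighbor_weights(cells, 2000, "inverse",
                              row_standardize = FALSE)
  for (i in 1:8) for (j in 1:8) {
    if (i == j || w$W[i, j] == 0) next
    d <- geosphere::distHaversine(c(cells$x[i], cells$y[i]),
                                  c(cells$x[j], cells$y[j]),
                                  r = 6371000) / 1000
    expect_equal(w$W[i, j], 1 / d, tolerance = 1e-9)
  }
})

make_cells <- function(nx, ny, spacing = 1) {
  tibble::tibble(x = rep(seq_len(nx) * spacing, times = ny),
                 y = rep(seq_len(ny) * spacing, each = nx))
}

test_that("SAR error model reduces to OLS when lambda = 0", {
  set.seed(11)
  cells <- make_cells(8, 8)
  X <- cbind(a = rnorm(64), b = rnorm(64))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(64, 0, 0.3)
  w <- build_neighbor_weights(cells, 160, "binary")
  fit <- fit_sar_error(y, X, w)
  ols <- stats::coef(stats::lm(y ~ X))
  expect_lt(max(abs(fit$coefficients - ols)), 1e-2)
  expect_lt(abs(fit$lambda), 0.35)
})

test_that("noise-free data give exact coefficients", {
  cells <- make_cells(6, 6)
  set.seed(12)
  X <- cbind(a = rnorm(36))
  y <- 2 + 3 * X[, 1]
  w <- build_neighbor_weights(cells, 160, "binary")
  fit <- fit_sar_error(y, X, w)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-8)
})

test_that("collinear predictors are rejected", {
  cells <- make_cells(4, 4)
  X <- cbind(a = rep(1, 16), b = rep(2, 16))
  w <- build_neighbor_weights(cells, 160, "binary")
  expect_error(fit_sar_error(rnorm(16), X, w),
               class = "invalid_argument")
})

test_that("Moran's I sign matches spatial pattern and errors when undefined", {
  cells <- make_cells(4, 4)
  w <- build_neighbor_weights(cells, 112, "binary") # rook neighbours
  checker <- (-1)^(outer(1:4, 1:4, `+`))
  mi <- morans_i(as.vector(checker), w, n_perm = 199, seed = 1)
  expect_lt(mi$I, mi$expectation)
  # direct-formula oracle
  z <- as.vector(checker) - mean(checker)
  I_direct <- (16 / sum(w$W)) * as.numeric(z %*% w$W %*% z) / sum(z^2)
  expect_equal(mi$I, I_direct, tolerance = 1e-12)

  grad <- morans_i(cells$x + cells$y, w, n_perm = 199, seed = 1)
  expect_gt(grad$I, 0)
  expect_lt(grad$p, 0.05)
  expect_error(morans_i(rep(1, 16), w), class = "undefined_statistic")
})

test_that("Moran permutation p is uniform under iid noise", {
  cells <- make_cells(4, 4)
  w <- build_neighbor_weights(cells, 112, "binary")
  ps <- vapply(1:100, function(i) {
    x <- withr::with_seed(2000 + i, rnorm(16))
    morans_i(x, w, n_perm = 99, seed = i)$p
  }, numeric(1))
  # permutation p values are discrete, so KS ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("neighbourhood selection equals exhaustive enumeration", {
  set.seed(13)
  cells <- make_cells(6, 6)
  X <- cbind(a = rnorm(36))
  y <- 1 + X[, 1] + rnorm(36, 0, 0.5)
  sel <- select_neighborhood(y, X, cells, step_km = 50, n_steps = 3)
  expect_equal(nrow(sel$aic_table), 3 * 3)
  best_row <- sel$aic_table[which.min(sel$aic_table$AIC), ]
  expect_equal(sel$threshold_km, best_row$threshold_km)
  expect_equal(sel$style, best_row$style)
  # brute-force re-fit of the winning candidate reproduces the AIC
  w <- build_neighbor_weights(cells, sel$threshold_km, sel$style)
  expect_equal(fit_sar_error(y, X, w)$AIC, sel$fit$AIC,
               tolerance = 1e-10)
})

test_that("residual z follows the chi-squared-framework formula", {
  expect_equal(residual_z(12, 9), 1.0)
  expect_equal(residual_z(5, 5), 0.0)
  expect_equal(residual_z(0, 4), -2.0)
  expect_true(is.na(residual_z(3, 0)))
  expect_equal(residual_z(6, 4, null_sd = 1, denominator = "sd"), 2)
  expect_error(residual_z(-1, 2), class = "invalid_argument")
})
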