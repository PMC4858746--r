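coast44 <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))

range_rect <- function(x0, x1, y0, y1) {
  mimicry:::as_mosaic(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

test_that("presence requires >= 50% cell coverage, inclusive", {
  grid <- make_grid(coast44, resolution = 1)
  ranges <- tibble::tibble(
    species = c("half", "under", "over"),
    geometry = list(range_rect(0, 0.5, 0, 1),     # exactly 50% of cell 1
                    range_rect(0, 0.499, 1, 2),   # 49.9%
                    range_rect(0, 2, 2, 4)))      # four full cells
  pres <- rasterize_presence(ranges, grid)
  cell <- function(x, y) which(pres$x == x & pres$y == y)
  expect_equal(pres$half[cell(0.5, 0.5)], 1L)
  expect_equal(sum(pres$half, na.rm = TRUE), 1)
  expect_equal(sum(pres$under, na.rm = TRUE), 0)
  expect_equal(sum(pres$over, na.rm = TRUE), 4)
})

test_that("richness is additive over disjoint species sets", {
  grid <- make_grid(coast44, resolution = 2)
  set.seed(1)
  mk <- function(i) range_rect(runif(1, 0, 2), runif(1, 2, 4),
                               runif(1, 0, 2), runif(1, 2, 4))
  ranges <- tibble::tibble(species = paste0("s", 1:6),
                           geometry = lapply(1:6, mk))
  pres <- rasterize_presence(ranges, grid)
  tags_a <- tibble::tibble(species = paste0("s", 1:6),
                           tag = rep(c("m1", "m2"), each = 3))
  rt <- richness_table(pres, tags_a)
  expect_equal(rt$m1 + rt$m2, rt$total)
})

test_that("rasterization is monotone in range size", {
  grid <- make_grid(coast44, resolution = 1)
  small <- range_rect(0.2, 1.8, 0.2, 1.8)
  big <- range_rect(0.1, 2.9, 0.1, 2.9)
  p <- rasterize_presence(tibble::tibble(species = c("small", "big"),
                                         geometry = list(small, big)),
                          grid)
  expect_true(all(p$big[which(p$small == 1)] == 1))
})

test_that("abundance counting is half-open and conservative", {
  grid <- make_grid(coast44, resolution = 1)
  occ <- tibble::tibble(
    species = c("a", "a", "a", "b"),
    lon = c(0.5, 1, 2.5, 3.999), # 1 sits exactly on a cell boundary
    lat = c(0.5, 1, 2.5, 0.001))
  tags <- tibble::tibble(species = c("a", "b"), tag = c("mimic", "model"))
  ab <- abundance_rasters(occ, grid, tags)
  expect_equal(sum(ab$total, na.rm = TRUE), 4)
  expect_equal(sum(ab$mimic, na.rm = TRUE), 3)
  # the boundary record went to exactly one cell
  expect_equal(max(ab$mimic, na.rm = TRUE), 1)
  one <- abundance_rasters(occ[1, ], grid, tags[1, ])
  expect_equal(sum(one$total, na.rm = TRUE), 1)
  expect_equal(sum(one$total > 0, na.rm = TRUE), 1)
})

test_that("log2 mimic/model ratio uses the +1 pseudocount", {
  expect_equal(log2_mimic_model_ratio(3, 1), 1.0)
  expect_equal(log2_mimic_model_ratio(0, 0), 0.0)
  expect_equal(log2_mimic_model_ratio(1, 7), -2.0)
  expect_error(log2_mimic_model_ratio(c(1, 2), 1),
               class = "invalid_argument")
  expect_error(log2_mimic_model_ratio(-1, 1), class = "invalid_argument")
})

test_that("subset_cells filters by occupancy and projects counts", {
  grid <- make_grid(coast44, resolution = 2)
  ranges <- tibble::tibble(
    species = c("m1", "c1"),
    geometry = list(range_rect(0, 2, 0, 2), range_rect(2, 4, 2, 4)))
  pres <- rasterize_presence(ranges, grid)
  tags <- tibble::tibble(species = c("m1", "c1"),
                         tag = c("mimic", "model"))
  rt <- richness_table(pres, tags)
  sm <- subset_cells(rt, "mimic")
  expect_equal(nrow(sm), 1)
  expect_equal(sm$mimic, 1)
  expect_equal(sm$model, 0)
  none <- richness_table(pres, tibble::tibble(
    species = c("m1", "c1"), tag = c("other", "model")))
  none$mimic <- 0
  expect_equal(nrow(subset_cells(none, "mimic")), 0)
})
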