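# Virtual-continent biogeography with a planted model->mimic coupling.
# Model and "other" species receive clumped ranges (buffered random walks
# clipped to the continent). The continent is divided into square regions;
# the number of mimic species seeded in region r is Poisson with mean
#   a + b_model * model_richness(r) + c_other * other_richness(r),
# where richness is the rasterized (>= 50% coverage) species count at the
# region resolution. Each seeded mimic occupies most of its region, so the
# planted slope is exactly the quantity estimated by a richness regression
# at the region scale.

default_continent <- function() {
  as_ring(cbind(c(-105, -35, -35, -105), c(-35, -35, 35, 35)))
}

# Clumped range: union of disks along a short random walk, clipped to the
# continent (assumes ambient RNG seeded by caller).
random_clump <- function(continent_m, n_steps = 4, step_sd = 4,
                         radius_range = c(5, 9)) {
  start <- sample_in_mosaic(1, continent_m)
  pts <- matrix(NA_real_, n_steps, 2)
  pts[1, ] <- start
  for (i in seq_len(n_steps - 1))
    pts[i + 1, ] <- pts[i, ] + stats::rnorm(2, 0, step_sd)
  r <- stats::runif(1, radius_range[1], radius_range[2])
  disks <- lapply(seq_len(n_steps), function(i)
    circle_polygon(pts[i, ], r, n = 12))
  m <- mosaic_union_convex(disks)
  clipped <- mosaic_intersect(m, continent_m)
  if (length(clipped) == 0) return(NULL)
  clipped
}

#' Simulate virtual-continent biogeography with planted coupling
#'
#' @param n_model,n_other numbers of model (coral snake analogue) and
#'   non-mimetic other species.
#' @param b_model planted coupling: expected extra mimic species per model
#'   species in a region.
#' @param n_mimic target expected total number of mimic species; sets the
#'   intercept `a` of the regional mimic-richness generator.
#' @param c_other coupling of mimic richness to other-species richness.
#' @param continent convex continent polygon (lon/lat degree matrix);
#'   default a 70 x 70 degree rectangle spanning the tropics and both
#'   temperate margins. The default fauna mirrors the empirical
#'   composition of the New World snake data (mimics roughly 12% and
#'   models roughly 10% of species).
#' @param region_size region (and recommended rasterization) resolution in
#'   degrees.
#' @param mean_occurrences mean number of occurrence records per species.
#' @param mimic_style `"region"` seeds mimics per region with the planted
#'   Poisson coupling; `"clump"` places them as plain clumped ranges like
#'   the other species (the default when both couplings are zero, where
#'   there is nothing to plant and mimic ranges should be exchangeable
#'   with other non-model ranges).
#' @param seed RNG seed.
#' @return object of class `biogeography_sim`: `species` tibble
#'   (`species`, `tag`, `geometry` list-column), `occurrences` tibble
#'   (`species`, `lon`, `lat`), `coefficients` (list `a`, `b_model`,
#'   `c_other`), `continent`, `region_size`, `regions` (tibble of region
#'   midpoints with true model/other richness and seeded mimic counts).
#' @export
simulate_virtual_biogeography <- function(n_model = 14, n_other = 100,
                                          b_model = 1, n_mimic = 35,
                                          c_other = 0,
                                          continent = default_continent(),
                                          region_size = 10,
                                          mean_occurrences = 25,
                                          mimic_style = NULL,
                                          seed = NULL) {
  if (n_model < 0 || n_other < 0 || n_mimic < 0)
    mim_abort("species counts must be non-negative", "invalid_argument")
  continent_m <- as_mosaic(continent)
  bb <- mosaic_bbox(continent_m)
  if (diff(bb[c("xmin", "xmax")]) < 2 * region_size ||
      diff(bb[c("ymin", "ymax")]) < 2 * region_size)
    mim_abort("continent too small for the requested region size",
              "generation_failure")
  mimic_style <- mimic_style %||%
    (if (b_model == 0 && c_other == 0) "clump" else "region")
  xb <- seq(bb["xmin"], bb["xmax"], by = region_size)
  yb <- seq(bb["ymin"], bb["ymax"], by = region_size)
  nx <- length(xb) - 1
  ny <- length(yb) - 1
  with_seed(seed, {
    place <- function(n, prefix, tag) {
      out <- list()
      guard <- 0
      while (length(out) < n) {
        g <- random_clump(continent_m)
        guard <- guard + 1
        if (guard > 20 * n + 50)
          mim_abort("could not place ranges on the continent",
                    "generation_failure")
        if (!is.null(g)) out[[length(out) + 1]] <- g
      }
      tibble::tibble(species = paste0(prefix, seq_len(n)),
                     tag = tag, geometry = out)
    }
    models <- place(n_model, "model", "model")
    others <- place(n_other, "other", "other")

    cover_count <- function(tbl) {
      mat <- matrix(0L, nx, ny)
      for (g in tbl$geometry) {
        cov <- mosaic_grid_cover_cpp(unclass(g), xb, yb) / region_size^2
        mat <- mat + (cov >= 0.5 - 1e-9)
      }
      mat
    }
    model_rich <- cover_count(models)
    other_rich <- cover_count(others)

    # intercept chosen so the expected total mimic count is ~ n_mimic
    mean_load <- mean(b_model * model_rich + c_other * other_rich)
    a <- max(0, n_mimic / (nx * ny) - mean_load)
    lambda <- pmax(0, a + b_model * model_rich + c_other * other_rich)
    n_per_region <- matrix(stats::rpois(nx * ny, lambda), nx, ny)

    mimics <- list()
    mid_x <- xb[-length(xb)] + region_size / 2
    mid_y <- yb[-length(yb)] + region_size / 2
    if (mimic_style == "clump") {
      mimics <- list(place(n_mimic, "mimic", "mimic"))
      n_per_region <- matrix(0L, nx, ny)
    } else for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
      k <- n_per_region[ix, iy]
      if (k == 0) next
      region <- as_ring(cbind(c(xb[ix], xb[ix + 1], xb[ix + 1], xb[ix]),
                              c(yb[iy], yb[iy], yb[iy + 1], yb[iy + 1])))
      for (i in seq_len(k)) {
        ctr <- c(mid_x[ix], mid_y[iy]) + stats::runif(2, -1, 1)
        disk <- circle_polygon(ctr, 0.72 * region_size, n = 24)
        g <- mosaic_intersect(new_mosaic(list(as_ring(disk))),
                              mosaic_intersect(as_mosaic(region),
                                               continent_m))
        mimics[[length(mimics) + 1]] <- tibble::tibble(
          species = sprintf("mimic%02d_%02d_%d", ix, iy, i),
          tag = "mimic", geometry = list(g))
      }
    }
    species <- dplyr::bind_rows(models, others, dplyr::bind_rows(mimics))

    occ <- lapply(seq_len(nrow(species)), function(i) {
      npts <- 1 + stats::rpois(1, mean_occurrences - 1)
      pts <- sample_in_mosaic(npts, species$geometry[[i]])
      tibble::tibble(species = species$species[i],
                     lon = pts[, 1], lat = pts[, 2])
    })
    regions <- tibble::tibble(
      x = rep(mid_x, times = ny), y = rep(mid_y, each = nx),
      model = as.vector(model_rich), other = as.vector(other_rich),
      mimic_seeded = as.vector(n_per_region))
    structure(list(species = species,
                   occurrences = dplyr::bind_rows(occ),
                   coefficients = list(a = a, b_model = b_model,
                                       c_other = c_other),
                   continent = continent_m, region_size = region_size,
                   regions = regions, seed = seed),
              class = "biogeography_sim")
  })
}

#' @export
print.biogeography_sim <- function(x, ...) {
  cat("Virtual biogeography:", nrow(x$species), "species (",
      sum(x$species$tag == "model"), "model,",
      sum(x$species$tag == "mimic"), "mimic,",
      sum(x$species$tag == "other"), "other),",
      nrow(x$occurrences), "occurrence records\n")
  cat("planted coupling b_model =", x$coefficients$b_model, "\n")
  invisible(x)
}

#' Rasterize a biogeography simulation
#'
#' @param sim a [simulate_virtual_biogeography()] result.
#' @param resolution grid resolution in degrees; defaults to the
#'   simulation's region size (at which the planted coupling is exact).
#' @return list with `grid`, `presence` (per-species), and `richness`
#'   (per-tag table from [richness_table()]).
#' @export
rasterize_biogeography <- function(sim, resolution = NULL) {
  resolution <- resolution %||% sim$region_size
  bb <- mosaic_bbox(sim$continent)
  # anchor cells at the continent corner so they tile the generator's
  # regions exactly
  grid <- make_grid(sim$continent, resolution = resolution,
                    origin = c(bb["xmin"], bb["ymin"]))
  presence <- rasterize_presence(sim$species[c("species", "geometry")],
                                 grid)
  list(grid = grid,
       presence = presence,
       richness = richness_table(presence,
                                 sim$species[c("species", "tag")]))
}

#' Estimate the model->mimic richness coupling by OLS
#'
#' Regresses rasterized mimic richness on model and other richness, the
#' estimator whose slope the generator plants.
#'
#' @inheritParams rasterize_biogeography
#' @return tibble of coefficients with 95% confidence intervals.
#' @export
fit_richness_lm <- function(sim, resolution = NULL) {
  rich <- rasterize_biogeography(sim, resolution)$richness
  rich <- dplyr::filter(rich, .data$onland)
  fit <- stats::lm(mimic ~ model + other, data = rich)
  ci <- stats::confint(fit)
  tibble::tibble(term = names(stats::coef(fit)),
                 estimate = as.numeric(stats::coef(fit)),
                 conf.low = ci[, 1], conf.high = ci[, 2])
}
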