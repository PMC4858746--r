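# Species range construction from occurrence records. The dispatch rule
# follows the record count: >= 5 records -> alpha hull grown until the
# range is contiguous and holds >= 99% of the records; 3-4 records ->
# minimum convex hull; 1-2 records -> 0.5-degree point buffers. Ranges are
# planar multipolygons in lon/lat degree space (the buffer is a disk in
# degree space, matching the degree-radius convention of the source data).

#' Alpha-hull parameters
#'
#' @param alpha_start initial alpha (degrees). Default `NULL` uses the mean
#'   nearest-neighbour distance among the points.
#' @param growth_factor multiplicative alpha increment per iteration (> 1).
#' @param max_iterations maximum number of alpha values tried.
#' @param containment_fraction required fraction of records inside the hull
#'   (boundary counts as inside); applied as count >= ceiling(frac * n).
#' @return a list of class `alpha_hull_params`.
#' @export
alpha_hull_params <- function(alpha_start = NULL, growth_factor = 1.5,
                              max_iterations = 30,
                              containment_fraction = 0.99) {
  if (growth_factor <= 1)
    mim_abort("growth_factor must be > 1", "invalid_argument")
  if (containment_fraction <= 0 || containment_fraction > 1)
    mim_abort("containment_fraction must be in (0, 1]", "invalid_argument")
  structure(list(alpha_start = alpha_start, growth_factor = growth_factor,
                 max_iterations = max_iterations,
                 containment_fraction = containment_fraction),
            class = "alpha_hull_params")
}

#' Grow an alpha hull until contiguous and sufficiently inclusive
#'
#' Builds the alpha complex (Delaunay triangles with circumradius <= alpha)
#' and sequentially increases alpha by `growth_factor` until the complex is
#' a single connected polygon containing at least `containment_fraction` of
#' the points. The smallest tested alpha meeting both conditions is used.
#'
#' @param points n x 2 matrix or data frame of (lon, lat); n >= 5 and not
#'   all collinear.
#' @param params an [alpha_hull_params()] object.
#' @return list with `geometry` (mosaic of Delaunay triangles), `alpha`
#'   (the alpha used), and `contained` (number of points inside).
#' @export
grow_alpha_hull <- function(points, params = alpha_hull_params()) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5)
    mim_abort("alpha hull needs >= 5 points", "invalid_argument")
  dt <- delaunay_triangulation(points) # errors on collinear input
  alpha <- params$alpha_start
  if (is.null(alpha)) {
    d <- as.matrix(stats::dist(points))
    diag(d) <- Inf
    alpha <- mean(apply(d, 1, min))
  }
  need <- ceiling(params$containment_fraction * n)
  last <- NULL
  for (it in seq_len(params$max_iterations)) {
    keep <- dt$circumradius <= alpha
    if (any(keep)) {
      tri_idx <- dt$triangles[keep, , drop = FALSE]
      m <- new_mosaic(lapply(seq_len(nrow(tri_idx)), function(k)
        as_ring(points[tri_idx[k, ], , drop = FALSE])))
      last <- list(geometry = m, alpha = alpha)
      if (alpha_connected(tri_idx)) {
        contained <- sum(point_in_mosaic(points, m))
        if (contained >= need)
          return(list(geometry = m, alpha = alpha, contained = contained))
      }
    }
    alpha <- alpha * params$growth_factor
  }
  mim_abort("alpha hull did not converge within max_iterations",
            "alpha_failure", geometry = last$geometry)
}

# Single connected component of the triangle adjacency graph (shared edge)?
# Triangles sharing only a vertex also merge the polygon, so use shared
# vertices for connectivity of the union.
alpha_connected <- function(tri_idx) {
  nt <- nrow(tri_idx)
  if (nt == 0) return(FALSE)
  comp <- seq_len(nt)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  verts <- unique(as.vector(tri_idx))
  for (v in verts) {
    hit <- which(apply(tri_idx == v, 1, any))
    if (length(hit) > 1) {
      r <- find(hit[1])
      for (h in hit[-1]) comp[find(h)] <- r
    }
  }
  length(unique(vapply(seq_len(nt), find, integer(1)))) == 1
}

#' Build a species range from occurrence points
#'
#' Dispatches on record count: >= 5 records builds an alpha hull (falling
#' back to a convex hull if alpha growth fails, or to point buffers if the
#' points are collinear), 3-4 records a minimum convex hull, 1-2 records a
#' union of 0.5-degree-radius disks.
#'
#' @param points n x 2 matrix/data frame of (lon, lat) for one species.
#' @param buffer_degrees disk radius for the 1-2 record case.
#' @param params alpha-hull parameters, see [alpha_hull_params()].
#' @return list with `geometry` (mosaic), `method` tag (one of `"alpha"`,
#'   `"hull"`, `"buffer"`), `alpha` (NA unless alpha method) and
#'   `n_records`.
#' @export
build_range <- function(points, buffer_degrees = 0.5,
                        params = alpha_hull_params()) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) {
    warn("species has no records; skipped")
    return(NULL)
  }
  buffer_fallback <- function() {
    disks <- lapply(seq_len(n), function(i)
      circle_polygon(points[i, ], buffer_degrees))
    list(geometry = mosaic_union_convex(disks), method = "buffer",
         alpha = NA_real_, n_records = n)
  }
  hull_fallback <- function() {
    tryCatch(
      list(geometry = as_mosaic(convex_hull_poly(points)), method = "hull",
           alpha = NA_real_, n_records = n),
      error = function(e) buffer_fallback())
  }
  if (n >= 5) {
    tryCatch({
      ah <- grow_alpha_hull(points, params)
      list(geometry = ah$geometry, method = "alpha", alpha = ah$alpha,
           n_records = n)
    },
    alpha_failure = function(e) {
      warn("alpha hull failed to converge; falling back to convex hull")
      hull_fallback()
    },
    degenerate_geometry = function(e) {
      warn("collinear records; falling back to point buffers")
      buffer_fallback()
    })
  } else if (n >= 3) {
    hull_fallback()
  } else {
    buffer_fallback()
  }
}

#' Build ranges for every species in an occurrence table
#'
#' @param occurrences data frame with columns `species`, `lon`, `lat`.
#' @param coast optional coastline polygon (matrix or mosaic); when given,
#'   each range is clipped to land and species whose range falls entirely
#'   at sea are dropped with a warning.
#' @inheritParams build_range
#' @return tibble with one row per species: `species`, `n_records`,
#'   `method`, `alpha` and a `geometry` list-column of mosaics.
#' @export
build_ranges <- function(occurrences, coast = NULL, buffer_degrees = 0.5,
                         params = alpha_hull_params()) {
  stopifnot(all(c("species", "lon", "lat") %in% names(occurrences)))
  coast_m <- if (!is.null(coast)) as_mosaic(coast)
  rows <- occurrences |>
    dplyr::group_by(.data$species) |>
    dplyr::group_map(function(df, key) {
      rg <- build_range(cbind(df$lon, df$lat), buffer_degrees, params)
      if (is.null(rg)) return(NULL)
      if (!is.null(coast_m)) {
        rg$geometry <- clip_to_land(rg$geometry, coast_m)
        if (length(rg$geometry) == 0) {
          warn(paste0("range of ", key$species,
                      " is entirely at sea; dropped"))
          return(NULL)
        }
      }
      tibble::tibble(species = key$species, n_records = rg$n_records,
                     method = rg$method, alpha = rg$alpha,
                     geometry = list(rg$geometry))
    })
  dplyr::bind_rows(rows)
}

#' Clip a range to the coastline
#'
#' @param range a mosaic (as stored in the `geometry` column of
#'   [build_ranges()] output).
#' @param coast coastline polygon (matrix or mosaic).
#' @return the intersected mosaic; empty (length 0) if the range lies
#'   entirely at sea.
#' @export
clip_to_land <- function(range, coast) {
  mosaic_intersect(as_mosaic(range), as_mosaic(coast))
}
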