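# Gridded richness and abundance. Grids are regular lon/lat lattices at a
# declared resolution (2 or 0.5 degrees in the motivating analyses); each
# cell is identified by its midpoint, carries an onland flag, and presence
# of a species requires its range to cover at least half of the cell
# (computed by exact polygon-cell intersection, threshold inclusive).

#' Build a regular lon/lat grid over a coastline
#'
#' @param coast coastline polygon (matrix or mosaic).
#' @param resolution cell size in degrees (2 and 0.5 are the conventional
#'   choices).
#' @param origin `c(lon, lat)` of a grid line intersection; defaults to the
#'   coast bounding box floored to a multiple of `resolution`.
#' @param onland_min_cover fraction of a cell that must be covered by the
#'   coast polygon for the cell to count as mainland.
#' @return tibble of cells with midpoint coordinates `x`, `y` and logical
#'   `onland`; grid metadata in attributes `resolution`, `xbreaks`,
#'   `ybreaks`.
#' @export
make_grid <- function(coast, resolution = 2, origin = NULL,
                      onland_min_cover = 0.5) {
  coast_m <- as_mosaic(coast)
  bb <- mosaic_bbox(coast_m)
  if (is.null(origin))
    origin <- c(floor(bb["xmin"] / resolution) * resolution,
                floor(bb["ymin"] / resolution) * resolution)
  xb <- seq(origin[1], bb["xmax"] + resolution, by = resolution)
  yb <- seq(origin[2], bb["ymax"] + resolution, by = resolution)
  cover <- mosaic_grid_cover_cpp(unclass(coast_m), xb, yb) / resolution^2
  nx <- length(xb) - 1
  ny <- length(yb) - 1
  grid <- tibble::tibble(
    x = rep(xb[-length(xb)] + resolution / 2, times = ny),
    y = rep(yb[-length(yb)] + resolution / 2, each = nx),
    onland = as.vector(cover) >= onland_min_cover - 1e-9
  )
  attr(grid, "resolution") <- resolution
  attr(grid, "xbreaks") <- xb
  attr(grid, "ybreaks") <- yb
  grid
}

grid_breaks <- function(grid) {
  list(xb = attr(grid, "xbreaks"), yb = attr(grid, "ybreaks"),
       res = attr(grid, "resolution"))
}

#' Rasterize range polygons to per-species presence
#'
#' A species is present in a cell when its range covers at least
#' `min_cover` (default 50%, inclusive) of the cell area. Cells off the
#' mainland carry `NA`.
#'
#' @param ranges output of [build_ranges()] (tibble with `species` and
#'   `geometry` columns).
#' @param grid a grid from [make_grid()].
#' @param min_cover inclusive coverage threshold.
#' @return the grid tibble extended with one integer presence column per
#'   species.
#' @export
rasterize_presence <- function(ranges, grid, min_cover = 0.5) {
  gb <- grid_breaks(grid)
  cell_area <- gb$res^2
  out <- grid
  for (i in seq_len(nrow(ranges))) {
    cover <- mosaic_grid_cover_cpp(unclass(ranges$geometry[[i]]),
                                   gb$xb, gb$yb) / cell_area
    pres <- as.integer(as.vector(cover) >= min_cover - 1e-9)
    pres[!grid$onland] <- NA_integer_
    out[[ranges$species[i]]] <- pres
  }
  out
}

species_columns <- function(presence) {
  setdiff(names(presence), c("x", "y", "onland"))
}

#' Per-cell richness of tagged species sets
#'
#' @param presence output of [rasterize_presence()].
#' @param tags data frame with columns `species` and `tag` (values
#'   `"model"`, `"mimic"`, `"other"`, ...).
#' @return tibble with `x`, `y`, `onland` and per-tag richness columns plus
#'   `total`.
#' @export
richness_table <- function(presence, tags) {
  sp <- species_columns(presence)
  missing <- setdiff(sp, tags$species)
  if (length(missing) > 0)
    mim_abort(paste("untagged species:", paste(missing, collapse = ", ")),
              "invalid_argument")
  out <- presence[c("x", "y", "onland")]
  mat <- as.matrix(presence[sp])
  for (tg in unique(tags$tag)) {
    cols <- intersect(sp, tags$species[tags$tag == tg])
    out[[tg]] <- if (length(cols))
      rowSums(mat[, cols, drop = FALSE]) else 0L
  }
  out$total <- rowSums(mat)
  out
}

#' Subset grid cells by occupancy predicate
#'
#' Restricts a richness table to mainland cells holding at least one
#' species of the requested set (at least one mimic, or at least one
#' model/coral snake).
#'
#' @param richness a [richness_table()] result (or any cell table with the
#'   named column).
#' @param predicate column that must be >= 1 (`"mimic"` or `"model"`).
#' @return the filtered tibble (possibly empty).
#' @export
subset_cells <- function(richness, predicate = c("mimic", "model")) {
  predicate <- match.arg(predicate)
  dplyr::filter(richness, .data$onland,
                !is.na(.data[[predicate]]), .data[[predicate]] >= 1)
}

#' Rasterize specimen counts
#'
#' Counts individual occurrence records per cell using half-open cell
#' intervals `[west, east) x [south, north)` so boundary records land in
#' exactly one cell. Records falling outside the grid or on sea cells are
#' dropped.
#'
#' @param occurrences data frame with `species`, `lon`, `lat`.
#' @param grid grid from [make_grid()].
#' @param tags data frame with `species`, `tag`; counts are returned per
#'   tag and in total.
#' @return tibble `x`, `y`, `onland`, one count column per tag, `total`.
#' @export
abundance_rasters <- function(occurrences, grid, tags) {
  gb <- grid_breaks(grid)
  nx <- length(gb$xb) - 1
  ny <- length(gb$yb) - 1
  ix <- findInterval(occurrences$lon, gb$xb, rightmost.closed = FALSE)
  iy <- findInterval(occurrences$lat, gb$yb, rightmost.closed = FALSE)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  cell <- ix + (iy - 1) * nx
  onland_cell <- grid$onland[cell[ok]]
  keep <- which(ok)[onland_cell]
  out <- grid[c("x", "y", "onland")]
  tagmap <- stats::setNames(tags$tag, tags$species)
  rec_tag <- tagmap[occurrences$species[keep]]
  for (tg in unique(tags$tag)) {
    cnt <- tabulate(cell[keep][rec_tag == tg], nbins = nx * ny)
    out[[tg]] <- as.integer(cnt)
  }
  out$total <- as.integer(tabulate(cell[keep], nbins = nx * ny))
  for (cl in setdiff(names(out), c("x", "y", "onland")))
    out[[cl]][!out$onland] <- NA_integer_
  out
}

#' Log2 mimic-to-model abundance ratio
#'
#' Adds one to each count before the ratio so empty cells are defined:
#' `log2((mimic + 1) / (model + 1))`.
#'
#' @param mimic_counts,model_counts aligned non-negative integer vectors.
#' @return numeric vector of per-cell log2 ratios.
#' @export
log2_mimic_model_ratio <- function(mimic_counts, model_counts) {
  if (length(mimic_counts) != length(model_counts))
    mim_abort("count vectors must be aligned", "invalid_argument")
  if (any(mimic_counts < 0, na.rm = TRUE) ||
      any(model_counts < 0, na.rm = TRUE))
    mim_abort("counts must be non-negative", "invalid_argument")
  log2((mimic_counts + 1) / (model_counts + 1))
}
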