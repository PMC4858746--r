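# Plain-text interchange: Newick trees, CSV traits/latitudes/occurrences,
# the x/y/onland grid-table dialect, and GeoJSON range polygons.

#' Read and write Newick trees
#'
#' Thin wrappers around the ape parser; round-trips preserve labels,
#' topology, polytomies and branch lengths.
#'
#' @param text a Newick string, or `file` a path.
#' @param file path to read/write.
#' @param tree a `phylo`.
#' @return `read_newick`: a `phylo`; `write_newick`: the Newick string
#'   (invisibly if written to a file).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (!is.null(file)) ape::read.tree(file)
    else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    mim_abort("malformed Newick string", "parse_error")
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Write a grid table in the x/y/onland CSV dialect
#'
#' Column order: `x` (longitude midpoint), `y` (latitude midpoint),
#' `onland` (0/1), then one column per species set.
#'
#' @param grid_table a richness/abundance tibble with `x`, `y`, `onland`.
#' @param file output path.
#' @export
write_grid_csv <- function(grid_table, file) {
  out <- grid_table
  out$onland <- as.integer(out$onland)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Write range polygons as a GeoJSON FeatureCollection
#'
#' Each species becomes one MultiPolygon feature (the disjoint convex
#' pieces of its range mosaic) with `species` and `tag` properties.
#'
#' @param ranges tibble with `species`, `geometry` (mosaics) and
#'   optionally `tag`.
#' @param file output path.
#' @export
write_ranges_geojson <- function(ranges, file) {
  feat <- lapply(seq_len(nrow(ranges)), function(i) {
    polys <- lapply(unclass(ranges$geometry[[i]]), function(p) {
      ring <- rbind(p, p[1, , drop = FALSE])
      list(lapply(seq_len(nrow(ring)), function(k) ring[k, ]))
    })
    list(type = "Feature",
         properties = list(
           species = ranges$species[i],
           tag = if ("tag" %in% names(ranges)) ranges$tag[i] else NA),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write tip traits or latitudes as CSV
#'
#' @param x named vector (species -> value).
#' @param file output path.
#' @param value_name column name for the value (`"state"` or
#'   `"latitude"`).
#' @export
write_species_csv <- function(x, file, value_name = "state") {
  df <- data.frame(species = names(x), value = unname(x))
  names(df)[2] <- value_name
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
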