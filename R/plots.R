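# ggplot2 views of the main result types.

#' Map a per-cell quantity on the lon/lat grid
#'
#' @param cells tibble with `x`, `y` and the fill column (e.g. a
#'   [richness_table()] or the `cells` element of [permutation_test()]).
#' @param fill name of the column to map to fill.
#' @return a ggplot.
#' @export
plot_richness_map <- function(cells, fill = "mimic") {
  cells <- dplyr::filter(cells, .data$onland)
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y,
                                      fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = fill) +
    ggplot2::theme_minimal()
}

#' @describeIn summarize_ensemble frequency-through-time curve.
#' @param object a `map_ensemble_summary`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.map_ensemble_summary <- function(object, ...) {
  ggplot2::ggplot(object$freq_through_time,
                  ggplot2::aes(.data$age, .data$freq1)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Mya)",
                  y = "frequency of RBB state among lineages") +
    ggplot2::theme_minimal()
}

#' Latitudinal density of gains and losses
#'
#' @param events tibble from [locate_events()].
#' @param bandwidth KDE bandwidth (degrees) or `"nrd0"`.
#' @return a ggplot with one density curve per event type.
#' @export
plot_event_density <- function(events, bandwidth = "nrd0") {
  dens <- dplyr::bind_rows(lapply(intersect(c("gain", "loss"),
                                            unique(events$type)),
                                  function(tp)
    dplyr::mutate(event_latitude_density(events, tp, bandwidth),
                  type = tp)))
  ggplot2::ggplot(dens, ggplot2::aes(.data$latitude, .data$density,
                                     colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(-23, 23, 35), linetype = 3) +
    ggplot2::labs(x = "latitude (degrees)", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
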