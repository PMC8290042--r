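#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a connectivity regression summary
#'
#' @param x A `conn_lm` from [boundary_regression()] or [focal_association()].
#' @param ... Unused.
#' @return One row per model term with `term`, `estimate`, `std.error`,
#'   `p.value`, and the printed significance `stars`
#'   (`*p<0.1, **p<0.05, ***p<0.01`).
#' @export
tidy.conn_lm <- function(x, ...) {
  tibble::tibble(
    term = x$terms$term,
    estimate = x$terms$coefficient,
    std.error = x$terms$standard_error,
    p.value = x$terms$p_value,
    stars = signif_stars(x$terms$p_value)
  )
}

#' @rdname tidy.conn_lm
#' @export
glance.conn_lm <- function(x, ...) {
  tibble::tibble(adj.r.squared = x$adjusted_r_squared,
                 nobs = x$n_observations)
}

#' Tidy a distance-decay fit
#'
#' @param x A `decay_fit` from [fit_distance_decay()].
#' @param ... Unused.
#' @return Tidy coefficients (`amplitude`, `exponent`); `glance()` reports
#'   the raw-scale R-squared, pair count and whether the log-log fallback
#'   was used.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "exponent"),
                 estimate = c(x$amplitude, x$exponent))
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_pairs,
                 fallback = x$fallback)
}

#' Plot a distance-decay fit
#'
#' Scatter of connectivity against distance with the fitted power-law curve
#' overlaid, on log-log axes where the power law is a straight line.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(
    d = exp(seq(log(min(object$data$d)), log(max(object$data$d)),
                length.out = 200))
  )
  grid$y <- object$amplitude * grid$d^(-object$exponent)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$d, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "centroid distance (miles)", y = "connectivity",
      title = sprintf("y = %.3g * d^(-%.2f),  R² = %.3f",
                      object$amplitude, object$exponent, object$r_squared)
    )
}

#' Plot the connectivity distribution of a matrix
#'
#' Histogram of the nonzero pairwise index values on a log10 axis.
#'
#' @param object A `pci_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pci_matrix <- function(object, ...) {
  ggplot2::ggplot(object$pci, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "place connectivity index (nonzero pairs)", y = "pairs")
}

#' Map a regionalization on its place layer
#'
#' Draws each place's polygon filled by community label at one cut level.
#'
#' @param object A `region_clust`.
#' @param layer The `place_layer` the dissimilarities came from.
#' @param k Cut level to draw (defaults to the finest stored cut).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_clust <- function(object, layer, k = NULL, ...) {
  if (is.null(k)) k <- min(object$assignments$k)
  asn <- region_assignment(object, k)
  rings <- purrr::map2_dfr(layer$place_id, layer$geometry, function(id, polys) {
    ring <- polys[[1]][[1]]
    tibble::tibble(place_id = id, lon = ring[, 1], lat = ring[, 2])
  })
  rings <- dplyr::inner_join(rings, asn, by = "place_id")
  ggplot2::ggplot(rings, ggplot2::aes(x = .data$lon, y = .data$lat,
                                      group = .data$place_id,
                                      fill = factor(.data$label))) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(fill = "community",
                  title = paste0("communities at k = ", k))
}
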