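#' @importFrom ggplot2 ggplot aes geom_histogram geom_line geom_col geom_tile
#'   geom_step labs theme_minimal scale_fill_viridis_c autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the fitted background mixture over the data histogram
#'
#' @param object A fitted `mpra_mixture`.
#' @param x Optional data vector to histogram under the fitted curves.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mpra_mixture <- function(object, x = NULL, ...) {
  lim <- c(object$mu0 - 4 * object$sigma0, object$mu1 + 4 * object$sigma1)
  grid <- seq(lim[1], lim[2], length.out = 400)
  curves <- dplyr::bind_rows(
    tibble(x = grid, density = mixture_density(object, grid),
           component = "mixture"),
    tibble(x = grid,
           density = object$pi * dnorm(grid, object$mu0, object$sigma0),
           component = "background"),
    tibble(x = grid,
           density = (1 - object$pi) * dnorm(grid, object$mu1, object$sigma1),
           component = "signal")
  )
  p <- ggplot(curves, aes(x = .data$x, y = .data$density,
                          colour = .data$component))
  if (!is.null(x)) {
    p <- p + geom_histogram(
      data = tibble(v = x),
      aes(x = .data$v, y = ggplot2::after_stat(density)),
      bins = object$n_bins, inherit.aes = FALSE, fill = "grey85",
      colour = NA
    )
  }
  p + geom_line(linewidth = 0.8) +
    labs(x = "activity (RNA/DNA)", y = "density",
         title = "Negative-control activity and fitted mixture") +
    theme_minimal()
}

#' Bar plot of temporal-class counts
#'
#' @param classes Result of [classify_temporal()].
#' @return A ggplot of the Venn-class partition.
#' @export
plot_temporal_partition <- function(classes) {
  part <- attr(classes, "partition")
  part$temporal_class <- factor(part$temporal_class,
                                levels = part$temporal_class)
  ggplot(part, aes(x = .data$temporal_class, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "elements", title = "Temporal activity classes") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Concordance-curve plot
#'
#' @param curve Result of [concordance_curve()].
#' @return A ggplot of fraction of coupled pairs versus cutoff, per group.
#' @export
plot_concordance <- function(curve) {
  ggplot(curve, aes(x = .data$cutoff, y = .data$fraction,
                    colour = .data$group)) +
    geom_step(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0.8, linetype = "dashed",
                        colour = "grey40") +
    labs(x = "|log2 fold change| cutoff",
         y = "fraction of pairs passing both cutoffs",
         title = "Activity-expression concordance") +
    theme_minimal()
}

#' Activity heatmap in dendrogram order
#'
#' Values are capped at the clustering object's `cap` for display; distances
#' were computed on uncapped values.
#'
#' @param clustering Result of [cluster_activity()].
#' @return A ggplot tile heatmap.
#' @export
plot_activity_heatmap <- function(clustering) {
  m <- pmin(clustering$matrix, clustering$cap)
  df <- as_tibble(m, rownames = "element_id") |>
    tidyr::pivot_longer(-"element_id", names_to = "sample",
                        values_to = "activity") |>
    mutate(element_id = factor(.data$element_id, levels = clustering$order))
  ggplot(df, aes(x = .data$sample, y = .data$element_id,
                 fill = .data$activity)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, title = "Enhancer activity (capped)") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
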