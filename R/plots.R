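#' Plot methods
#'
#' ggplot2 views of the package's result objects: gridded surfaces are
#' drawn with `geom_raster()` on the cell centers, importance profiles as
#' ranked bars, PCA scores as a scatter coloured by cluster.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name stacksdm-plots
NULL

plot_surface <- function(df, fill, title) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(title = title, x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' @rdname stacksdm-plots
#' @export
autoplot.richness_map <- function(object, ...) {
  plot_surface(tidy(object), "richness", "Predicted species richness")
}

#' @rdname stacksdm-plots
#' @export
autoplot.uncertainty_map <- function(object, ...) {
  plot_surface(tidy(object), "uncertainty", "Between-algorithm uncertainty")
}

#' @rdname stacksdm-plots
#' @export
autoplot.endemism_map <- function(object, ...) {
  plot_surface(tidy(object), "endemism", "Weighted endemism")
}

#' @rdname stacksdm-plots
#' @param layer Layer name to draw.
#' @export
autoplot.env_stack <- function(object, layer = env_layer_names(object)[1], ...) {
  plot_surface(object$data, layer, layer)
}

#' @rdname stacksdm-plots
#' @export
autoplot.ensemble_sdm <- function(object, ...) {
  df <- cell_centers(object$spec)
  df$suitability <- object$suitability
  plot_surface(df, "suitability",
               sprintf("%s ensemble suitability", object$species))
}

#' Mean variable importance across species
#'
#' @param ensembles List of `ensemble_sdm`/`fitted_sdm` objects, or an
#'   importance matrix from [importance_matrix()].
#' @return A ggplot of mean importance per environmental layer with one
#'   standard deviation whiskers.
#' @export
plot_importance <- function(ensembles) {
  m <- if (is.matrix(ensembles)) ensembles else importance_matrix(ensembles)
  df <- tibble::tibble(layer = colnames(m),
                       mean = colMeans(m),
                       sd = apply(m, 2, stats::sd))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$layer, .data$mean),
                                   y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean importance (%)",
                  title = "Ensemble variable importance") +
    ggplot2::theme_minimal()
}

#' @rdname stacksdm-plots
#' @param clusters Optional `cluster_assignment` to colour the scores by.
#' @export
autoplot.sdm_pca <- function(object, clusters = NULL, ...) {
  df <- tibble::tibble(species = rownames(object$scores),
                       PC1 = object$scores[, 1], PC2 = object$scores[, 2])
  if (!is.null(clusters)) {
    df$cluster <- factor(clusters$assignment$cluster[
      match(df$species, clusters$assignment$species)])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(title = "Importance-profile PCA") +
    ggplot2::theme_minimal()
  if (is.null(df$cluster)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster))
}
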