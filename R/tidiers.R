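#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-component table of an
#' object (importances, cells, loadings, Tukey contrasts, ...) and
#' `glance()` a one-row model summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name stacksdm-tidiers
NULL

#' @rdname stacksdm-tidiers
#' @export
tidy.fitted_sdm <- function(x, ...) {
  tibble::tibble(species = x$species, algorithm = x$algorithm,
                 layer = names(x$importance),
                 importance = as.numeric(x$importance))
}

#' @rdname stacksdm-tidiers
#' @export
glance.fitted_sdm <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(species = x$species, algorithm = x$algorithm),
    x$cv_metrics,
    tibble::tibble(threshold = x$threshold))
}

#' @rdname stacksdm-tidiers
#' @export
tidy.ensemble_sdm <- function(x, ...) {
  tibble::tibble(species = x$species,
                 layer = names(x$importance),
                 importance = as.numeric(x$importance))
}

#' @rdname stacksdm-tidiers
#' @export
glance.ensemble_sdm <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(species = x$species,
                   combo = paste(x$algorithms, collapse = "-")),
    x$metrics,
    tibble::tibble(threshold = x$threshold))
}

#' @rdname stacksdm-tidiers
#' @export
tidy.richness_map <- function(x, ...) {
  out <- cell_centers(x$spec)
  out$richness <- x$counts
  out
}

#' @rdname stacksdm-tidiers
#' @export
tidy.uncertainty_map <- function(x, ...) {
  out <- cell_centers(x$spec)
  out$uncertainty <- x$values
  out
}

#' @rdname stacksdm-tidiers
#' @export
tidy.endemism_map <- function(x, ...) {
  out <- cell_centers(x$spec)
  out$endemism <- x$values
  out
}

#' @rdname stacksdm-tidiers
#' @export
tidy.env_stack <- function(x, ...) {
  x$data
}

#' @rdname stacksdm-tidiers
#' @export
tidy.sdm_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-variable, names_to = "component",
                        values_to = "loading")
}

#' @rdname stacksdm-tidiers
#' @export
glance.sdm_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$eigenvalues),
                 total_variance = sum(x$eigenvalues),
                 pc1_share = x$eigenvalues[1] / sum(x$eigenvalues))
}

#' @rdname stacksdm-tidiers
#' @export
tidy.regional_anova <- function(x, ...) {
  x$tukey
}

#' @rdname stacksdm-tidiers
#' @export
glance.regional_anova <- function(x, ...) {
  tibble::tibble(n_regions = x$n_regions,
                 df_between = x$anova$df[1], df_within = x$anova$df[2],
                 f_statistic = x$anova$statistic[1],
                 p.value = x$anova$p.value[1])
}

#' @rdname stacksdm-tidiers
#' @export
tidy.cluster_assignment <- function(x, ...) {
  x$assignment
}

#' @rdname stacksdm-tidiers
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(k = x$k, linkage = x$linkage,
                 n_species = nrow(x$assignment))
}

utils::globalVariables(c("variable"))
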