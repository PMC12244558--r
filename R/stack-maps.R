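#' Stack binary range maps into a species richness surface
#'
#' Each species' ensemble suitability is binarised at its TSS-optimal
#' threshold and the binary maps are summed cell by cell.
#'
#' @param ensembles List of `ensemble_sdm` (or `fitted_sdm`) objects sharing
#'   one grid.
#' @return A `richness_map`: fields `spec`, `counts` (integer vector over
#'   cells, `NA` where the stack is invalid) and `n_species`.
#' @export
stack_binary <- function(ensembles) {
  stopifnot(length(ensembles) >= 1)
  spec <- ensembles[[1]]$spec
  for (e in ensembles[-1]) {
    if (!same_geometry(spec, e$spec)) stop("ensembles on mismatched grids", call. = FALSE)
  }
  bin <- vapply(ensembles, function(e) as.integer(binary_surface(e)),
                integer(length(ensembles[[1]]$suitability)))
  counts <- as.integer(rowSums(bin))
  structure(list(spec = spec, counts = counts, n_species = length(ensembles)),
            class = "richness_map")
}

#' @export
print.richness_map <- function(x, ...) {
  cat(sprintf("<richness_map> %d species on a %d x %d grid; richness %d-%d\n",
              x$n_species, x$spec$n_rows, x$spec$n_cols,
              min(x$counts, na.rm = TRUE), max(x$counts, na.rm = TRUE)))
  invisible(x)
}

#' Between-algorithm uncertainty surface
#'
#' Per cell: the standard deviation (population form, i.e. divisor `n`) of
#' the member suitabilities within each species' ensemble, averaged over
#' species. High values flag places where the algorithms disagree.
#'
#' @param ensembles List of `ensemble_sdm` objects, each with >= 2 members.
#' @return An `uncertainty_map` (fields `spec`, `values`).
#' @export
uncertainty_map <- function(ensembles) {
  if (any(vapply(ensembles, function(e) length(e$members) < 2, logical(1)))) {
    stop("uncertainty needs ensembles with at least 2 members", call. = FALSE)
  }
  spec <- ensembles[[1]]$spec
  per_species <- vapply(ensembles, function(e) {
    suit <- vapply(e$members, function(m) m$suitability,
                   numeric(length(e$suitability)))
    sqrt(rowMeans((suit - rowMeans(suit))^2))
  }, numeric(length(ensembles[[1]]$suitability)))
  structure(list(spec = spec, values = rowMeans(per_species)),
            class = "uncertainty_map")
}

#' Weighted endemism surface
#'
#' The weighted endemism index (WEI) of a cell is the sum over species
#' present there of the inverse of the species' predicted range size (in
#' cells), so range-restricted species dominate the surface.
#'
#' @param ensembles List of `ensemble_sdm` (or `fitted_sdm`) objects.
#' @return An `endemism_map` (fields `spec`, `values`, `method = "WEI"`).
#'   Species with an empty predicted range are excluded with a warning.
#' @export
endemism_map <- function(ensembles) {
  spec <- ensembles[[1]]$spec
  bin <- vapply(ensembles, function(e) as.numeric(binary_surface(e)),
                numeric(length(ensembles[[1]]$suitability)))
  range_size <- colSums(bin, na.rm = TRUE)
  if (any(range_size == 0)) {
    warning(sprintf("%d species with empty predicted range excluded from endemism",
                    sum(range_size == 0)), call. = FALSE)
    bin <- bin[, range_size > 0, drop = FALSE]
    range_size <- range_size[range_size > 0]
  }
  values <- as.numeric(bin %*% (1 / range_size))
  values[rowSums(is.na(bin)) > 0] <- NA_real_
  structure(list(spec = spec, values = values, method = "WEI"),
            class = "endemism_map")
}

#' Evaluate a stacked prediction against observed assemblages
#'
#' Evaluation sites are the grid cells holding at least one observed record.
#' At each site the predicted assemblage (species whose binary map is
#' presence there) is confronted with the observed species list over the
#' full modelled roster: species recorded in the cell count as observed
#' presences and the remaining roster species as observed absences (the
#' conventional reading forced by presence-only data). Per-site metrics are
#' the confusion suite plus `prediction_success` (percent correct) and
#' `species_richness_error` (absolute difference between predicted and
#' observed richness); means and SDs are taken across sites. Sites where a
#' metric is undefined (e.g. every roster species observed) are skipped for
#' that metric with a warning.
#'
#' @param ensembles List of `ensemble_sdm`/`fitted_sdm` objects (the roster).
#' @param records Occurrence tibble with `taxon` and `cell` (or lon/lat).
#' @param stack The [env_stack()] defining the grid.
#' @return Tibble with columns `metric`, `mean`, `sd`, `n_sites`.
#' @export
evaluate_community <- function(ensembles, records, stack) {
  roster <- vapply(ensembles, function(e) e$species, character(1))
  if (!"cell" %in% names(records)) {
    records$cell <- point_to_cell(stack$spec, records$lon, records$lat)
  }
  records <- records[records$taxon %in% roster & !is.na(records$cell), , drop = FALSE]
  sites <- sort(unique(records$cell))
  if (!length(sites)) stop("no evaluation sites with observed records", call. = FALSE)
  bin <- vapply(ensembles, function(e) binary_surface(e)[sites],
                logical(length(sites)))
  if (length(sites) == 1) bin <- matrix(bin, nrow = 1)
  obs <- matrix(FALSE, length(sites), length(roster),
                dimnames = list(NULL, roster))
  obs[cbind(match(records$cell, sites), match(records$taxon, roster))] <- TRUE

  skipped <- 0L
  per_site <- purrr::map_dfr(seq_along(sites), function(i) {
    p <- bin[i, ]
    o <- obs[i, ]
    tp <- sum(p & o); fp <- sum(p & !o); tn <- sum(!p & !o); fn <- sum(!p & o)
    base <- if (tp + fn > 0 && tn + fp > 0) {
      confusion_metrics(tp, fp, tn, fn)
    } else {
      skipped <<- skipped + 1L
      tibble::tibble(sensitivity = NA_real_, specificity = NA_real_,
                     omission_rate = NA_real_, prop_correct = NA_real_,
                     kappa = NA_real_, tss = NA_real_, jaccard = NA_real_)
    }
    dplyr::mutate(base,
                  prediction_success = 100 * prop_correct,
                  species_richness_error = abs(sum(p) - sum(o)))
  })
  if (skipped > 0) {
    warning(sprintf("%d site(s) skipped for confusion metrics (one observed class empty)",
                    skipped), call. = FALSE)
  }
  tidyr::pivot_longer(per_site, dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(metric) |>
    dplyr::summarise(mean = mean(value, na.rm = TRUE),
                     sd = stats::sd(value, na.rm = TRUE),
                     n_sites = sum(!is.na(value))) |>
    dplyr::ungroup()
}

utils::globalVariables(c("metric", "value", "prop_correct"))
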