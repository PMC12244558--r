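#' Combine per-algorithm models into a per-species ensemble
#'
#' The ensemble suitability surface is the weighted mean of the member
#' suitabilities, with weights either uniform or proportional to each
#' member's cross-validated AUC (the default). The binarisation threshold is
#' recomputed by TSS maximisation on the combined predictions at the union
#' of the members' training cells, using each member's out-of-fold
#' cross-validation predictions where available (falling back to its
#' suitability surface), so the threshold is not biased by refit
#' overfitting; the ensemble metrics are evaluated on the same predictions.
#' Member importances are combined with the same weights and renormalised.
#'
#' @param members List of `fitted_sdm` objects for one species on one grid.
#' @param weighting `"auc"` (default) or `"uniform"`.
#' @return An `ensemble_sdm`: fields `species`, `members`, `algorithms`,
#'   `weights`, `suitability`, `threshold`, `metrics`, `importance`, `spec`.
#' @export
combine_sdm <- function(members, weighting = c("auc", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(members) < 2) stop("an ensemble needs at least 2 members", call. = FALSE)
  species <- unique(vapply(members, function(m) m$species, character(1)))
  if (length(species) != 1) stop("members model different species", call. = FALSE)
  for (m in members[-1]) {
    if (!same_geometry(members[[1]]$spec, m$spec)) {
      stop("members are fitted on mismatched grids", call. = FALSE)
    }
  }
  w <- switch(weighting,
              uniform = rep(1, length(members)),
              auc = vapply(members, function(m) m$cv_metrics$auc, numeric(1)))
  if (sum(w) <= 0) w <- rep(1, length(members))
  w <- w / sum(w)

  suit_mat <- vapply(members, function(m) m$suitability,
                     numeric(length(members[[1]]$suitability)))
  suitability <- as.numeric(suit_mat %*% w)

  train <- dplyr::distinct(
    dplyr::bind_rows(lapply(members, function(m) m$train[c("cell", "y")])),
    cell, .keep_all = TRUE)
  # combined predictions at the training cells: each member contributes its
  # cross-validated (out-of-fold) prediction where one exists, so the
  # threshold is calibrated on predictions not inflated by refit overfitting;
  # cells a member never trained on fall back to its suitability surface
  pred_mat <- vapply(members, function(m) {
    p <- m$suitability[train$cell]
    if ("cv_pred" %in% names(m$train)) {
      idx <- match(train$cell, m$train$cell)
      hit <- which(!is.na(idx))
      cvp <- m$train[["cv_pred"]][idx[hit]]
      ok <- !is.na(cvp)
      p[hit[ok]] <- cvp[ok]
    }
    p
  }, numeric(nrow(train)))
  pred <- as.numeric(pred_mat %*% w)
  metrics <- evaluate_predictions(pred, train$y)

  imp_mat <- vapply(members, function(m) m$importance,
                    numeric(length(members[[1]]$importance)))
  importance <- as.numeric(imp_mat %*% w)
  names(importance) <- names(members[[1]]$importance)
  if (sum(importance) > 0) importance <- 100 * importance / sum(importance)

  structure(
    list(species = species,
         members = members,
         algorithms = vapply(members, function(m) m$algorithm, character(1)),
         weights = w,
         suitability = suitability,
         threshold = metrics$threshold,
         metrics = metrics[setdiff(names(metrics), "threshold")],
         importance = importance,
         train = train,
         spec = members[[1]]$spec),
    class = "ensemble_sdm")
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat(sprintf("<ensemble_sdm> %s [%s]: threshold %.3f, apparent AUC %.3f\n",
              x$species, paste(x$algorithms, collapse = "-"), x$threshold,
              x$metrics$auc))
  invisible(x)
}

#' Pairwise correlation between member suitability maps
#'
#' @param ensemble An `ensemble_sdm`.
#' @return Symmetric Pearson correlation matrix over valid cells, with the
#'   member algorithm names as dimnames. A constant member map yields an
#'   undefined (`NA`) entry, flagged with a warning.
#' @export
inter_algorithm_correlation <- function(ensemble) {
  if (length(ensemble$members) < 2) stop("need at least 2 members", call. = FALSE)
  suit <- vapply(ensemble$members, function(m) m$suitability,
                 numeric(length(ensemble$suitability)))
  colnames(suit) <- ensemble$algorithms
  suit <- suit[stats::complete.cases(suit), , drop = FALSE]
  sds <- apply(suit, 2, stats::sd)
  out <- suppressWarnings(stats::cor(suit))
  diag(out) <- ifelse(sds == 0, NA_real_, 1)
  if (any(sds == 0)) {
    warning("constant member map(s) with undefined correlations: ",
            paste(colnames(suit)[sds == 0], collapse = ", "), call. = FALSE)
  }
  out
}

#' Search algorithm combinations on a species subset
#'
#' Evaluates every combination of the candidate algorithms of the given
#' sizes on a seeded random subset of species: members are combined with
#' [combine_sdm()], the stacked prediction is scored against the observed
#' occurrences at evaluation sites with [evaluate_community()], and
#' combinations are ranked by mean assemblage Jaccard, then mean prediction
#' success, then smaller mean species-richness error. The species subset
#' depends only on the seed and the set of species names, never on the
#' storage order of `fitted`.
#'
#' @param fitted Nested list: `fitted[[species]][[algorithm]]` is a
#'   `fitted_sdm` covering every candidate algorithm.
#' @param records Cleaned occurrence tibble used for community evaluation.
#' @param stack The [env_stack()] the models were fitted on.
#' @param sizes Ensemble sizes to try (default 3:5).
#' @param n_species Subset size (default 50, capped at available species).
#' @param weighting Passed to [combine_sdm()].
#' @param seed Integer seed for the subset draw.
#' @return Tibble leaderboard, one row per combination, ranked best first:
#'   `combo`, `size`, then `<metric>_mean` / `<metric>_sd` columns.
#' @export
search_combinations <- function(fitted, records, stack, sizes = 3:5,
                                n_species = 50, weighting = "auc", seed = 1) {
  all_species <- sort(names(fitted))
  algorithms <- sort(names(fitted[[all_species[1]]]))
  stopifnot(all(sizes %in% 3:5))
  n_species <- min(n_species, length(all_species))
  subset <- local_seed(substream_seed(seed, "ensemble"),
                       sort(sample(all_species, n_species)))
  combos <- purrr::list_flatten(purrr::map(
    sizes[sizes <= length(algorithms)],
    function(s) utils::combn(algorithms, s, simplify = FALSE)))
  rows <- purrr::map_dfr(combos, function(cmb) {
    ensembles <- lapply(subset, function(sp) {
      combine_sdm(fitted[[sp]][cmb], weighting = weighting)
    })
    ev <- evaluate_community(ensembles, records, stack)
    wide <- tidyr::pivot_wider(ev[c("metric", "mean", "sd")],
                               names_from = "metric",
                               values_from = c("mean", "sd"),
                               names_glue = "{metric}_{.value}")
    dplyr::bind_cols(
      tibble::tibble(combo = paste(cmb, collapse = "-"), size = length(cmb)),
      wide)
  })
  dplyr::arrange(rows, dplyr::desc(jaccard_mean),
                 dplyr::desc(prediction_success_mean),
                 species_richness_error_mean)
}

utils::globalVariables(c("jaccard_mean", "prediction_success_mean",
                         "species_richness_error_mean"))
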