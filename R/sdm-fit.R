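#' Cross-validated evaluation of one algorithm on one species
#'
#' Stratified k-fold cross-validation (folds preserve the class ratio),
#' repeated `n_reps` times with reshuffled folds. Each held-out fold is
#' scored at its own TSS-optimal threshold, and the returned metrics are
#' means over all folds and replicates. When a species has fewer presences
#' (or absences) than `k`, the fold count is lowered to the smaller class
#' size and a message is emitted.
#'
#' @param pa A `pa_set` from [generate_pseudo_absences()].
#' @param algorithm Algorithm name (see [sdm_algorithms()]).
#' @param k Number of folds (default 20).
#' @param n_reps Number of replicate fold shuffles (default 10).
#' @param seed Integer seed; results are fully deterministic given it.
#' @return One-row tibble of mean metrics (`auc`, `sensitivity`,
#'   `specificity`, `omission_rate`, `prop_correct`, `kappa`, `tss`,
#'   `jaccard`) with attributes `k_used` and `per_fold` (all fold rows).
#' @export
crossvalidate <- function(pa, algorithm, k = 20, n_reps = 10, seed = 1) {
  X <- as.data.frame(pa$data[pa$layers])
  y <- pa$data$y
  idx_pos <- which(y == 1)
  idx_neg <- which(y == 0)
  if (length(idx_pos) < 2 || length(idx_neg) < 2) {
    stop("cross-validation needs at least 2 presences and 2 absences", call. = FALSE)
  }
  k_used <- min(k, length(idx_pos), length(idx_neg))
  if (k_used < k) {
    message(sprintf("crossvalidate: k lowered from %d to %d (smallest class size)",
                    k, k_used))
  }
  adapter <- sdm_adapter(algorithm)
  rows <- list()
  oof <- matrix(NA_real_, length(y), n_reps)
  for (r in seq_len(n_reps)) {
    folds <- local_seed(substream_seed(seed, "cv", r), {
      f <- integer(length(y))
      f[idx_pos] <- sample(rep_len(seq_len(k_used), length(idx_pos)))
      f[idx_neg] <- sample(rep_len(seq_len(k_used), length(idx_neg)))
      f
    })
    for (fold in seq_len(k_used)) {
      test <- folds == fold
      fit <- adapter$fit(X[!test, , drop = FALSE], y[!test],
                         substream_seed(seed, "fit", r * 1000 + fold))
      pred <- adapter$predict(fit, X[test, , drop = FALSE])
      oof[test, r] <- pred
      rows[[length(rows) + 1]] <- evaluate_predictions(pred, y[test])
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(per_fold, dplyr::across(-threshold, mean))
  attr(out, "k_used") <- k_used
  attr(out, "per_fold") <- per_fold
  # per-row out-of-fold predictions, averaged over replicates: each training
  # cell predicted only by models that never saw it
  attr(out, "oof_pred") <- rowMeans(oof)
  out
}

#' Permutation importance of environmental predictors
#'
#' For each predictor, the column is permuted `n_reps` times and the raw
#' importance is the mean of `1 - r`, where `r` is the Pearson correlation
#' between the model's predictions on the intact and on the permuted data
#' (an undefined correlation counts as 0). Negative raw values are clipped
#' to 0 and the vector is normalised to percentages summing to 100; a model
#' whose predictions ignore the inputs gets all-zero importances.
#'
#' @param fit A `fitted_sdm` from [fit_species()], or a list with elements
#'   `model` and `algorithm`.
#' @param pa The `pa_set` the model was trained on.
#' @param n_reps Permutations per predictor (default 10).
#' @param seed Integer seed.
#' @return Named numeric vector of percentage importances over the layers.
#' @export
permutation_importance <- function(fit, pa, n_reps = 10, seed = 1) {
  adapter <- sdm_adapter(fit$algorithm)
  X <- as.data.frame(pa$data[pa$layers])
  base <- adapter$predict(fit$model, X)
  raw <- stats::setNames(numeric(length(pa$layers)), pa$layers)
  if (stats::sd(base) > 0) {
    for (v in pa$layers) {
      drops <- vapply(seq_len(n_reps), function(r) {
        Xp <- X
        Xp[[v]] <- local_seed(substream_seed(seed, "importance", r), sample(Xp[[v]]))
        pred <- adapter$predict(fit$model, Xp)
        r2 <- suppressWarnings(stats::cor(base, pred))
        1 - (if (is.na(r2)) 0 else r2)
      }, numeric(1))
      raw[v] <- mean(drops)
    }
  }
  raw[raw < 0] <- 0
  if (sum(raw) == 0) raw else 100 * raw / sum(raw)
}

#' Fit one species distribution model
#'
#' Runs the full single-algorithm workflow for one species: cross-validated
#' evaluation, a final refit on all training data, prediction of the
#' suitability surface over every valid grid cell, TSS-optimal threshold
#' selection on the in-sample predictions, and permutation variable
#' importance.
#'
#' @inheritParams crossvalidate
#' @param stack The [env_stack()] to predict over.
#' @return A `fitted_sdm` object: fields `species`, `algorithm`,
#'   `suitability` (numeric vector over grid cells, `NA` where invalid),
#'   `threshold`, `cv_metrics`, `importance`, `train` (tibble `cell`, `y`,
#'   `pred`), `model`, `spec`, `seed`.
#' @export
fit_species <- function(pa, algorithm, stack, k = 20, n_reps = 10, seed = 1) {
  y <- pa$data$y
  if (!any(y == 1) || !any(y == 0)) {
    stop("training data must contain both presences and absences", call. = FALSE)
  }
  adapter <- sdm_adapter(algorithm)
  X <- as.data.frame(pa$data[pa$layers])
  cv <- crossvalidate(pa, algorithm, k = k, n_reps = n_reps, seed = seed)
  model <- adapter$fit(X, y, substream_seed(seed, "fit", 0L))

  suitability <- rep(NA_real_, nrow(stack$data))
  valid <- which(stack$data$valid)
  suitability[valid] <- adapter$predict(
    model, as.data.frame(stack$data[valid, pa$layers, drop = FALSE]))

  in_sample <- suitability[pa$data$cell]
  threshold <- select_threshold(in_sample, y)
  fit <- structure(
    list(species = pa$species, algorithm = toupper(algorithm),
         suitability = suitability, threshold = threshold,
         cv_metrics = cv, importance = NULL,
         train = tibble::tibble(cell = pa$data$cell, y = y, pred = in_sample,
                                cv_pred = attr(cv, "oof_pred")),
         model = model, spec = stack$spec, seed = seed),
    class = "fitted_sdm")
  fit$importance <- permutation_importance(fit, pa, n_reps = n_reps, seed = seed)
  fit
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("<fitted_sdm> %s [%s]: cv AUC %.3f, TSS %.3f, threshold %.3f\n",
              x$species, x$algorithm, x$cv_metrics$auc, x$cv_metrics$tss,
              x$threshold))
  invisible(x)
}

#' Binary range surface of a fitted or ensemble model
#'
#' @param x A `fitted_sdm` or `ensemble_sdm`.
#' @return Logical vector over grid cells (`suitability >= threshold`,
#'   `NA` where the stack is invalid).
#' @export
binary_surface <- function(x) {
  ifelse(is.na(x$suitability), NA, x$suitability >= x$threshold)
}
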