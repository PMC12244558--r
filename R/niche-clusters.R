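#' Species-by-layer importance matrix
#'
#' Collects the ensemble-level permutation importances of a list of fitted
#' ensembles into a species x environmental-layer matrix of percentages
#' (each row sums to 100). All-zero rows (models insensitive to every
#' predictor) are excluded with a warning.
#'
#' @param ensembles List of `ensemble_sdm` or `fitted_sdm` objects.
#' @return Numeric matrix with species as rownames, layers as colnames.
#' @export
importance_matrix <- function(ensembles) {
  m <- t(vapply(ensembles, function(e) e$importance,
                numeric(length(ensembles[[1]]$importance))))
  rownames(m) <- vapply(ensembles, function(e) e$species, character(1))
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero importance profile(s) excluded: %s", sum(zero),
                    paste(rownames(m)[zero], collapse = ", ")), call. = FALSE)
    m <- m[!zero, , drop = FALSE]
  }
  m
}

#' PCA of importance profiles
#'
#' Principal component analysis of a species x variable matrix, centred and
#' (by default) scaled, i.e. an eigendecomposition of the correlation
#' matrix. With all components retained, scores times transposed loadings
#' reproduce the standardised data exactly.
#'
#' @param mat Numeric matrix (>= 2 rows and columns, no missing entries).
#' @param center,scale Standardisation toggles passed to [stats::prcomp()].
#' @return An `sdm_pca` object: `eigenvalues`, `loadings` (variable x
#'   component), `scores` (row x component), `explained` (cumulative
#'   proportion), plus the centring/scaling vectors.
#' @export
pca_importance <- function(mat, center = TRUE, scale = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need >= 2 rows and 2 columns", call. = FALSE)
  if (anyNA(mat)) stop("matrix must not contain missing entries", call. = FALSE)
  if (scale) {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance column(s) under scaling: ",
           paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  pc <- stats::prcomp(mat, center = center, scale. = scale)
  eig <- pc$sdev^2
  structure(
    list(eigenvalues = eig,
         loadings = pc$rotation,
         scores = pc$x,
         explained = cumsum(eig) / sum(eig),
         center = pc$center, scale = pc$scale, prcomp = pc),
    class = "sdm_pca")
}

#' @export
print.sdm_pca <- function(x, ...) {
  cat(sprintf("<sdm_pca> %d components; leading eigenvalues: %s\n",
              length(x$eigenvalues),
              paste(signif(utils::head(x$eigenvalues, 4), 3), collapse = ", ")))
  invisible(x)
}

# within-cluster inertia of a partition of score rows
within_inertia <- function(scores, groups) {
  sum(vapply(split(seq_len(nrow(scores)), groups), function(idx) {
    s <- scores[idx, , drop = FALSE]
    sum(sweep(s, 2, colMeans(s))^2)
  }, numeric(1)))
}

#' Hierarchical clustering on principal components
#'
#' Ward-linkage agglomerative clustering on the retained component scores
#' (HCPC-style, without the optional k-means consolidation step). By
#' default enough components to explain 80% of the variance are retained
#' (capped at 5). With `k = "auto"` the cut is chosen as the candidate
#' `k` in 2..10 with the largest relative drop of within-cluster inertia
#' between consecutive cuts; the procedure is fully deterministic.
#'
#' @param pca An `sdm_pca` from [pca_importance()].
#' @param n_components Number of leading components to cluster on
#'   (default: smallest number explaining >= 80% variance, at most 5).
#' @param k Number of clusters, or `"auto"`.
#' @return A `cluster_assignment`: `assignment` (tibble `species`,
#'   `cluster`), `k`, `linkage = "ward"`, `inertia` (tibble `k`,
#'   `within_inertia`, `relative_loss`), the `hclust` tree and the retained
#'   `scores`.
#' @export
hcpc_clusters <- function(pca, n_components = NULL, k = "auto") {
  if (is.null(n_components)) {
    n_components <- min(which(pca$explained >= 0.8), 5)
  }
  if (n_components > ncol(pca$scores)) {
    stop("n_components exceeds the available components", call. = FALSE)
  }
  scores <- pca$scores[, seq_len(n_components), drop = FALSE]
  n <- nrow(scores)
  if (!identical(k, "auto") && k > n) {
    stop("fewer species than requested clusters", call. = FALSE)
  }
  total <- sum(sweep(scores, 2, colMeans(scores))^2)
  if (total == 0) {
    warning("all profiles identical; returning a single cluster", call. = FALSE)
    return(structure(list(
      assignment = tibble::tibble(species = rownames(scores), cluster = 1L),
      k = 1L, linkage = "ward",
      inertia = tibble::tibble(k = 1L, within_inertia = 0, relative_loss = NA_real_),
      tree = NULL, scores = scores), class = "cluster_assignment"))
  }
  tree <- stats::hclust(stats::dist(scores), method = "ward.D2")
  k_max <- min(10L, n - 1L)
  wk <- vapply(seq_len(k_max), function(kk) {
    within_inertia(scores, stats::cutree(tree, kk))
  }, numeric(1))
  rel <- c(NA_real_, (wk[-length(wk)] - wk[-1]) / wk[-length(wk)])
  rel[!is.finite(rel)] <- NA_real_
  inertia <- tibble::tibble(k = seq_len(k_max), within_inertia = wk,
                            relative_loss = rel)
  if (identical(k, "auto")) {
    cand <- which(!is.na(rel) & seq_len(k_max) >= 2)
    k <- cand[which.max(rel[cand])]
  }
  groups <- stats::cutree(tree, k)
  structure(list(
    assignment = tibble::tibble(species = rownames(scores),
                                cluster = as.integer(groups)),
    k = as.integer(k), linkage = "ward", inertia = inertia,
    tree = tree, scores = scores), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters (Ward on %d components): sizes %s\n",
              x$k, ncol(x$scores),
              paste(table(x$assignment$cluster), collapse = ", ")))
  invisible(x)
}

#' Characterise importance clusters
#'
#' For each cluster: the mean importance of every variable, a standardised
#' between-cluster contrast (`(cluster mean - overall mean) / overall sd`,
#' so the variables that define the cluster rank first), and the
#' representative species (nearest to the cluster centroid in standardised
#' profile space; a singleton cluster's representative is itself).
#'
#' @param assignment A `cluster_assignment` from [hcpc_clusters()].
#' @param mat The species x variable importance matrix that was clustered.
#' @return List with `summary` (tibble `cluster`, `variable`,
#'   `mean_importance`, `contrast`, `rank`) and `representatives` (tibble
#'   `cluster`, `species`, `distance`).
#' @export
characterize_clusters <- function(assignment, mat) {
  mat <- as.matrix(mat)[assignment$assignment$species, , drop = FALSE]
  groups <- assignment$assignment$cluster
  overall_mean <- colMeans(mat)
  overall_sd <- apply(mat, 2, stats::sd)
  overall_sd[overall_sd == 0] <- 1
  std <- sweep(sweep(mat, 2, overall_mean), 2, overall_sd, "/")
  summary <- purrr::map_dfr(sort(unique(groups)), function(g) {
    mm <- colMeans(mat[groups == g, , drop = FALSE])
    contrast <- (mm - overall_mean) / overall_sd
    tibble::tibble(cluster = g, variable = names(mm),
                   mean_importance = unname(mm), contrast = unname(contrast),
                   rank = rank(-unname(contrast), ties.method = "first"))
  })
  representatives <- purrr::map_dfr(sort(unique(groups)), function(g) {
    idx <- which(groups == g)
    ctr <- colMeans(std[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(std[idx, , drop = FALSE], 2, ctr)^2))
    tibble::tibble(cluster = g,
                   species = assignment$assignment$species[idx[which.min(d)]],
                   distance = min(d))
  })
  list(summary = summary, representatives = representatives)
}
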