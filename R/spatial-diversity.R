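#' Regional one-way ANOVA with Tukey HSD on a richness surface
#'
#' Compares mean per-cell richness between user-defined regions with a
#' classical one-way ANOVA, followed by Tukey honest significant difference
#' intervals (studentized-range distribution, 95% family-wise confidence).
#'
#' @param richness A `richness_map` from [stack_binary()].
#' @param regions Region labels: either a character/factor vector over all
#'   grid cells (`NA` for unlabelled) or a tibble with columns `cell`,
#'   `region`.
#' @return A `regional_anova` object: `anova` (tibble with `term`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p.value`), `tukey` (tibble with
#'   `comparison`, `diff`, `conf.low`, `conf.high`, `p.adj`), `n_regions`
#'   and the underlying `stats::aov` fit.
#' @export
regional_anova <- function(richness, regions) {
  if (is.data.frame(regions)) {
    lab <- rep(NA_character_, length(richness$counts))
    lab[regions$cell] <- as.character(regions$region)
  } else {
    lab <- as.character(regions)
  }
  keep <- !is.na(richness$counts) & !is.na(lab)
  df <- data.frame(richness = richness$counts[keep], region = factor(lab[keep]))
  tab <- table(df$region)
  if (length(tab) < 2) stop("need at least 2 regions", call. = FALSE)
  if (any(tab < 2)) {
    stop("region(s) with fewer than 2 cells: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(richness ~ region, data = df)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    term = trimws(rownames(an)),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p.value = an$`Pr(>F)`
  )
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$region
  tukey_tbl <- tibble::tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"], conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"], p.adj = tk[, "p adj"]
  )
  structure(list(anova = anova_tbl, tukey = tukey_tbl,
                 n_regions = length(tab), fit = fit),
            class = "regional_anova")
}

#' @export
print.regional_anova <- function(x, ...) {
  cat(sprintf("<regional_anova> %d regions: F(%d, %d) = %.4g, p = %.3g\n",
              x$n_regions, x$anova$df[1], x$anova$df[2],
              x$anova$statistic[1], x$anova$p.value[1]))
  invisible(x)
}

#' Diversity gradient by ordinary least squares
#'
#' Regresses per-cell richness on the cell-center latitude (y) or longitude
#' (x). For very large grids a seeded random subsample of cells can be used.
#'
#' @param richness A `richness_map`.
#' @param axis `"latitude"` or `"longitude"`.
#' @param subsample Optional number of cells to subsample.
#' @param seed Seed for the subsample draw.
#' @return One-row tibble: `axis`, `beta` (species per unit coordinate),
#'   `t_stat`, `r_squared`, `f_stat`, `p`, `n`.
#' @export
gradient_regression <- function(richness, axis = c("latitude", "longitude"),
                                subsample = NULL, seed = 1) {
  axis <- match.arg(axis)
  ctr <- cell_centers(richness$spec)
  keep <- which(!is.na(richness$counts))
  if (!is.null(subsample) && subsample < length(keep)) {
    keep <- local_seed(substream_seed(seed, "diversity"),
                       sort(sample(keep, subsample)))
  }
  coord <- if (axis == "latitude") ctr$y[keep] else ctr$x[keep]
  if (length(keep) < 3 || length(unique(coord)) < 2) {
    stop("gradient regression needs >= 3 cells with coordinate variance", call. = FALSE)
  }
  response <- as.numeric(richness$counts[keep])
  if (stats::sd(response) == 0) {
    # a flat surface carries no gradient: slope 0, no variance explained
    return(tibble::tibble(axis = axis, beta = 0, t_stat = 0, r_squared = 0,
                          f_stat = 0, p = 1, n = length(keep)))
  }
  fit <- stats::lm(response ~ coord)
  sm <- summary(fit)
  tibble::tibble(
    axis = axis,
    beta = unname(stats::coef(fit)[2]),
    t_stat = sm$coefficients[2, "t value"],
    r_squared = sm$r.squared,
    f_stat = unname(sm$fstatistic[1]),
    p = sm$coefficients[2, "Pr(>|t|)"],
    n = length(keep)
  )
}

#' Rook-contiguity spatial weights on a grid
#'
#' Binary, symmetric, not row-standardised: cells sharing an edge get
#' weight 1.
#'
#' @param spec A [grid_spec()].
#' @param cells Integer indices of the cells to connect (e.g. valid cells).
#' @return Sparse symmetric matrix (`Matrix::dgCMatrix`) of dimension
#'   `length(cells)` in the order of `cells`.
#' @export
rook_weights <- function(spec, cells) {
  pos <- match(seq_len(spec$n_rows * spec$n_cols), cells)
  row <- (cells - 1L) %/% spec$n_cols + 1L
  col <- (cells - 1L) %% spec$n_cols + 1L
  edges <- list()
  right <- which(col < spec$n_cols)
  nb <- pos[cells[right] + 1L]
  ok <- !is.na(nb)
  edges$right <- cbind(right[ok], nb[ok])
  down <- which(row < spec$n_rows)
  nb <- pos[cells[down] + spec$n_cols]
  ok <- !is.na(nb)
  edges$down <- cbind(down[ok], nb[ok])
  ij <- do.call(rbind, edges)
  Matrix::sparseMatrix(i = c(ij[, 1], ij[, 2]), j = c(ij[, 2], ij[, 1]),
                       x = 1, dims = c(length(cells), length(cells)))
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the total weight. Expectation under no autocorrelation is
#' `-1/(n-1)`; the z-score and p-value use the normality approximation.
#' Invariant to adding a constant to, or positively rescaling, the values.
#'
#' @param values Numeric vector (e.g. per-cell richness at the weight
#'   matrix's cells); must be non-constant.
#' @param weights Sparse or dense symmetric non-negative weight matrix, e.g.
#'   from [rook_weights()].
#' @param alternative `"greater"` (default: positive autocorrelation),
#'   `"less"`, or `"two.sided"`.
#' @return One-row tibble: `I`, `expected`, `sd`, `z`, `p`, `n`.
#' @export
morans_i <- function(values, weights,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 3) stop("Moran's I needs n >= 3", call. = FALSE)
  if (any(is.na(values))) stop("`values` must not contain NA", call. = FALSE)
  z <- values - mean(values)
  if (sum(z^2) == 0) stop("Moran's I undefined for a constant surface", call. = FALSE)
  W <- Matrix::Matrix(weights, sparse = TRUE)
  S0 <- sum(W)
  if (S0 <= 0) stop("weights must contain at least one positive entry", call. = FALSE)
  cross <- as.numeric(Matrix::crossprod(z, W %*% z))
  I <- (n / S0) * cross / sum(z^2)
  expected <- -1 / (n - 1)
  S1 <- sum((W + Matrix::t(W))^2) / 2
  rs <- Matrix::rowSums(W)
  cs <- Matrix::colSums(W)
  S2 <- sum((rs + cs)^2)
  var_i <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - expected^2
  sd_i <- sqrt(var_i)
  zscore <- (I - expected) / sd_i
  p <- switch(alternative,
              greater = stats::pnorm(zscore, lower.tail = FALSE),
              less = stats::pnorm(zscore),
              two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE))
  tibble::tibble(I = I, expected = expected, sd = sd_i, z = zscore, p = p, n = n)
}

#' Moran's I of a richness surface with rook weights
#'
#' Convenience wrapper building binary rook weights over the valid cells of
#' the map (optionally a seeded subsample) and calling [morans_i()].
#'
#' @param richness A `richness_map` (or an [env_stack()] plus `layer`).
#' @param subsample Optional cap on the number of cells (a seeded random
#'   subsample keeps the grid's contiguity structure on the kept cells).
#' @param seed Seed for the subsample.
#' @inheritParams morans_i
#' @return One-row tibble as [morans_i()].
#' @export
morans_i_map <- function(richness, subsample = NULL, seed = 1,
                         alternative = "greater") {
  cells <- which(!is.na(richness$counts))
  if (!is.null(subsample) && subsample < length(cells)) {
    cells <- local_seed(substream_seed(seed, "diversity", 1L),
                        sort(sample(cells, subsample)))
  }
  W <- rook_weights(richness$spec, cells)
  morans_i(richness$counts[cells], W, alternative = alternative)
}
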