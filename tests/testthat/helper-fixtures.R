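# Small programmatic fixtures shared across the suite.

# stack with one layer from a matrix given in grid orientation
stack_from_matrix <- function(m, cell_size = 1, origin_x = 0,
                              origin_y = nrow(m) * cell_size, name = "v") {
  gs <- grid_spec(nrow(m), ncol(m), cell_size = cell_size,
                  origin_x = origin_x, origin_y = origin_y)
  env_stack(stats::setNames(list(m), name), gs)
}

# multi-layer stack from vectors laid out row-major on an nr x nc grid
stack_from_vectors <- function(nr, nc, ..., cell_size = 1) {
  gs <- grid_spec(nr, nc, cell_size = cell_size)
  layers <- lapply(list(...), function(v) matrix(v, nr, nc, byrow = TRUE))
  env_stack(layers, gs)
}

# hand-built pa_set from a design matrix and labels (cells are synthetic ids)
make_pa <- function(X, y, species = "Testus examplei") {
  X <- as.data.frame(X)
  structure(list(
    species = species,
    presence_cells = which(y == 1),
    absence_cells = which(y == 0),
    layers = names(X),
    data = dplyr::bind_cols(tibble::tibble(cell = seq_along(y), y = as.integer(y)), X)
  ), class = "pa_set")
}

# fabricated fitted_sdm with given suitability surface; enough structure for
# combine_sdm / stacking / importance collection without a real model
fake_fitted <- function(species, algorithm, suitability, spec, auc = 0.9,
                        threshold = 0.5, importance = NULL,
                        train_cells = NULL, train_y = NULL) {
  nl <- if (is.null(importance)) 2 else length(importance)
  if (is.null(importance)) {
    importance <- stats::setNames(rep(100 / nl, nl), paste0("L", seq_len(nl)))
  }
  if (is.null(train_cells)) {
    ord <- order(suitability, decreasing = TRUE)
    n <- max(2, floor(length(suitability) / 4))
    train_cells <- c(ord[seq_len(n)], rev(ord)[seq_len(n)])
    train_y <- rep(c(1L, 0L), each = n)
  }
  cv <- stacksdm:::evaluate_predictions(suitability[train_cells], train_y)
  cv$auc <- auc
  structure(list(
    species = species, algorithm = algorithm, suitability = suitability,
    threshold = threshold, cv_metrics = cv[setdiff(names(cv), "threshold")],
    importance = importance,
    train = tibble::tibble(cell = train_cells, y = train_y,
                           pred = suitability[train_cells]),
    model = NULL, spec = spec, seed = 0L
  ), class = "fitted_sdm")
}

# brute-force two-pass Pearson correlation (independent oracle)
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive-search TSS threshold (independent oracle for select_threshold)
threshold_brute <- function(pred, labels) {
  cand <- sort(unique(pred))
  tss <- vapply(cand, function(t) {
    sens <- mean(pred[labels == 1] >= t)
    spec <- mean(pred[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(tss)]
}

# cached small end-to-end run shared by several acceptance checks
e2e_cache <- new.env(parent = emptyenv())
run_default_scenario <- function(seed = 20260901) {
  key <- as.character(seed)
  if (!is.null(e2e_cache[[key]])) return(e2e_cache[[key]])
  sc <- build_scenario(seed = seed)
  rec <- suppressMessages(clean_occurrences(sc$occurrences, sc$stack))
  rec <- spatial_thin(rec, sc$stack$spec)
  rec <- filter_rare(rec)
  species <- sort(unique(rec$taxon))
  fitted <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    pa <- generate_pseudo_absences(rec, sc$stack, sp,
                                   seed = seed + 1000L + si)
    fitted[[sp]] <- suppressMessages(lapply(
      c(CTA = "CTA", RF = "RF", SVM = "SVM"),
      function(a) fit_species(pa, a, sc$stack, k = 20, n_reps = 10,
                              seed = seed + 2000L + si)))
  }
  ensembles <- lapply(fitted, combine_sdm)
  out <- list(scenario = sc, records = rec, species = species,
              fitted = fitted, ensembles = ensembles,
              richness = stack_binary(ensembles))
  e2e_cache[[key]] <- out
  out
}
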