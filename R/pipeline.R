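#' Validate a run configuration
#'
#' Schema and cross-field checks for the pipeline configuration; problems
#' are returned, never thrown, so a front-end can report them all at once.
#'
#' @param config A configuration list (see [run_pipeline()]) or the path to
#'   a YAML file holding one.
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character(0)
  say <- function(...) problems <<- c(problems, sprintf(...))

  if (is.null(config$seed) || !is.numeric(config$seed)) {
    say("`seed` must be an integer")
  }
  if (is.null(config$output_dir)) say("`output_dir` is missing")

  inp <- config$input
  if (is.null(inp) || (is.null(inp$synthetic) && is.null(inp$occurrences))) {
    say("`input` must provide either `synthetic` parameters or an `occurrences` path")
  }
  if (!is.null(inp$occurrences)) {
    for (f in c("occurrences", "layers", "taxonomy", "synonyms")) {
      p <- inp[[f]]
      if (!is.null(p) && !file.exists(p) && !dir.exists(p)) {
        say("input path `%s` does not exist: %s", f, p)
      }
    }
  }
  pre <- config$preprocessing
  thr <- pre$collinearity_threshold %||% 0.85
  if (!is.numeric(thr) || thr <= 0 || thr > 1) {
    say("`preprocessing$collinearity_threshold` must be in (0, 1]")
  }
  if (!is.null(pre$min_occurrences) && pre$min_occurrences < 1) {
    say("`preprocessing$min_occurrences` must be >= 1")
  }
  mod <- config$modelling
  k <- mod$k %||% 20
  if (!is.numeric(k) || k < 2) say("`modelling$k` must be >= 2")
  if (!is.null(mod$n_reps) && mod$n_reps < 1) say("`modelling$n_reps` must be >= 1")
  algos <- mod$algorithms %||% c("CTA", "RF", "SVM")
  unknown <- setdiff(toupper(algos), sdm_algorithms())
  if (length(unknown)) say("unknown algorithm(s): %s", paste(unknown, collapse = ", "))
  if (length(algos) < 2) say("`modelling$algorithms` needs >= 2 algorithms for an ensemble")
  w <- mod$weighting %||% "auc"
  if (!w %in% c("auc", "uniform")) say("`modelling$weighting` must be 'auc' or 'uniform'")
  problems
}

pipeline_stage <- function(name, expr) {
  message(sprintf("[%s] starting", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full stacked-SDM pipeline
#'
#' Executes prepare -> clean -> fit -> ensemble -> stack -> diversity ->
#' clusters from one configuration and writes maps, tables and JSON reports
#' into the output directory. All randomness flows from the root seed via
#' named substreams, so re-running the same configuration reproduces
#' identical outputs.
#'
#' Configuration (list or YAML path): `seed`; `output_dir`; `input` (either
#' `synthetic: {n_rows, n_cols, n_species, n_layers, records_per_species}`
#' or `occurrences`/`layers`/`taxonomy`/`synonyms` paths); `preprocessing`
#' (`min_occurrences`, `collinearity_threshold`, `priority`); `modelling`
#' (`algorithms`, `k`, `n_reps`, `n_strata`, `buffer_cells`, `weighting`);
#' `stacking` (`uncertainty`, `endemism` toggles); `analysis`
#' (`gradient_axes`, `morans`, `subsample`); `clusters` (`k`).
#'
#' @param config Configuration list or path to a YAML file.
#' @return Invisibly, a list with the fitted objects and result tables
#'   (`stack`, `records`, `fitted`, `ensembles`, `richness`, `community`,
#'   `diversity`, `clusters`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  seed <- as.integer(config$seed)
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pre <- config$preprocessing %||% list()
  mod <- config$modelling %||% list()
  algos <- toupper(mod$algorithms %||% c("CTA", "RF", "SVM"))
  k <- mod$k %||% 20
  n_reps <- mod$n_reps %||% 10
  weighting <- mod$weighting %||% "auc"

  env <- pipeline_stage("prepare", {
    if (!is.null(config$input$synthetic)) {
      sy <- config$input$synthetic
      scenario <- build_scenario(
        spec = grid_spec(sy$n_rows %||% 100, sy$n_cols %||% 100,
                         cell_size = sy$cell_size %||% 0.05,
                         origin_x = sy$origin_x %||% 48,
                         origin_y = sy$origin_y %||% 30),
        n_species = sy$n_species %||% 20,
        n_layers = sy$n_layers %||% 15,
        records_per_species = sy$records_per_species %||% 60,
        seed = substream_seed(seed, "simulate"))
      list(stack = scenario$stack, records_raw = scenario$occurrences,
           scenario = scenario, synonyms = NULL)
    } else {
      stack <- read_env_stack(config$input$layers)
      syn <- if (!is.null(config$input$synonyms)) {
        tibble::as_tibble(utils::read.csv(config$input$synonyms))
      }
      list(stack = read_env_stack(config$input$layers),
           records_raw = read_occurrences(config$input$occurrences),
           scenario = NULL, synonyms = syn)
    }
  })
  stack <- env$stack

  stack <- pipeline_stage("screen", {
    thr <- pre$collinearity_threshold %||% 0.85
    priority <- pre$priority %||% env_layer_names(stack)
    corr <- pairwise_correlation(stack)
    retained <- screen_collinear(corr, priority, threshold = thr)
    message(sprintf("[screen] retained %d/%d layers", length(retained),
                    length(env_layer_names(stack))))
    select_layers(stack, retained)
  })

  records <- pipeline_stage("clean", {
    rec <- clean_occurrences(env$records_raw, stack, synonyms = env$synonyms)
    rec <- spatial_thin(rec, stack$spec)
    filter_rare(rec, min_occurrences = pre$min_occurrences %||% 4)
  })
  species <- sort(unique(records$taxon))
  if (!length(species)) stop("stage 'clean' failed: no species left after filtering", call. = FALSE)

  fitted <- pipeline_stage("fit", {
    out <- list()
    for (si in seq_along(species)) {
      sp <- species[si]
      n_pres <- length(unique(records$cell[records$taxon == sp]))
      pa_cache <- list()
      out[[sp]] <- list()
      n_eligible <- sum(stack$data$valid) - n_pres
      for (algo in algos) {
        n_abs <- min(mod$n_absences %||% default_n_absences(algo, n_pres),
                     n_eligible)
        key <- as.character(n_abs)
        if (is.null(pa_cache[[key]])) {
          pa_cache[[key]] <- generate_pseudo_absences(
            records, stack, sp, n_absences = n_abs,
            n_strata = mod$n_strata %||% 5,
            buffer_cells = mod$buffer_cells %||% 0,
            seed = substream_seed(seed, "absences", si))
        }
        out[[sp]][[algo]] <- fit_species(
          pa_cache[[key]], algo, stack, k = k, n_reps = n_reps,
          seed = substream_seed(seed, "fit", si))
      }
    }
    out
  })

  ensembles <- pipeline_stage("ensemble", {
    lapply(fitted, function(members) combine_sdm(members, weighting = weighting))
  })

  stk <- pipeline_stage("stack", {
    res <- list(richness = stack_binary(ensembles))
    if (isTRUE(config$stacking$uncertainty %||% TRUE)) {
      res$uncertainty <- uncertainty_map(ensembles)
    }
    if (isTRUE(config$stacking$endemism %||% TRUE)) {
      res$endemism <- endemism_map(ensembles)
    }
    res$community <- evaluate_community(ensembles, records, stack)
    res
  })

  diversity <- pipeline_stage("diversity", {
    axes <- config$analysis$gradient_axes %||% c("latitude", "longitude")
    res <- list(gradients = purrr::map_dfr(axes, function(a) {
      gradient_regression(stk$richness, axis = a,
                          subsample = config$analysis$subsample, seed = seed)
    }))
    if (isTRUE(config$analysis$morans %||% TRUE)) {
      res$morans <- morans_i_map(stk$richness,
                                 subsample = config$analysis$subsample,
                                 seed = seed)
    }
    res
  })

  clusters <- pipeline_stage("clusters", {
    imp <- importance_matrix(ensembles)
    if (nrow(imp) >= 3) {
      pca <- pca_importance(imp)
      cl <- hcpc_clusters(pca, k = config$clusters$k %||% "auto")
      list(pca = pca, clusters = cl,
           profile = characterize_clusters(cl, imp), importance = imp)
    } else {
      message("[clusters] skipped: fewer than 3 species with importance profiles")
      list(importance = imp)
    }
  })

  paths <- pipeline_stage("write", {
    species_metrics <- purrr::map_dfr(fitted, function(members) {
      purrr::map_dfr(members, glance)
    })
    utils::write.csv(species_metrics, file.path(outdir, "species_metrics.csv"),
                     row.names = FALSE)
    ensemble_metrics <- purrr::map_dfr(ensembles, glance)
    utils::write.csv(ensemble_metrics, file.path(outdir, "ensemble_metrics.csv"),
                     row.names = FALSE)
    importance <- purrr::map_dfr(ensembles, tidy)
    utils::write.csv(importance, file.path(outdir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(stk$richness), file.path(outdir, "richness.csv"),
                     row.names = FALSE)
    utils::write.csv(stk$community, file.path(outdir, "community_eval.csv"),
                     row.names = FALSE)
    if (!is.null(clusters$clusters)) {
      utils::write.csv(clusters$clusters$assignment,
                       file.path(outdir, "clusters.csv"), row.names = FALSE)
    }
    report <- list(
      seed = seed,
      n_species = length(species),
      algorithms = algos,
      mean_cv_auc = mean(species_metrics$auc),
      community = as.list(stats::setNames(stk$community$mean, stk$community$metric)),
      gradients = diversity$gradients,
      morans = diversity$morans
    )
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(outdir = outdir, report = file.path(outdir, "report.json"))
  })

  invisible(list(stack = stack, records = records, scenario = env$scenario,
                 fitted = fitted, ensembles = ensembles,
                 richness = stk$richness, uncertainty = stk$uncertainty,
                 endemism = stk$endemism, community = stk$community,
                 diversity = diversity, clusters = clusters, paths = paths))
}
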