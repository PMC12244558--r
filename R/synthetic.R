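#' Default value ranges for a simulated coastal-shelf stack
#'
#' Fifteen named layers with ranges typical of a shallow, hypersaline
#' semi-enclosed basin: bathymetry -127..-2 m, sea-surface and bottom
#' temperatures (degC), salinity 37.04-37.46, chlorophyll-a 0.73-12.99
#' mg/m3, dissolved oxygen 4.51-5.02 ml/l, iron (mol/m3), silicate /
#' phosphate / nitrate (umol/l) and pH. Requesting more than 15 layers
#' appends generic unit-range layers.
#'
#' @param n_layers Number of layers wanted.
#' @return Named list of `c(min, max)` ranges.
#' @export
default_layer_ranges <- function(n_layers = 15) {
  base <- list(
    bathymetry = c(-127, -2),
    sst_min = c(13.09, 24.23),
    sst_mean = c(24.23, 29.45),
    sst_max = c(29.45, 37.60),
    temp_bottom_min = c(12.5, 23.5),
    temp_bottom_mean = c(20.0, 28.5),
    temp_bottom_max = c(26.0, 36.0),
    salinity = c(37.04, 37.46),
    chlorophyll_a = c(0.73, 12.99),
    dissolved_oxygen = c(4.51, 5.02),
    iron = c(1e-4, 2e-3),
    silicate = c(1.80, 2.79),
    phosphate = c(0.15, 0.42),
    nitrate = c(0.81, 2.58),
    ph = c(8.13, 8.14)
  )
  if (n_layers <= length(base)) return(base[seq_len(n_layers)])
  extra <- stats::setNames(
    replicate(n_layers - length(base), c(0, 1), simplify = FALSE),
    paste0("env", seq.int(length(base) + 1, n_layers)))
  c(base, extra)
}

# separable Gaussian smoothing of a matrix; radius in cells (kernel +-radius)
gaussian_smooth <- function(m, radius) {
  if (radius <= 0) return(m)
  s <- radius / 2
  k <- stats::dnorm(seq(-radius, radius), sd = s)
  smooth_axis <- function(n) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - radius):min(n, i + radius)
      w <- k[j - i + radius + 1]
      A[i, j] <- w / sum(w)
    }
    A
  }
  smooth_axis(nrow(m)) %*% m %*% t(smooth_axis(ncol(m)))
}

rescale01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0.5, nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng)
}

#' Simulate a spatially autocorrelated environmental stack
#'
#' Each layer is a mixture `gradient_weight * ramp + (1 - gradient_weight) *
#' noise` of a linear ramp (alternating north-south / east-west orientation
#' across layers) and Gaussian-smoothed white noise (kernel radius
#' `autocorr_range_cells`; radius 0 gives pure white noise), affinely
#' rescaled to the layer's value range. Deterministic under `seed`.
#'
#' @param spec A [grid_spec()].
#' @param n_layers Number of layers (default 15).
#' @param autocorr_range_cells Smoothing kernel radius in cells.
#' @param gradient_weight Weight of the deterministic ramp in `[0, 1]`;
#'   1 gives exact affine surfaces.
#' @param value_ranges Named list of `c(min, max)` per layer; default
#'   [default_layer_ranges()].
#' @param seed Integer seed.
#' @return An [env_stack()].
#' @export
generate_env_stack <- function(spec, n_layers = 15, autocorr_range_cells = 5,
                               gradient_weight = 0.25, value_ranges = NULL,
                               seed = 1) {
  stopifnot(n_layers >= 1, gradient_weight >= 0, gradient_weight <= 1)
  value_ranges <- value_ranges %||% default_layer_ranges(n_layers)
  if (length(value_ranges) != n_layers) {
    stop("`value_ranges` must provide one range per layer", call. = FALSE)
  }
  bad <- names(value_ranges)[vapply(value_ranges,
                                    function(r) r[1] >= r[2], logical(1))]
  if (length(bad)) {
    stop("invalid value range (min >= max) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nr <- spec$n_rows
  nc <- spec$n_cols
  layers <- local_seed(seed, {
    lapply(seq_len(n_layers), function(i) {
      ramp <- if (i %% 2 == 1) {
        matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)   # north-south
      } else {
        matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc) # east-west
      }
      noise <- rescale01(gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                                         autocorr_range_cells))
      field <- gradient_weight * ramp + (1 - gradient_weight) * noise
      rng <- value_ranges[[i]]
      rng[1] + rescale01(field) * diff(rng)
    })
  })
  env_stack(stats::setNames(layers, names(value_ranges)), spec)
}

#' Define a virtual species niche
#'
#' @param responses Tibble with columns `layer`, `optimum`, `breadth`
#'   (breadths strictly positive); layers absent from it respond flat.
#' @param prevalence Target occupied fraction of the valid area, in (0, 1].
#' @return A `niche_definition` list.
#' @export
niche_definition <- function(responses, prevalence = 0.15) {
  stopifnot(nrow(responses) >= 1, all(responses$breadth > 0),
            prevalence > 0, prevalence <= 1)
  structure(list(responses = tibble::as_tibble(responses),
                 prevalence = prevalence),
            class = "niche_definition")
}

#' Realise a virtual species on a landscape
#'
#' Suitability is the product of Gaussian responses
#' `exp(-0.5 * ((x - optimum) / breadth)^2)` over the niche's non-flat
#' layers, normalised by its maximum over valid cells (so the best cell
#' scores 1). The true range is the set of cells whose suitability reaches
#' the occupancy cutoff, the suitability quantile chosen so the occupied
#' fraction approximates the niche's target prevalence.
#'
#' @param niche A [niche_definition()].
#' @param stack An [env_stack()] containing every referenced layer.
#' @param name Species name (binomial style keeps cleaning happy).
#' @return A `virtual_species`: `name`, `niche`, `suitability` (vector over
#'   cells, max 1), `cutoff`, `true_binary` (logical vector), `range_size`.
#' @export
define_virtual_species <- function(niche, stack, name = "Virtualia exempli") {
  missing <- setdiff(niche$responses$layer, env_layer_names(stack))
  if (length(missing)) {
    stop("niche references unknown layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  suit <- rep(1, nrow(stack$data))
  for (i in seq_len(nrow(niche$responses))) {
    r <- niche$responses[i, ]
    x <- stack$data[[r$layer]]
    suit <- suit * exp(-0.5 * ((x - r$optimum) / r$breadth)^2)
  }
  suit[!stack$data$valid] <- NA_real_
  mx <- max(suit, na.rm = TRUE)
  if (mx == 0) stop("niche yields zero suitability everywhere", call. = FALSE)
  suit <- suit / mx
  cutoff <- stats::quantile(suit[stack$data$valid], 1 - niche$prevalence,
                            names = FALSE)
  true_binary <- !is.na(suit) & suit >= cutoff
  if (!any(true_binary)) stop("virtual species occupies no cell", call. = FALSE)
  structure(list(name = name, niche = niche, suitability = suit,
                 cutoff = cutoff, true_binary = true_binary,
                 range_size = sum(true_binary)),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> %s: %d-layer niche, range %d cells\n",
              x$name, nrow(x$niche$responses), x$range_size))
  invisible(x)
}

#' Sample presence-only occurrences of a virtual species
#'
#' Occupied cells are drawn with probability proportional to suitability
#' (with replacement, then deduplicated to the cell level; detection is
#' perfect). Record coordinates are cell centers; `depth_m` is filled from
#' a `bathymetry` layer when present.
#'
#' @param vs A `virtual_species`.
#' @param stack The [env_stack()] it lives on.
#' @param n Number of draws (>= 1) before deduplication.
#' @param seed Integer seed.
#' @return Occurrence tibble (`taxon`, `lon`, `lat`, `depth_m`,
#'   `source_id`, `cell`); every record lies inside the species' true range.
#' @export
sample_occurrences <- function(vs, stack, n, seed = 1) {
  stopifnot(n >= 1)
  occupied <- which(vs$true_binary)
  draws <- local_seed(seed, {
    if (length(occupied) == 1) rep(occupied, n)
    else sample(occupied, n, replace = TRUE, prob = vs$suitability[occupied])
  })
  cells <- unique(draws)
  ctr <- stack$data[cells, , drop = FALSE]
  tibble::tibble(
    taxon = vs$name,
    lon = ctr$x,
    lat = ctr$y,
    depth_m = if ("bathymetry" %in% names(ctr)) ctr$bathymetry else NA_real_,
    source_id = "synthetic",
    cell = cells
  )
}

# synthetic specific epithets: aa, ab, ...
synthetic_epithet <- function(i) {
  paste0(letters[(i - 1) %/% 26 + 1], letters[(i - 1) %% 26 + 1])
}

#' Build a full synthetic scenario with known truth
#'
#' Generates a landscape, draws virtual species with random Gaussian niches
#' (the number of niche layers is sampled from `niche_layer_probs`, by
#' default 1 or 2 layers with probabilities 0.7/0.3 — simple, separable
#' niches that sixty records can characterise, with single-layer species
#' plentiful enough to score importance recovery; optima uniform within
#' each layer's realised range; breadths uniform within `breadth_range` as
#' a fraction of the layer range; prevalence uniform within
#' `prevalence_range`), samples presence-only occurrences,
#' and records the ground truth: per-species niches, true binary ranges and
#' the true richness surface. The scenario is the test bed standing in for
#' a compiled occurrence dataset, with every quantity the pipeline should
#' recover known exactly.
#'
#' @param spec A [grid_spec()] (default 100 x 100 unit cells).
#' @param n_species Number of virtual species (default 20).
#' @param n_layers Number of environmental layers (default 15).
#' @param records_per_species Presence draws per species (default 60).
#' @param autocorr_range_cells,gradient_weight,value_ranges Passed to
#'   [generate_env_stack()].
#' @param niche_layer_probs Probabilities of a 1-, 2-, ... layer niche
#'   (vector of length up to the number of layers).
#' @param breadth_range Niche breadth bounds as fractions of a layer range.
#' @param prevalence_range Occupied-fraction bounds per species.
#' @param seed Integer root seed; all randomness derives from it.
#' @return A `synthetic_scenario`: `stack`, `species` (list of
#'   `virtual_species`), `occurrences` (tibble), `true_richness`
#'   (`richness_map`), `truth` (tibble `species`, `n_niche_layers`,
#'   `niche_layers`, `prevalence`, `range_size`), `seed`.
#' @export
build_scenario <- function(spec = grid_spec(100, 100, cell_size = 0.05,
                                            origin_x = 48, origin_y = 30),
                           n_species = 20, n_layers = 15,
                           records_per_species = 60,
                           autocorr_range_cells = 5, gradient_weight = 0.25,
                           value_ranges = NULL,
                           niche_layer_probs = c(0.7, 0.3),
                           breadth_range = c(0.08, 0.25),
                           prevalence_range = c(0.08, 0.20),
                           seed = 1) {
  stopifnot(n_species >= 1)
  stack <- generate_env_stack(spec, n_layers = n_layers,
                              autocorr_range_cells = autocorr_range_cells,
                              gradient_weight = gradient_weight,
                              value_ranges = value_ranges,
                              seed = substream_seed(seed, "simulate"))
  layer_names <- env_layer_names(stack)
  valid <- stack$data$valid
  species <- vector("list", n_species)
  occ <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    niche <- local_seed(substream_seed(seed, "simulate", s), {
      nl <- sample(seq_along(niche_layer_probs), 1, prob = niche_layer_probs)
      nl <- min(nl, length(layer_names))
      lyr <- sample(layer_names, nl)
      resp <- purrr::map_dfr(lyr, function(nm) {
        rng <- range(stack$data[[nm]][valid])
        tibble::tibble(layer = nm,
                       optimum = stats::runif(1, rng[1], rng[2]),
                       breadth = stats::runif(1, breadth_range[1],
                                              breadth_range[2]) * diff(rng))
      })
      niche_definition(resp, prevalence = stats::runif(1, prevalence_range[1],
                                                       prevalence_range[2]))
    })
    vs <- define_virtual_species(niche, stack,
                                 name = paste("Virtualia", synthetic_epithet(s)))
    species[[s]] <- vs
    occ[[s]] <- sample_occurrences(vs, stack, records_per_species,
                                   seed = substream_seed(seed, "sample", s))
    stopifnot(all(vs$true_binary[occ[[s]]$cell]))
  }
  occurrences <- dplyr::bind_rows(occ)
  counts <- rowSums(vapply(species, function(v) as.integer(v$true_binary),
                           integer(nrow(stack$data))))
  counts[!valid] <- NA_integer_
  true_richness <- structure(list(spec = spec, counts = as.integer(counts),
                                  n_species = n_species),
                             class = "richness_map")
  truth <- purrr::map_dfr(species, function(v) {
    tibble::tibble(species = v$name,
                   n_niche_layers = nrow(v$niche$responses),
                   niche_layers = paste(v$niche$responses$layer, collapse = ";"),
                   prevalence = v$niche$prevalence,
                   range_size = v$range_size)
  })
  structure(list(stack = stack, species = species, occurrences = occurrences,
                 true_richness = true_richness, truth = truth, seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> %d species, %d layers, %d x %d grid, %d occurrences (seed %d)\n",
              length(x$species), length(env_layer_names(x$stack)),
              x$stack$spec$n_rows, x$stack$spec$n_cols,
              nrow(x$occurrences), x$seed))
  invisible(x)
}

#' Serialise a scenario to plain-text files
#'
#' Writes the layer grids and manifest ([write_env_stack()]), the occurrence
#' CSV, a truth CSV (species, niche layers, prevalence, range size) and a
#' JSON provenance file with the seed.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_env_stack(scenario$stack, file.path(dir, "layers"))
  utils::write.csv(scenario$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = scenario$seed,
                            n_species = length(scenario$species)),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
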