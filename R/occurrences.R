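#' Read an occurrence table
#'
#' Expected CSV columns: `taxon`, `lon`, `lat`, and optionally `depth_m`
#' (metres, non-positive below sea level) and `source_id`.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return Tibble of occurrence records.
#' @export
read_occurrences <- function(path) {
  dat <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           encoding = "UTF-8"))
  required <- c("taxon", "lon", "lat")
  missing <- setdiff(required, names(dat))
  if (length(missing)) {
    stop("occurrence file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"depth_m" %in% names(dat)) dat$depth_m <- NA_real_
  if (!"source_id" %in% names(dat)) dat$source_id <- NA_character_
  dat
}

#' Read a taxonomy table
#'
#' Columns: `species`, `genus`, `family`, `superfamily`, `order`,
#' `wall_type` (hyaline, porcelaneous or agglutinated).
#'
#' @param path Path to a CSV file.
#' @return Tibble with one row per species.
#' @export
read_taxonomy <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    encoding = "UTF-8"))
}

# species-level binomial: exactly two tokens, lowercase alphabetic epithet
# that is not an open-nomenclature marker
is_species_level <- function(taxon) {
  parts <- strsplit(trimws(taxon), "\\s+")
  vapply(parts, function(p) {
    length(p) == 2 &&
      grepl("^[A-Za-z][a-z-]*$", p[2]) &&
      !tolower(p[2]) %in% c("sp", "spp", "sp.", "spp.", "cf", "aff", "indet")
  }, logical(1))
}

#' Clean an occurrence table against an environmental stack
#'
#' Applies, in order: local synonym standardisation (`old_name` ->
#' `accepted_name`), removal of exact duplicate rows, removal of records
#' with missing or out-of-range coordinates, removal of records falling
#' outside the stack extent or on nodata cells, and removal of taxa not
#' resolvable to species level (single words or open nomenclature such as
#' "Ammonia sp."). Nothing errors; every drop is counted in the
#' `"drop_log"` attribute and reported via a message.
#'
#' @param records Occurrence tibble (`taxon`, `lon`, `lat`, ...).
#' @param stack An [env_stack()] defining the usable extent.
#' @param synonyms Optional tibble with columns `old_name`, `accepted_name`.
#' @return The cleaned tibble with an added `cell` column and a `drop_log`
#'   attribute (tibble of `reason`, `n`).
#' @export
clean_occurrences <- function(records, stack, synonyms = NULL) {
  log <- list()
  if (!is.null(synonyms) && nrow(synonyms)) {
    idx <- match(records$taxon, synonyms$old_name)
    hit <- !is.na(idx)
    records$taxon[hit] <- synonyms$accepted_name[idx[hit]]
  }
  n0 <- nrow(records)
  records <- dplyr::distinct(records)
  log$duplicate <- n0 - nrow(records)

  ok_coord <- !is.na(records$lon) & !is.na(records$lat) &
    records$lon >= -180 & records$lon <= 180 &
    records$lat >= -90 & records$lat <= 90
  log$bad_coordinates <- sum(!ok_coord)
  records <- records[ok_coord, , drop = FALSE]

  cell <- point_to_cell(stack$spec, records$lon, records$lat)
  on_grid <- !is.na(cell) & stack$data$valid[ifelse(is.na(cell), 1L, cell)]
  log$off_grid_or_nodata <- sum(!on_grid)
  records <- records[on_grid, , drop = FALSE]
  records$cell <- cell[on_grid]

  sp_level <- is_species_level(records$taxon)
  log$not_species_level <- sum(!sp_level)
  records <- records[sp_level, , drop = FALSE]

  log_tbl <- tibble::tibble(reason = names(log), n = unlist(log, use.names = FALSE))
  dropped <- sum(log_tbl$n)
  if (dropped > 0) {
    message(sprintf("clean_occurrences: dropped %d record(s) [%s]", dropped,
                    paste(sprintf("%s: %d", log_tbl$reason, log_tbl$n),
                          collapse = ", ")))
  }
  attr(records, "drop_log") <- log_tbl
  records
}

#' Spatially thin occurrences to one record per species per grid cell
#'
#' Records are first ordered by `source_id` (then original row order) so the
#' kept record is independent of incidental input shuffling; the first record
#' per species-cell pair is retained.
#'
#' @param records Cleaned occurrence tibble.
#' @param spec A [grid_spec()] defining the thinning unit (the analysis cell).
#' @return Thinned tibble with a `cell` column.
#' @export
spatial_thin <- function(records, spec) {
  if (!nrow(records)) return(records)
  if (!"cell" %in% names(records)) {
    records$cell <- point_to_cell(spec, records$lon, records$lat)
  }
  records$.row <- seq_len(nrow(records))
  records <- dplyr::arrange(records, dplyr::across(dplyr::any_of("source_id")), .row)
  records <- dplyr::distinct(records, taxon, cell, .keep_all = TRUE)
  records$.row <- NULL
  records
}

#' Drop species with too few thinned occurrences
#'
#' @param records Thinned occurrence tibble.
#' @param min_occurrences Minimum number of thinned records a species needs
#'   to be kept. The default 4 removes species with three or fewer records.
#' @return Filtered tibble.
#' @export
filter_rare <- function(records, min_occurrences = 4) {
  if (!nrow(records)) return(records)
  dplyr::filter(dplyr::group_by(records, taxon),
                dplyr::n() >= min_occurrences) |>
    dplyr::ungroup()
}

#' Per-family default pseudo-absence counts
#'
#' Regression-family algorithms (GLM, GAM, MARS) default to 1000 background
#' points (capped at the number of eligible cells at draw time);
#' classification-family algorithms (CTA, RF, GBM, SVM, ANN, MAXENT) default
#' to as many pseudo-absences as presences.
#'
#' @param algorithm Algorithm name.
#' @param n_presences Number of presence cells for the species.
#' @return Integer number of pseudo-absences to draw.
#' @export
default_n_absences <- function(algorithm, n_presences) {
  if (toupper(algorithm) %in% c("GLM", "GAM", "MARS")) 1000L else as.integer(n_presences)
}

#' Generate spatially stratified pseudo-absences for one species
#'
#' Absence cells are drawn without replacement from valid cells that are not
#' presence cells and lie outside a Chebyshev buffer of `buffer_cells` around
#' any presence. Draws are allocated across an `n_strata` x `n_strata`
#' partition of the grid proportionally to each block's count of eligible
#' cells (floor allocation; remainders go to the blocks with the largest
#' eligibility, ties by block order), which spreads the background sample
#' over the whole landscape. Fully deterministic under `seed`.
#'
#' @param records Occurrence tibble containing (at least) the target species,
#'   with a `cell` column or `lon`/`lat` coordinates.
#' @param stack An [env_stack()].
#' @param species Species name to build the set for.
#' @param n_absences Number of pseudo-absences; defaults to the number of
#'   presence cells (see [default_n_absences()]).
#' @param n_strata Blocks per axis for the geographic stratification.
#' @param buffer_cells Chebyshev exclusion radius around presences, in cells.
#' @param seed Integer seed.
#' @return A `pa_set`: list with `species`, `presence_cells`,
#'   `absence_cells`, `layers`, and `data` (tibble `cell`, `y`, one column
#'   per environmental layer; `y` = 1 for presence rows).
#' @export
generate_pseudo_absences <- function(records, stack, species,
                                     n_absences = NULL, n_strata = 5,
                                     buffer_cells = 0, seed = 1) {
  rec <- records[records$taxon == species, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("no records for species '%s'", species), call. = FALSE)
  if (!"cell" %in% names(rec)) {
    rec$cell <- point_to_cell(stack$spec, rec$lon, rec$lat)
  }
  presence <- sort(unique(rec$cell[!is.na(rec$cell) & stack$data$valid[rec$cell]]))
  if (!length(presence)) stop("species has no presence cell on the valid grid", call. = FALSE)

  spec <- stack$spec
  excluded <- rep(FALSE, nrow(stack$data))
  excluded[presence] <- TRUE
  if (buffer_cells > 0) {
    pr <- stack$data$row[presence]
    pc <- stack$data$col[presence]
    for (i in seq_along(presence)) {
      rows <- max(1, pr[i] - buffer_cells):min(spec$n_rows, pr[i] + buffer_cells)
      cols <- max(1, pc[i] - buffer_cells):min(spec$n_cols, pc[i] + buffer_cells)
      excluded[as.vector(outer((rows - 1) * spec$n_cols, cols, "+"))] <- TRUE
    }
  }
  eligible <- which(stack$data$valid & !excluded)
  if (is.null(n_absences)) n_absences <- length(presence)
  n_absences <- as.integer(n_absences)
  if (length(eligible) < n_absences) {
    stop(sprintf(
      "only %d eligible background cells for %d requested pseudo-absences (shortfall %d)",
      length(eligible), n_absences, n_absences - length(eligible)), call. = FALSE)
  }

  block_of <- function(cells) {
    sr <- ceiling(stack$data$row[cells] * n_strata / spec$n_rows)
    sc <- ceiling(stack$data$col[cells] * n_strata / spec$n_cols)
    (sr - 1) * n_strata + sc
  }
  blocks <- block_of(eligible)
  tally <- table(blocks)
  ids <- as.integer(names(tally))
  e <- as.integer(tally)
  alloc <- floor(n_absences * e / sum(e))
  # remainders: one at a time to the largest-eligibility blocks with headroom
  ord <- order(-e, ids)
  while (sum(alloc) < n_absences) {
    for (i in ord) {
      if (sum(alloc) == n_absences) break
      if (alloc[i] < e[i]) alloc[i] <- alloc[i] + 1
    }
  }
  absences <- local_seed(seed, {
    unlist(lapply(seq_along(ids), function(i) {
      pool <- eligible[blocks == ids[i]]
      if (alloc[i] == 0) return(integer(0))
      if (length(pool) == 1) return(pool)
      sample(pool, alloc[i])
    }))
  })
  absences <- sort(absences)

  cells <- c(presence, absences)
  data <- dplyr::bind_cols(
    tibble::tibble(cell = cells,
                   y = rep(c(1L, 0L), c(length(presence), length(absences)))),
    env_values_at(stack, cells)
  )
  structure(list(species = species,
                 presence_cells = presence,
                 absence_cells = absences,
                 layers = env_layer_names(stack),
                 data = data),
            class = "pa_set")
}

#' @export
print.pa_set <- function(x, ...) {
  cat(sprintf("<pa_set> %s: %d presences, %d pseudo-absences, %d predictors\n",
              x$species, length(x$presence_cells), length(x$absence_cells),
              length(x$layers)))
  invisible(x)
}

# round half-up to `digits` decimals (printed percentage convention)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Taxonomic composition of a species set
#'
#' Tallies the distinct species in `records` by order, family, genus and
#' wall type, with percentage shares of the total species count rounded
#' half-up to one decimal (so raw shares sum to 100 before rounding).
#'
#' @param records Occurrence tibble (only the `taxon` column is used).
#' @param taxonomy Taxonomy tibble covering every species in `records`.
#' @param ranks Ranks to tally; defaults to the taxonomy columns present
#'   among order, family, genus, wall_type.
#' @return Tibble with columns `rank`, `group`, `n_species`, `share`.
#' @export
summarize_composition <- function(records, taxonomy,
                                  ranks = intersect(c("order", "family",
                                                      "genus", "wall_type"),
                                                    names(taxonomy))) {
  species <- unique(records$taxon)
  missing <- setdiff(species, taxonomy$species)
  if (length(missing)) {
    stop("species missing from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tax <- taxonomy[match(species, taxonomy$species), , drop = FALSE]
  total <- length(species)
  purrr::map_dfr(ranks, function(rk) {
    # the group universe is the full taxonomy, so empty groups report 0.0%
    universe <- unique(taxonomy[[rk]])
    dplyr::count(tax, group = .data[[rk]], name = "n_species") |>
      tidyr::complete(group = universe,
                      fill = list(n_species = 0L)) |>
      dplyr::mutate(rank = rk,
                    share = round_half_up(100 * n_species / total, 1)) |>
      dplyr::select(rank, group, n_species, share) |>
      dplyr::arrange(dplyr::desc(n_species), group)
  })
}

#' Expand printed taxon tallies into a synthetic placeholder taxonomy
#'
#' Takes a table of published per-group species counts (rows with `rank`
#' equal to `order`, `genus` or `wall_type`, a `group` name, `n_species`,
#' and for genus rows the parent `order`) and fabricates a taxonomy with
#' exactly those tallies: real group names, synthetic filler species,
#' genus and family names. Useful for checking composition arithmetic
#' against published summaries without redistributing the underlying
#' occurrence dataset. All filler names are synthetic placeholders.
#'
#' @param counts Tibble with columns `rank`, `group`, `n_species` and
#'   optionally `order` (for genus rows).
#' @return Taxonomy tibble (`species`, `genus`, `family`, `superfamily`,
#'   `order`, `wall_type`) whose group tallies reproduce `counts`.
#' @export
taxonomy_from_counts <- function(counts) {
  orders <- counts[counts$rank == "order", , drop = FALSE]
  genera <- counts[counts$rank == "genus", , drop = FALSE]
  walls <- counts[counts$rank == "wall_type", , drop = FALSE]
  epithet <- function(i) {
    paste0("synthetica", letters[(i - 1) %/% 26 + 1], letters[(i - 1) %% 26 + 1])
  }
  rows <- list()
  for (k in seq_len(nrow(orders))) {
    ord <- orders$group[k]
    n_ord <- orders$n_species[k]
    gen_here <- genera[!is.na(genera$order) & genera$order == ord, , drop = FALSE]
    gen_names <- c(gen_here$group,
                   paste0(substr(ord, 1, nchar(ord) - 1), "gen", seq_len(200)))
    gen_quota <- c(gen_here$n_species, rep(8L, 200))
    made <- 0L
    g <- 1L
    while (made < n_ord) {
      take <- min(gen_quota[g], n_ord - made)
      gname <- gen_names[g]
      rows[[length(rows) + 1]] <- tibble::tibble(
        species = paste(gname, vapply(seq_len(take), epithet, character(1))),
        genus = gname,
        family = paste0(gname, "idae"),
        superfamily = paste0(substr(ord, 1, nchar(ord) - 1), "oidea"),
        order = ord
      )
      made <- made + take
      g <- g + 1L
    }
  }
  tax <- dplyr::bind_rows(rows)
  # wall types: conventional assignment by order, then adjust synthetic
  # filler species until the published wall tallies are matched exactly
  conventional <- c(Miliolida = "porcelaneous", Lituolida = "agglutinated",
                    Textulariida = "agglutinated", Astrorhizida = "agglutinated")
  tax$wall_type <- dplyr::coalesce(conventional[tax$order], "hyaline")
  if (nrow(walls)) {
    target <- stats::setNames(walls$n_species, walls$group)
    filler <- grepl("synthetica", tax$species)
    for (w in names(target)) {
      deficit <- target[[w]] - sum(tax$wall_type == w)
      while (deficit > 0) {
        surplus_walls <- names(target)[vapply(names(target), function(v) {
          sum(tax$wall_type == v) > target[[v]]
        }, logical(1))]
        cand <- which(filler & tax$wall_type %in% surplus_walls)
        if (!length(cand)) break
        mv <- utils::tail(cand, deficit)
        tax$wall_type[mv] <- w
        deficit <- target[[w]] - sum(tax$wall_type == w)
      }
    }
  }
  tax
}
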