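occ_row <- function(taxon, lon, lat, src = "s1") {
  tibble::tibble(taxon = taxon, lon = lon, lat = lat,
                 depth_m = NA_real_, source_id = src)
}

test_that("cleaning applies the four drop rules with a per-rule log", {
  st <- stack_from_vectors(5, 5, depth = -(1:25))
  good <- dplyr::bind_rows(
    occ_row("Ammonia tepida", 0.5, 4.5),
    occ_row("Ammonia tepida", 1.5, 4.5),
    occ_row("Elphidium advenum", 2.5, 3.5),
    occ_row("Elphidium advenum", 0.5, 0.5),
    occ_row("Bolivina striatula", 3.5, 2.5),
    occ_row("Bolivina striatula", 4.5, 1.5)
  )
  fixture <- dplyr::bind_rows(
    good,
    good[1, ], good[3, ],                       # 2 exact duplicates
    occ_row("Ammonia tepida", 40, 2.5),         # off the stack extent
    occ_row("Ammonia sp.", 1.5, 1.5)            # genus-level name
  )
  out <- suppressMessages(clean_occurrences(fixture, st))
  expect_equal(nrow(out), 6)
  log <- attr(out, "drop_log")
  expect_equal(log$n[log$reason == "duplicate"], 2)
  expect_equal(log$n[log$reason == "off_grid_or_nodata"], 1)
  expect_equal(log$n[log$reason == "not_species_level"], 1)

  # invalid coordinates are dropped, not treated as off-grid
  bad <- suppressMessages(clean_occurrences(occ_row("Ammonia tepida", 999, 2), st))
  expect_equal(nrow(bad), 0)
  expect_equal(attr(bad, "drop_log")$n[2], 1)

  # records on nodata cells are dropped
  mask <- matrix(TRUE, 5, 5); mask[1, 1] <- FALSE
  st2 <- env_stack(list(depth = matrix(-(1:25), 5, 5)),
                   grid_spec(5, 5, valid_mask = mask))
  out2 <- suppressMessages(clean_occurrences(occ_row("Ammonia tepida", 0.5, 4.5), st2))
  expect_equal(nrow(out2), 0)
})

test_that("synonym standardisation resolves names before the species-level filter", {
  st <- stack_from_vectors(3, 3, depth = -(1:9))
  syn <- tibble::tibble(old_name = "Rotalia beccarii",
                        accepted_name = "Ammonia beccarii")
  rec <- dplyr::bind_rows(occ_row("Rotalia beccarii", 0.5, 0.5),
                          occ_row("Ammonia beccarii", 0.5, 0.5))
  out <- suppressMessages(clean_occurrences(rec, st, synonyms = syn))
  # the synonym maps onto the accepted record and collapses as a duplicate
  expect_equal(nrow(out), 1)
  expect_equal(out$taxon, "Ammonia beccarii")
})

test_that("spatial thinning keeps one record per species per cell", {
  st <- stack_from_vectors(4, 4, depth = -(1:16))
  one_cell <- dplyr::bind_rows(lapply(1:5, function(i)
    occ_row("Ammonia tepida", 0.2 + i * 0.1, 3.5)))
  expect_equal(nrow(spatial_thin(one_cell, st$spec)), 1)

  shared <- dplyr::bind_rows(
    occ_row("Ammonia tepida", 1.5, 1.5),
    occ_row("Elphidium advenum", 1.5, 1.5),
    occ_row("Bolivina striatula", 1.5, 1.5))
  expect_equal(nrow(spatial_thin(shared, st$spec)), 3)

  # 8 records, 2 species, 3 cells: thinned count = occupied (species, cell) pairs
  fix <- dplyr::bind_rows(
    occ_row("Ammonia tepida", 0.5, 3.5), occ_row("Ammonia tepida", 0.6, 3.4),
    occ_row("Ammonia tepida", 1.5, 3.5),
    occ_row("Elphidium advenum", 0.5, 3.5), occ_row("Elphidium advenum", 0.7, 3.3),
    occ_row("Elphidium advenum", 2.5, 2.5), occ_row("Elphidium advenum", 2.6, 2.4),
    occ_row("Ammonia tepida", 1.6, 3.6))
  thin <- spatial_thin(fix, st$spec)
  key <- unique(paste(fix$taxon, point_to_cell(st$spec, fix$lon, fix$lat)))
  expect_equal(nrow(thin), length(key)) # 4 occupied pairs by enumeration
  expect_equal(nrow(thin), 4)
})

test_that("rare-species filtering uses the at-least-four rule boundary", {
  st <- stack_from_vectors(4, 4, depth = -(1:16))
  rec3 <- dplyr::bind_rows(lapply(1:3, function(i) occ_row("Rarus tres", i - 0.5, 3.5)))
  rec4 <- dplyr::bind_rows(lapply(1:4, function(i) occ_row("Commonus quattuor", i - 0.5, 2.5)))
  thin <- spatial_thin(dplyr::bind_rows(rec3, rec4), st$spec)
  kept <- filter_rare(thin)
  expect_false("Rarus tres" %in% kept$taxon)
  expect_equal(sum(kept$taxon == "Commonus quattuor"), 4)
  expect_equal(nrow(filter_rare(thin[0, ])), 0)
})

test_that("clean -> thin -> filter is idempotent", {
  st <- stack_from_vectors(6, 6, depth = -(1:36))
  set.seed(5)
  rec <- dplyr::bind_rows(lapply(1:40, function(i) {
    occ_row(sample(c("Ammonia tepida", "Elphidium advenum", "Bolivina striatula"), 1),
            runif(1, 0, 6), runif(1, 0, 6))
  }))
  once <- filter_rare(spatial_thin(suppressMessages(clean_occurrences(rec, st)), st$spec))
  twice <- filter_rare(spatial_thin(suppressMessages(clean_occurrences(once, st)), st$spec))
  expect_equal(twice, once)
})

test_that("pseudo-absence sampling honours eligibility, determinism and allocation", {
  st <- stack_from_vectors(4, 4, depth = -(1:16))
  rec <- dplyr::bind_rows(occ_row("Ammonia tepida", 0.5, 3.5),
                          occ_row("Ammonia tepida", 1.5, 3.5))
  rec$cell <- point_to_cell(st$spec, rec$lon, rec$lat)

  # all eligible cells requested: absences are exactly the complement
  pa <- generate_pseudo_absences(rec, st, "Ammonia tepida", n_absences = 14,
                                 n_strata = 2, seed = 9)
  expect_setequal(pa$absence_cells, setdiff(1:16, pa$presence_cells))
  expect_length(intersect(pa$presence_cells, pa$absence_cells), 0)
  expect_equal(nrow(pa$data), 16)

  # determinism under a fixed seed
  pa2 <- generate_pseudo_absences(rec, st, "Ammonia tepida", n_absences = 7,
                                  n_strata = 2, seed = 11)
  pa3 <- generate_pseudo_absences(rec, st, "Ammonia tepida", n_absences = 7,
                                  n_strata = 2, seed = 11)
  expect_identical(pa2$absence_cells, pa3$absence_cells)

  # proportional allocation: blocks (2x2 of 4 cells) have eligibility
  # {2, 4, 4, 4}; n = 7 -> floor(7 e/14) = {1, 2, 2, 2} = 7, no remainder
  blocks <- function(cells) {
    r <- (cells - 1) %/% 4 + 1; c <- (cells - 1) %% 4 + 1
    paste(ceiling(r / 2), ceiling(c / 2))
  }
  tab <- table(blocks(pa2$absence_cells))
  expect_equal(unname(tab[order(names(tab))]), c(1, 2, 2, 2),
               ignore_attr = TRUE)

  # remainder goes to the largest-eligibility block first: n = 8 -> {1,3,2,2}
  pa4 <- generate_pseudo_absences(rec, st, "Ammonia tepida", n_absences = 8,
                                  n_strata = 2, seed = 11)
  tab4 <- table(blocks(pa4$absence_cells))
  expect_equal(unname(tab4[order(names(tab4))]), c(1, 3, 2, 2),
               ignore_attr = TRUE)

  # shortfall errors with the count in the message
  expect_error(generate_pseudo_absences(rec, st, "Ammonia tepida",
                                        n_absences = 15, seed = 1),
               "eligible")
})

test_that("the Chebyshev buffer excludes cells around presences", {
  st <- stack_from_vectors(5, 5, depth = -(1:25))
  rec <- occ_row("Ammonia tepida", 2.5, 2.5) # center cell 13
  rec$cell <- point_to_cell(st$spec, rec$lon, rec$lat)
  pa <- generate_pseudo_absences(rec, st, "Ammonia tepida", n_absences = 16,
                                 buffer_cells = 1, seed = 2)
  ctr <- cell_centers(st$spec)
  cheb <- pmax(abs(ctr$row[pa$absence_cells] - 3), abs(ctr$col[pa$absence_cells] - 3))
  expect_true(all(cheb > 1))
})

test_that("composition shares are exact half-up percentages over the taxonomy universe", {
  tax <- tibble::tibble(
    species = paste("Genus", letters[1:8]),
    genus = c(rep("Quinqueloculina", 5), rep("Ammonia", 3)),
    family = "F", superfamily = "S",
    order = c(rep("Miliolida", 5), rep("Rotaliida", 3)),
    wall_type = c(rep("porcelaneous", 5), rep("hyaline", 3)))
  rec <- tibble::tibble(taxon = tax$species)
  comp <- summarize_composition(rec, tax)
  ord <- comp[comp$rank == "order", ]
  expect_equal(ord$share[ord$group == "Miliolida"], 62.5)
  expect_equal(ord$share[ord$group == "Rotaliida"], 37.5)
  expect_equal(sum(ord$n_species), 8)

  # a taxonomy group with no recorded species reports 0.0%
  comp2 <- summarize_composition(rec[1:5, ], tax)
  ord2 <- comp2[comp2$rank == "order", ]
  expect_equal(ord2$share[ord2$group == "Rotaliida"], 0)

  # shares sum to 100 within rounding slack per rank
  for (rk in unique(comp$rank)) {
    expect_lt(abs(sum(comp$share[comp$rank == rk]) - 100),
              0.1 * sum(comp$rank == rk) + 1e-9)
  }

  expect_error(summarize_composition(tibble::tibble(taxon = "Missing species"), tax),
               "Missing species")
})

test_that("half-up rounding matches the printed-percentage convention", {
  expect_equal(stacksdm:::round_half_up(5.25, 1), 5.3)
  expect_equal(stacksdm:::round_half_up(5.34999, 1), 5.3)
  expect_equal(stacksdm:::round_half_up(100 * 26 / 492, 1), 5.3)
  expect_equal(stacksdm:::round_half_up(100 * 270 / 492, 1), 54.9)
})
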