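test_that("simulated landscapes honour ranges, ramps and white-noise nulls", {
  gs <- grid_spec(40, 40)
  st <- generate_env_stack(gs, n_layers = 3, autocorr_range_cells = 0,
                          gradient_weight = 0, seed = 5)
  rng <- default_layer_ranges(3)
  for (nm in names(rng)) {
    v <- st$data[[nm]]
    expect_gte(min(v), rng[[nm]][1])
    expect_lte(max(v), rng[[nm]][2])
  }
  # pure white noise: Moran's I within 3 SE of -1/(n-1)
  W <- rook_weights(gs, seq_len(1600))
  mi <- morans_i(st$data[[names(rng)[1]]], W)
  expect_lt(abs(mi$I - mi$expected) / mi$sd, 3)

  # gradient_weight 1: an exact affine ramp recovered with R^2 = 1
  ramp <- generate_env_stack(gs, n_layers = 1, gradient_weight = 1, seed = 1)
  fake_rich <- structure(list(spec = gs, counts = ramp$data[[env_layer_names(ramp)[1]]],
                              n_species = 1L), class = "richness_map")
  fit <- suppressWarnings(gradient_regression(fake_rich, "latitude"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # layer 1 runs north-south: value spans its range over n_rows - 1 cells
  span <- diff(default_layer_ranges(1)[[1]])
  expect_equal(fit$beta, -span / 39, tolerance = 1e-9)

  # smoothing raises autocorrelation well above the white-noise null
  sm <- generate_env_stack(gs, n_layers = 1, autocorr_range_cells = 5,
                           gradient_weight = 0, seed = 5)
  expect_gt(morans_i(sm$data[[env_layer_names(sm)[1]]], W)$I, 0.5)

  expect_identical(generate_env_stack(gs, n_layers = 2, seed = 9)$data,
                   generate_env_stack(gs, n_layers = 2, seed = 9)$data)
  expect_error(generate_env_stack(gs, n_layers = 1,
                                  value_ranges = list(bad = c(2, 2))),
               "invalid value range")
})

test_that("virtual species follow the Gaussian product response", {
  # single layer taking values 0..4: optimum 2, breadth 1
  st <- stack_from_vectors(1, 5, L1 = 0:4)
  vs <- define_virtual_species(
    niche_definition(tibble::tibble(layer = "L1", optimum = 2, breadth = 1),
                     prevalence = 0.4), st)
  expect_equal(vs$suitability[3], 1) # cell at the optimum
  expect_equal(vs$suitability[4], exp(-0.5)) # one breadth away
  expect_equal(vs$suitability[5], exp(-2))

  # two-layer niche: cell at (opt1, opt2 + breadth2) scores exp(-0.5)
  st2 <- stack_from_vectors(1, 3, A = c(0, 0, 1), B = c(0, 1, 3))
  vs2 <- define_virtual_species(
    niche_definition(tibble::tibble(layer = c("A", "B"),
                                    optimum = c(0, 0), breadth = c(1, 1)),
                     prevalence = 0.5), st2)
  expect_equal(vs2$suitability[1], 1)
  expect_equal(vs2$suitability[2], exp(-0.5))
  expect_equal(vs2$suitability[3], exp(-0.5) * exp(-4.5))

  # occupancy cutoff approximates the prevalence target
  gs <- grid_spec(30, 30)
  big <- generate_env_stack(gs, n_layers = 2, seed = 3)
  vs3 <- define_virtual_species(
    niche_definition(tibble::tibble(layer = names(default_layer_ranges(2))[1],
                                    optimum = -60, breadth = 20),
                     prevalence = 0.15), big)
  expect_equal(vs3$range_size / 900, 0.15, tolerance = 0.02)

  expect_error(define_virtual_species(
    niche_definition(tibble::tibble(layer = "nope", optimum = 0, breadth = 1)),
    st), "unknown layer")
})

test_that("occurrence sampling stays in range, is seeded and converges", {
  st <- stack_from_vectors(5, 5, L1 = rep(1, 25))
  vs <- define_virtual_species(
    niche_definition(tibble::tibble(layer = "L1", optimum = 1, breadth = 1),
                     prevalence = 1), st)
  expect_equal(vs$range_size, 25) # constant suitability occupies everything

  occ <- sample_occurrences(vs, st, n = 4000, seed = 3)
  expect_true(all(vs$true_binary[occ$cell]))
  expect_identical(sample_occurrences(vs, st, 50, seed = 8)$cell,
                   sample_occurrences(vs, st, 50, seed = 8)$cell)

  # equal suitability: draw frequencies uniform within binomial tolerance
  draws <- local({
    set.seed(3)
    sample(which(vs$true_binary), 4000, replace = TRUE,
           prob = vs$suitability[vs$true_binary])
  })
  freq <- tabulate(draws, 25)
  expect_true(all(abs(freq - 160) < 4 * sqrt(4000 * (1 / 25) * (24 / 25))))

  # a huge sample visits the whole occupied set
  expect_setequal(sample_occurrences(vs, st, 2000, seed = 1)$cell, 1:25)
})

test_that("scenarios carry consistent ground truth", {
  sc1 <- build_scenario(spec = grid_spec(20, 20), n_species = 1, n_layers = 3,
                        records_per_species = 20, seed = 11)
  expect_equal(sc1$true_richness$counts,
               as.integer(sc1$species[[1]]$true_binary))

  sc <- build_scenario(spec = grid_spec(25, 25), n_species = 5, n_layers = 4,
                       records_per_species = 25, seed = 12)
  # conservation: richness total equals the summed range sizes
  expect_equal(sum(sc$true_richness$counts), sum(sc$truth$range_size))
  # every occurrence sits inside its species' true range
  for (v in sc$species) {
    cells <- sc$occurrences$cell[sc$occurrences$taxon == v$name]
    expect_true(all(v$true_binary[cells]))
  }
  # determinism of the whole scenario
  sc_b <- build_scenario(spec = grid_spec(25, 25), n_species = 5, n_layers = 4,
                         records_per_species = 25, seed = 12)
  expect_identical(sc$occurrences, sc_b$occurrences)
  expect_identical(sc$true_richness$counts, sc_b$true_richness$counts)
})

test_that("narrow disjoint niches produce non-overlapping ranges", {
  gs <- grid_spec(20, 20)
  st <- generate_env_stack(gs, n_layers = 1, gradient_weight = 1, seed = 2)
  nm <- names(default_layer_ranges(1))
  rng <- range(st$data[[nm]])
  vss <- lapply(c(0.15, 0.5, 0.85), function(q) {
    define_virtual_species(
      niche_definition(tibble::tibble(layer = nm,
                                      optimum = rng[1] + q * diff(rng),
                                      breadth = diff(rng) / 100),
                       prevalence = 0.05), st)
  })
  rich <- rowSums(vapply(vss, function(v) as.integer(v$true_binary),
                         integer(400)))
  expect_lte(max(rich), 1)
})

test_that("scenarios serialise to plain text and read back", {
  sc <- build_scenario(spec = grid_spec(10, 10), n_species = 2, n_layers = 2,
                       records_per_species = 10, seed = 4)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_true(file.exists(file.path(dir, "occurrences.csv")))
  rt <- read_env_stack(file.path(dir, "layers"))
  expect_equal(rt$data[env_layer_names(rt)], sc$stack$data[env_layer_names(sc$stack)])
})
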