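gs <- grid_spec(3, 4)
mk <- function(species, suit, threshold = 0.5, members = NULL) {
  if (is.null(members)) {
    fake_fitted(species, "RF", suit, gs, threshold = threshold)
  } else {
    e <- combine_sdm(members)
    e$threshold <- threshold
    e
  }
}

test_that("stacking sums hand-built binary maps and conserves range sizes", {
  b1 <- c(1, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0)
  b2 <- c(1, 0, 1, 0, 1, 0, 0, 0, 0, 0, 0, 0)
  b3 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  b4 <- rep(0, 12)
  b5 <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1)
  bins <- list(b1, b2, b3, b4, b5)
  ens <- purrr::imap(bins, function(b, i) mk(paste("Species", i), b, threshold = 1))
  rich <- stack_binary(ens)
  expect_equal(rich$counts, as.integer(b1 + b2 + b3 + b4 + b5))
  expect_equal(rich$counts[1], 3L) # three species share cell 1
  expect_equal(rich$counts[8], 0L)
  # conservation: total richness equals the summed range sizes
  expect_equal(sum(rich$counts), sum(unlist(bins)))

  # brute-force recount from the suitability/threshold rule
  brute <- rowSums(vapply(ens, function(e) e$suitability >= e$threshold,
                          logical(12)))
  expect_equal(rich$counts, as.integer(brute))

  bad <- fake_fitted("Species 9", "RF", runif(6), grid_spec(2, 3))
  expect_error(stack_binary(list(ens[[1]], bad)), "mismatched")
})

test_that("uncertainty averages the population SD across member algorithms", {
  same <- combine_sdm(list(fake_fitted("Species a", "CTA", rep(0.3, 12), gs),
                           fake_fitted("Species a", "RF", rep(0.3, 12), gs)))
  expect_equal(uncertainty_map(list(same))$values, rep(0, 12))

  two_point <- combine_sdm(list(fake_fitted("Species b", "CTA", rep(0, 12), gs),
                                fake_fitted("Species b", "RF", rep(1, 12), gs)))
  expect_equal(uncertainty_map(list(two_point))$values, rep(0.5, 12))

  # species SDs 0.1 and 0.3 average to 0.2: members at +-0.1 and +-0.3
  s1 <- combine_sdm(list(fake_fitted("Species c", "CTA", rep(0.4, 12), gs),
                         fake_fitted("Species c", "RF", rep(0.6, 12), gs)))
  s2 <- combine_sdm(list(fake_fitted("Species d", "CTA", rep(0.2, 12), gs),
                         fake_fitted("Species d", "RF", rep(0.8, 12), gs)))
  expect_equal(uncertainty_map(list(s1, s2))$values, rep(0.2, 12))

  single <- fake_fitted("Species e", "RF", runif(12), gs)
  expect_error(uncertainty_map(list(structure(list(members = list(single)),
                                             class = "ensemble_sdm"))),
               "2 members")
})

test_that("weighted endemism follows the inverse-range formula", {
  one_cell <- mk("Species a", c(1, rep(0, 11)), threshold = 1)
  wei <- endemism_map(list(one_cell))
  expect_equal(wei$values[1], 1)
  expect_equal(sum(wei$values), 1)

  # A occupies {1}; B occupies {1,2,3,4}: WEI(1) = 1 + 1/4, WEI(2) = 1/4
  a <- mk("Species a", c(1, rep(0, 11)), threshold = 1)
  b <- mk("Species b", c(1, 1, 1, 1, rep(0, 8)), threshold = 1)
  wei2 <- endemism_map(list(a, b))
  expect_equal(wei2$values[1], 1.25)
  expect_equal(wei2$values[2], 0.25)
  expect_equal(wei2$values[5], 0)

  # all species everywhere: constant S / |cells| per cell summing over species
  c1 <- mk("Species a", rep(1, 12), threshold = 0)
  c2 <- mk("Species b", rep(1, 12), threshold = 0)
  wei3 <- endemism_map(list(c1, c2))
  expect_equal(unique(wei3$values), 2 / 12)

  empty <- mk("Species c", rep(0, 12), threshold = 1)
  expect_warning(endemism_map(list(a, empty)), "empty predicted range")
})

test_that("community evaluation counts set overlaps over the roster", {
  st <- stack_from_vectors(3, 4, L1 = runif(12))
  roster <- paste("Species", letters[1:10])
  # site = cell 5; observed {a,b,c}; predicted {a,b,d}
  ens <- lapply(roster, function(s) {
    suit <- rep(0, 12)
    if (s %in% c("Species a", "Species b", "Species d")) suit[5] <- 1
    mk(s, suit, threshold = 1)
  })
  rec <- tibble::tibble(taxon = c("Species a", "Species b", "Species c"),
                        cell = 5L)
  ev <- evaluate_community(ens, rec, st)
  get <- function(m) ev$mean[ev$metric == m]
  # TP=2 FP=1 FN=1 TN=6
  expect_equal(get("jaccard"), 0.5)
  expect_equal(get("species_richness_error"), 0)
  expect_equal(get("sensitivity"), 2 / 3)
  expect_equal(get("specificity"), 6 / 7)
  expect_equal(get("prediction_success"), 100 * 8 / 10)

  # perfect prediction at every site (roster of 5, 3 observed and predicted)
  ens_perfect <- lapply(roster[1:5], function(s) {
    suit <- rep(0, 12)
    if (s %in% roster[1:3]) suit[5] <- 1
    mk(s, suit, threshold = 1)
  })
  rec3 <- tibble::tibble(taxon = roster[1:3], cell = 5L)
  evp <- evaluate_community(ens_perfect, rec3, st)
  expect_equal(evp$mean[evp$metric == "species_richness_error"], 0)
  expect_equal(evp$mean[evp$metric == "prediction_success"], 100)

  # complement prediction: sensitivity and specificity collapse to 0
  ens_comp <- lapply(roster[1:4], function(s) {
    suit <- rep(0, 12)
    if (s %in% c("Species c", "Species d")) suit[5] <- 1
    mk(s, suit, threshold = 1)
  })
  rec_comp <- tibble::tibble(taxon = c("Species a", "Species b"), cell = 5L)
  evc <- evaluate_community(ens_comp, rec_comp, st)
  expect_equal(evc$mean[evc$metric == "sensitivity"], 0)
  expect_equal(evc$mean[evc$metric == "specificity"], 0)
})
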