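test_that("bilinear resampling reproduces constants, symmetry and the hand formula", {
  src <- stack_from_matrix(matrix(7, 3, 3))
  tgt <- grid_spec(2, 2, cell_size = 0.8, origin_x = 0.5, origin_y = 2.5)
  expect_equal(resample_bilinear(src, tgt)$data$v, rep(7, 4))

  # 2x2 source [[0,1],[2,3]]; centers at (0.5,1.5),(1.5,1.5),(0.5,0.5),(1.5,0.5)
  src <- stack_from_matrix(matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE))
  mid <- grid_spec(1, 1, cell_size = 1, origin_x = 0.5, origin_y = 1.5)
  expect_equal(resample_bilinear(src, mid)$data$v, 1.5)

  # fractional offset (0.25, 0.25) from the top-left center:
  # w00*v00 + w01*v01 + w10*v10 + w11*v11 with weights from the products
  frac <- grid_spec(1, 1, cell_size = 1, origin_x = 0.25, origin_y = 1.75)
  expected <- 0.75 * 0.75 * 0 + 0.75 * 0.25 * 1 + 0.25 * 0.75 * 2 + 0.25 * 0.25 * 3
  expect_equal(resample_bilinear(src, frac)$data$v, expected)
})

test_that("bilinear resampling is exact for affine surfaces", {
  gs <- grid_spec(6, 7, cell_size = 1)
  ctr <- cell_centers(gs)
  affine <- function(x, y) 2.5 + 1.25 * x - 0.75 * y
  st <- env_stack(list(v = matrix(affine(ctr$x, ctr$y), 6, 7, byrow = TRUE)), gs)
  tgt <- grid_spec(4, 4, cell_size = 0.73, origin_x = 1.1, origin_y = 4.9)
  out <- resample_bilinear(st, tgt)
  tc <- cell_centers(tgt)
  expect_equal(out$data$v, affine(tc$x, tc$y), tolerance = 1e-12)
})

test_that("nodata propagates to every output cell a nodata corner contributes to", {
  m <- matrix(1, 4, 4)
  m[2, 2] <- NA # source center at (1.5, 2.5)
  src <- stack_from_matrix(m)
  tgt <- grid_spec(6, 6, cell_size = 0.5, origin_x = 0.5, origin_y = 3.5)
  out <- resample_bilinear(src, tgt)
  tc <- cell_centers(tgt)
  # any target center whose enclosing 2x2 source-center box includes (1.5,2.5)
  touches <- abs(tc$x - 1.5) < 1 & abs(tc$y - 2.5) < 1
  expect_true(all(is.na(out$data$v[touches])))
  expect_true(all(out$data$v[!touches] == 1))
})

test_that("resampling rejects non-overlapping extents", {
  src <- stack_from_matrix(matrix(1:4, 2, 2))
  far <- grid_spec(2, 2, cell_size = 1, origin_x = 50, origin_y = 50)
  expect_error(resample_bilinear(src, far), "overlap")
})

test_that("crop keeps exactly the cells whose centers fall in the bbox", {
  gs <- grid_spec(4, 4, cell_size = 1)
  st <- env_stack(list(v = matrix(1:16, 4, 4, byrow = TRUE)), gs)
  full <- crop_stack(st, c(0, 0, 4, 4))
  expect_equal(full$data$v, st$data$v)
  expect_equal(full$spec$n_rows, 4)

  left <- crop_stack(st, c(0, 0, 2, 4))
  expect_equal(left$spec$n_cols, 2)
  expect_equal(left$spec$n_rows, 4)
  expect_equal(env_layer_matrix(left, "v"),
               matrix(1:16, 4, 4, byrow = TRUE)[, 1:2])

  # bbox containing exactly one center: cell (row 2, col 3) centered (2.5, 2.5)
  one <- crop_stack(st, c(2.3, 2.3, 2.7, 2.7))
  expect_equal(dim(env_layer_matrix(one, "v")), c(1, 1))
  expect_equal(one$data$v, 7)

  expect_error(crop_stack(st, c(10, 10, 11, 11)), "center")
})

test_that("pairwise correlation matches a brute-force Pearson and flags degenerate layers", {
  set.seed(11)
  a <- rnorm(10)
  b <- 0.5 * a + rnorm(10)
  st <- stack_from_vectors(2, 5, a = a, b = b, neg_a = -a)
  r <- pairwise_correlation(st)
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r, t(r))
  expect_equal(r["a", "neg_a"], -1)
  expect_equal(r["a", "b"], pearson_brute(a, b), tolerance = 1e-12)
  expect_true(all(abs(r) <= 1 + 1e-12))

  st2 <- stack_from_vectors(2, 5, a = a, flat = rep(3, 10))
  expect_warning(r2 <- pairwise_correlation(st2), "zero-variance")
  expect_true(all(is.na(r2["flat", ])))
  expect_identical(attr(r2, "undefined_layers"), "flat")
})

test_that("collinearity screening follows the greedy priority rule", {
  nm <- c("A", "B", "C")
  r <- diag(3)
  dimnames(r) <- list(nm, nm)
  r["A", "B"] <- r["B", "A"] <- 0.95
  r["A", "C"] <- r["C", "A"] <- 0.2
  r["B", "C"] <- r["C", "B"] <- 0.3
  expect_equal(screen_collinear(r, c("A", "B", "C"), threshold = 1), nm)
  expect_equal(screen_collinear(r, c("A", "B", "C"), threshold = 0.85), c("A", "C"))
  expect_equal(screen_collinear(r, c("B", "A", "C"), threshold = 0.85), c("B", "C"))

  # duplicate layers: only the higher-priority copy survives
  r2 <- matrix(1, 2, 2, dimnames = list(c("A", "A2"), c("A", "A2")))
  expect_equal(screen_collinear(r2, c("A2", "A"), threshold = 0.99), "A2")

  expect_error(screen_collinear(r, c("A", "B", "Z"), 0.85), "Z")

  # result depends only on the priority order, not storage order
  perm <- c("C", "A", "B")
  expect_equal(screen_collinear(r[perm, perm], c("A", "B", "C"), 0.85),
               screen_collinear(r, c("A", "B", "C"), 0.85))
})

test_that("stack round-trips through the text-grid format", {
  gs <- grid_spec(3, 4, cell_size = 0.5, origin_x = 50, origin_y = 26,
                  crs = "EPSG:4326")
  st <- env_stack(list(bathymetry = matrix(-(1:12), 3, 4),
                       salinity = matrix(37 + (1:12) / 100, 3, 4)), gs)
  dir <- withr::local_tempdir()
  write_env_stack(st, dir, units = c(bathymetry = "m", salinity = "psu"),
                  priority = c(bathymetry = 1, salinity = 2))
  rt <- read_env_stack(dir)
  expect_equal(env_layer_names(rt), env_layer_names(st))
  expect_equal(rt$data$bathymetry, st$data$bathymetry)
  expect_equal(rt$spec$origin_x, 50)
  expect_equal(attr(rt, "units")[["salinity"]], "psu")
})
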