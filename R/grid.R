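#' Define a regular analysis grid
#'
#' A `grid_spec` describes the shared geometry of every gridded surface in a
#' modelling run: a regular lattice of square cells with row 1 as the
#' northernmost row and column 1 as the westernmost column. `origin_x` /
#' `origin_y` give the coordinates of the grid's north-west corner (not a cell
#' center). Cell ownership is half-open: a point belongs to the cell whose
#' footprint `[x, x + cell_size)` (and symmetrically in y, from the top edge)
#' contains it, which is equivalent to snapping to the nearest cell center.
#'
#' @param n_rows,n_cols Positive integers, the grid dimensions.
#' @param cell_size Positive cell edge length in map units (e.g. degrees).
#' @param origin_x,origin_y Coordinates of the north-west grid corner.
#' @param crs Free-text identifier of the coordinate reference system.
#' @param valid_mask Optional logical matrix (`n_rows` x `n_cols`); `FALSE`
#'   marks cells outside the study area (e.g. land). Default: all valid.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' gs <- grid_spec(4, 5, cell_size = 1, origin_x = 50, origin_y = 30)
#' grid_extent(gs)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs = "EPSG:4326", valid_mask = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, n_rows, n_cols)
  }
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), c(n_rows, n_cols))) {
    stop("`valid_mask` must be a logical matrix of dimension n_rows x n_cols", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y, crs = crs,
         valid_mask = valid_mask),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf("<grid_spec> %d x %d cells, cell_size %g, crs %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]; %d valid cells\n",
              ext[["xmin"]], ext[["xmax"]], ext[["ymin"]], ext[["ymax"]],
              sum(x$valid_mask)))
  invisible(x)
}

#' Grid extent
#'
#' @param spec A [grid_spec()].
#' @return Named numeric vector `xmin, ymin, xmax, ymax` (outer cell edges).
#' @export
grid_extent <- function(spec) {
  c(xmin = spec$origin_x,
    ymin = spec$origin_y - spec$n_rows * spec$cell_size,
    xmax = spec$origin_x + spec$n_cols * spec$cell_size,
    ymax = spec$origin_y)
}

#' Cell centers of a grid
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per cell in row-major order (`cell` =
#'   `(row - 1) * n_cols + col`) and columns `cell`, `row`, `col`, `x`, `y`,
#'   `valid`.
#' @export
cell_centers <- function(spec) {
  row <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  col <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  tibble::tibble(
    cell = seq_len(spec$n_rows * spec$n_cols),
    row = row,
    col = col,
    x = spec$origin_x + (col - 0.5) * spec$cell_size,
    y = spec$origin_y - (row - 0.5) * spec$cell_size,
    valid = as.vector(t(spec$valid_mask))
  )
}

#' Map point coordinates to grid cells
#'
#' Points are assigned by the half-open ownership rule; points outside the
#' grid extent get `NA`.
#'
#' @param spec A [grid_spec()].
#' @param x,y Numeric coordinate vectors of equal length.
#' @return Integer vector of row-major cell indices (`NA` when off-grid).
#' @export
point_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1
  # the outer south/east edges belong to the last row/column
  col[x == spec$origin_x + spec$n_cols * spec$cell_size] <- spec$n_cols
  row[y == spec$origin_y - spec$n_rows * spec$cell_size] <- spec$n_rows
  ok <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= spec$n_cols & row >= 1 & row <= spec$n_rows
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((row[ok] - 1) * spec$n_cols + col[ok])
  out
}

# row-major vector <-> matrix helpers (internal)
vec_to_matrix <- function(v, spec) {
  matrix(v, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
}

matrix_to_vec <- function(m) {
  as.vector(t(m))
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$n_rows, b$n_rows)) && isTRUE(all.equal(a$n_cols, b$n_cols)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}
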