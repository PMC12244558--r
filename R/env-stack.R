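#' Build an environmental raster stack
#'
#' An `env_stack` holds a set of co-registered environmental layers (e.g.
#' bathymetry, temperature, salinity, chlorophyll-a) on one [grid_spec()].
#' Internally the stack is a cell-indexed tibble (one row per grid cell, one
#' numeric column per layer), the tabular form every downstream modelling
#' function consumes. A cell is *valid* when it lies inside the spec's mask
#' and every layer has a finite value there; elsewhere layer values are `NA`.
#'
#' @param layers Named list of numeric matrices (`n_rows` x `n_cols` each).
#' @param spec A [grid_spec()] shared by all layers.
#' @return An object of class `env_stack` with elements `spec` and `data`
#'   (tibble with `cell`, `row`, `col`, `x`, `y`, `valid`, then one column
#'   per layer).
#' @examples
#' gs <- grid_spec(2, 2)
#' st <- env_stack(list(depth = matrix(-(1:4), 2, 2)), gs)
#' env_layer_names(st)
#' @export
env_stack <- function(layers, spec) {
  if (is.null(names(layers)) || anyDuplicated(names(layers)) || any(names(layers) == "")) {
    stop("`layers` must be a uniquely named list of matrices", call. = FALSE)
  }
  reserved <- c("cell", "row", "col", "x", "y", "valid")
  if (any(names(layers) %in% reserved)) {
    stop("layer names may not clash with grid columns: ",
         paste(intersect(names(layers), reserved), collapse = ", "), call. = FALSE)
  }
  dat <- cell_centers(spec)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!identical(dim(m), c(spec$n_rows, spec$n_cols))) {
      stop(sprintf("layer '%s' does not match the grid dimensions", nm), call. = FALSE)
    }
    v <- matrix_to_vec(m)
    v[!dat$valid] <- NA_real_
    dat[[nm]] <- as.numeric(v)
  }
  if (length(layers)) {
    finite <- rowSums(!is.finite(as.matrix(dat[names(layers)]))) == 0
    dat$valid <- dat$valid & finite
    for (nm in names(layers)) dat[[nm]][!dat$valid] <- NA_real_
  }
  structure(list(spec = spec, data = dat), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s) on a %d x %d grid (%d valid cells)\n",
              length(env_layer_names(x)), x$spec$n_rows, x$spec$n_cols,
              sum(x$data$valid)))
  cat("  layers:", paste(env_layer_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Layer names of a stack
#' @param stack An [env_stack()].
#' @return Character vector of layer names, in stack order.
#' @export
env_layer_names <- function(stack) {
  setdiff(names(stack$data), c("cell", "row", "col", "x", "y", "valid"))
}

#' Extract one layer as a matrix
#' @param stack An [env_stack()].
#' @param name Layer name.
#' @return Numeric matrix in grid orientation (row 1 = north).
#' @export
env_layer_matrix <- function(stack, name) {
  if (!name %in% env_layer_names(stack)) {
    stop(sprintf("unknown layer '%s'", name), call. = FALSE)
  }
  vec_to_matrix(stack$data[[name]], stack$spec)
}

#' Environmental values at given cells
#'
#' @param stack An [env_stack()].
#' @param cells Integer cell indices.
#' @param layers Optional subset of layer names (default: all).
#' @return Tibble of layer values, one row per requested cell.
#' @export
env_values_at <- function(stack, cells, layers = NULL) {
  layers <- layers %||% env_layer_names(stack)
  stack$data[cells, layers, drop = FALSE]
}

#' Keep a subset of layers
#'
#' @param stack An [env_stack()].
#' @param layers Layer names to keep, in the order given.
#' @return An [env_stack()] with only those layers.
#' @export
select_layers <- function(stack, layers) {
  missing <- setdiff(layers, env_layer_names(stack))
  if (length(missing)) {
    stop("unknown layer(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  env_stack(stats::setNames(lapply(layers, function(nm) env_layer_matrix(stack, nm)),
                            layers),
            stack$spec)
}

#' Resample layers onto a new grid by bilinear interpolation
#'
#' Every target cell center is interpolated from the four enclosing source
#' cell centers. Nodata is conservative: if any contributing corner (one with
#' non-zero interpolation weight) is nodata, the output cell is nodata, so no
#' values are fabricated along coastlines. Target centers outside the source
#' center lattice are nodata. Interpolation is exact for affine surfaces.
#'
#' @param stack An [env_stack()] (needs at least a 2 x 2 grid).
#' @param target A [grid_spec()] whose extent overlaps the source extent.
#' @param layers Optional subset of layer names to carry over.
#' @return A new [env_stack()] on `target`.
#' @export
resample_bilinear <- function(stack, target, layers = NULL) {
  layers <- layers %||% env_layer_names(stack)
  src <- stack$spec
  if (src$n_rows < 2 || src$n_cols < 2) {
    stop("source grid must be at least 2 x 2 for bilinear interpolation", call. = FALSE)
  }
  se <- grid_extent(src)
  te <- grid_extent(target)
  if (te[["xmin"]] >= se[["xmax"]] || te[["xmax"]] <= se[["xmin"]] ||
      te[["ymin"]] >= se[["ymax"]] || te[["ymax"]] <= se[["ymin"]]) {
    stop("target extent does not overlap the source extent", call. = FALSE)
  }
  ctr <- cell_centers(target)
  # fractional position in source cell-center index space (1-based)
  cx <- (ctr$x - src$origin_x) / src$cell_size + 0.5
  cy <- (src$origin_y - ctr$y) / src$cell_size + 0.5
  j0 <- floor(cx); fx <- cx - j0
  i0 <- floor(cy); fy <- cy - i0
  eps <- 1e-9
  j1 <- ifelse(fx <= eps, j0, j0 + 1)
  i1 <- ifelse(fy <= eps, i0, i0 + 1)
  ok <- j0 >= 1 & j1 <= src$n_cols & i0 >= 1 & i1 <= src$n_rows &
    !is.na(j0) & !is.na(i0)
  interp_one <- function(v) {
    m <- vec_to_matrix(v, src)
    out <- rep(NA_real_, nrow(ctr))
    if (any(ok)) {
      v00 <- m[cbind(i0[ok], j0[ok])]
      v01 <- m[cbind(i0[ok], j1[ok])]
      v10 <- m[cbind(i1[ok], j0[ok])]
      v11 <- m[cbind(i1[ok], j1[ok])]
      w00 <- (1 - fy[ok]) * (1 - fx[ok])
      w01 <- (1 - fy[ok]) * fx[ok]
      w10 <- fy[ok] * (1 - fx[ok])
      w11 <- fy[ok] * fx[ok]
      zero <- function(v, w) ifelse(w == 0, 0, v * w)
      val <- zero(v00, w00) + zero(v01, w01) + zero(v10, w10) + zero(v11, w11)
      bad <- (w00 > 0 & is.na(v00)) | (w01 > 0 & is.na(v01)) |
        (w10 > 0 & is.na(v10)) | (w11 > 0 & is.na(v11))
      val[bad] <- NA_real_
      out[ok] <- val
    }
    vec_to_matrix(out, target)
  }
  env_stack(stats::setNames(lapply(layers, function(nm) interp_one(stack$data[[nm]])),
                            layers),
            target)
}

#' Crop a stack to a bounding box
#'
#' Keeps exactly the cells whose centers fall inside `bbox` (bounds
#' inclusive); the resulting grid stays regular and layer order is preserved.
#'
#' @param stack An [env_stack()].
#' @param bbox Numeric `c(xmin, ymin, xmax, ymax)`.
#' @return A cropped [env_stack()].
#' @export
crop_stack <- function(stack, bbox) {
  stopifnot(length(bbox) == 4)
  names(bbox) <- c("xmin", "ymin", "xmax", "ymax")
  spec <- stack$spec
  xs <- spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  ys <- spec$origin_y - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  keep_col <- which(xs >= bbox[["xmin"]] & xs <= bbox[["xmax"]])
  keep_row <- which(ys >= bbox[["ymin"]] & ys <= bbox[["ymax"]])
  if (!length(keep_col) || !length(keep_row)) {
    stop("bbox does not contain any cell center of the stack", call. = FALSE)
  }
  new_spec <- grid_spec(
    n_rows = length(keep_row), n_cols = length(keep_col),
    cell_size = spec$cell_size,
    origin_x = spec$origin_x + (min(keep_col) - 1) * spec$cell_size,
    origin_y = spec$origin_y - (min(keep_row) - 1) * spec$cell_size,
    crs = spec$crs,
    valid_mask = spec$valid_mask[keep_row, keep_col, drop = FALSE]
  )
  layers <- lapply(env_layer_names(stack), function(nm) {
    env_layer_matrix(stack, nm)[keep_row, keep_col, drop = FALSE]
  })
  env_stack(stats::setNames(layers, env_layer_names(stack)), new_spec)
}

#' Pairwise Pearson correlation between layers
#'
#' Correlations are computed pairwise-complete over cells valid in both
#' layers (at least 3 required per pair). A layer with zero variance yields
#' an undefined (`NA`) row/column, reported via a warning and the
#' `"undefined_layers"` attribute rather than silently coerced to 0.
#'
#' @param stack An [env_stack()].
#' @param layers Optional subset of layer names.
#' @return Symmetric correlation matrix with unit diagonal (for defined
#'   layers) and attribute `undefined_layers`.
#' @export
pairwise_correlation <- function(stack, layers = NULL) {
  layers <- layers %||% env_layer_names(stack)
  vals <- as.matrix(stack$data[layers])
  p <- length(layers)
  out <- matrix(NA_real_, p, p, dimnames = list(layers, layers))
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  undefined <- layers[is.na(sds) | sds == 0]
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (layers[i] %in% undefined || layers[j] %in% undefined) next
      ok <- stats::complete.cases(vals[, c(i, j)])
      if (sum(ok) < 3) {
        stop(sprintf("fewer than 3 jointly valid cells for layers '%s' and '%s'",
                     layers[i], layers[j]), call. = FALSE)
      }
      r <- if (i == j) 1 else stats::cor(vals[ok, i], vals[ok, j])
      out[i, j] <- out[j, i] <- r
    }
  }
  if (length(undefined)) {
    warning("zero-variance layer(s) with undefined correlations: ",
            paste(undefined, collapse = ", "), call. = FALSE)
  }
  attr(out, "undefined_layers") <- undefined
  out
}

#' Greedy collinearity screening
#'
#' Scans layers in order of ecological priority (rank 1 = most relevant) and
#' drops a layer iff its absolute correlation with an already-retained layer
#' exceeds `threshold`. The result depends only on the priority order, never
#' on the storage order of the stack.
#'
#' @param corr Correlation matrix from [pairwise_correlation()].
#' @param priority Character vector listing every layer exactly once, most
#'   ecologically relevant first.
#' @param threshold Drop threshold on `|r|`, in `(0, 1]`. Default 0.85.
#' @return Character vector of retained layer names, in priority order.
#' @export
screen_collinear <- function(corr, priority, threshold = 0.85) {
  stopifnot(threshold > 0, threshold <= 1)
  layer_names <- rownames(corr)
  if (!setequal(priority, layer_names) || anyDuplicated(priority)) {
    bad <- unique(c(setdiff(priority, layer_names), setdiff(layer_names, priority)))
    stop("`priority` must list every layer exactly once; mismatch: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  retained <- character(0)
  for (nm in priority) {
    r <- abs(corr[nm, retained])
    if (!length(retained) || all(is.na(r) | r <= threshold)) {
      retained <- c(retained, nm)
    }
  }
  retained
}

#' Write / read an environmental stack as text grids
#'
#' Each layer is stored as a plain-text value matrix (`<name>.txt`,
#' whitespace-separated, `NA` for nodata) next to a `manifest.yaml` that
#' records the grid geometry and, optionally, units and screening priority
#' per layer.
#'
#' @param stack An [env_stack()].
#' @param dir Directory to write into (created if needed).
#' @param units Optional named character vector of units per layer.
#' @param priority Optional named integer vector of priority ranks.
#' @return `write_env_stack()` returns the manifest path invisibly;
#'   `read_env_stack()` returns an [env_stack()] with `units`/`priority`
#'   attributes when present in the manifest.
#' @export
write_env_stack <- function(stack, dir, units = NULL, priority = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- stack$spec
  nms <- env_layer_names(stack)
  for (nm in nms) {
    utils::write.table(env_layer_matrix(stack, nm),
                       file.path(dir, paste0(nm, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    grid = list(n_rows = spec$n_rows, n_cols = spec$n_cols,
                cell_size = spec$cell_size, origin_x = spec$origin_x,
                origin_y = spec$origin_y, crs = spec$crs),
    layers = lapply(nms, function(nm) {
      entry <- list(name = nm, file = paste0(nm, ".txt"))
      if (!is.null(units) && nm %in% names(units)) entry$units <- unname(units[[nm]])
      if (!is.null(priority) && nm %in% names(priority)) {
        entry$priority <- unname(priority[[nm]])
      }
      entry
    })
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.yaml") else dir
  manifest <- yaml::read_yaml(path)
  g <- manifest$grid
  spec <- grid_spec(g$n_rows, g$n_cols, g$cell_size, g$origin_x, g$origin_y,
                    crs = g$crs %||% "EPSG:4326")
  base <- dirname(path)
  layers <- list()
  units <- character(0)
  priority <- integer(0)
  for (entry in manifest$layers) {
    m <- as.matrix(utils::read.table(file.path(base, entry$file)))
    dimnames(m) <- NULL
    layers[[entry$name]] <- m
    if (!is.null(entry$units)) units[entry$name] <- entry$units
    if (!is.null(entry$priority)) priority[entry$name] <- entry$priority
  }
  out <- env_stack(layers, spec)
  if (length(units)) attr(out, "units") <- units
  if (length(priority)) attr(out, "priority") <- priority
  out
}
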