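#' Define a regular geographic grid
#'
#' A grid is the shared georeference of every raster in an analysis: a
#' regular latitude-longitude lattice in decimal degrees (WGS84), described
#' by its lower-left corner, square cell size and dimensions. Rasters are
#' stored as matrices in map orientation: row 1 is the northernmost row,
#' column 1 the westernmost column.
#'
#' @param nrow,ncol Number of rows (latitude) and columns (longitude).
#' @param cellsize Cell edge length in decimal degrees (> 0).
#' @param xll,yll Longitude/latitude of the lower-left *corner* of the grid.
#' @return An object of class `enm_grid`.
#' @export
enm_grid <- function(nrow, ncol, cellsize = 0.2, xll = 0, yll = 0) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = cellsize, xll = xll, yll = yll),
            class = "enm_grid")
}

#' @export
print.enm_grid <- function(x, ...) {
  cat(sprintf("<enm_grid> %d x %d cells of %g deg, lower-left (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

#' Cell-center coordinates of a grid
#'
#' @param grid An `enm_grid`.
#' @param cells Optional vector of linear (column-major) cell indices; by
#'   default all cells are returned in column-major order.
#' @return A data.frame with columns `longitude`, `latitude`.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$nrow * grid$ncol)
  i <- ((cells - 1L) %% grid$nrow) + 1L   # row, 1 = north
  j <- ((cells - 1L) %/% grid$nrow) + 1L  # col, 1 = west
  data.frame(
    longitude = grid$xll + (j - 0.5) * grid$cellsize,
    latitude  = grid$yll + (grid$nrow - i + 0.5) * grid$cellsize
  )
}

#' Map point coordinates to grid cell indices
#'
#' @param grid An `enm_grid`.
#' @param longitude,latitude Point coordinates in decimal degrees.
#' @return Integer vector of column-major cell indices; `NA` for points
#'   falling outside the grid extent.
#' @export
cell_index <- function(grid, longitude, latitude) {
  j <- floor((longitude - grid$xll) / grid$cellsize) + 1
  i_from_south <- floor((latitude - grid$yll) / grid$cellsize) + 1
  i <- grid$nrow - i_from_south + 1
  ok <- j >= 1 & j <= grid$ncol & i >= 1 & i <= grid$nrow
  idx <- ifelse(ok, (j - 1) * grid$nrow + i, NA_integer_)
  as.integer(idx)
}

#' Construct a single-layer raster
#'
#' @param values Numeric matrix in map orientation (row 1 = north).
#' @param grid The `enm_grid` georeference.
#' @return An object of class `enm_raster` (list with `values`, `grid`).
#' @export
enm_raster <- function(values, grid) {
  stopifnot(inherits(grid, "enm_grid"),
            all(dim(values) == c(grid$nrow, grid$ncol)))
  structure(list(values = values, grid = grid), class = "enm_raster")
}

#' Build a stack of co-registered raster layers
#'
#' A `LayerStack` holds named environmental layers that share one grid and
#' one validity mask. Values at masked-out cells are ignored by every
#' downstream computation.
#'
#' @param grid An `enm_grid`.
#' @param layers Named list of numeric matrices of dimension
#'   `grid$nrow x grid$ncol`.
#' @param mask Logical matrix of the same dimension; `TRUE` marks valid
#'   cells. Defaults to all cells valid.
#' @return An object of class `enm_stack`.
#' @export
enm_stack <- function(grid, layers, mask = NULL) {
  stopifnot(inherits(grid, "enm_grid"), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop("layers must be uniquely named")
  for (nm in nms) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$nrow || ncol(m) != grid$ncol)
      stop("layer '", nm, "' does not match the grid dimensions")
  }
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrow, grid$ncol)
  stopifnot(is.logical(mask), all(dim(mask) == c(grid$nrow, grid$ncol)))
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "enm_stack")
}

#' @export
print.enm_stack <- function(x, ...) {
  cat(sprintf("<enm_stack> %d layer(s) [%s] on %d x %d grid, %d valid cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$nrow, x$grid$ncol, sum(x$mask)))
  invisible(x)
}

#' @export
names.enm_stack <- function(x) names(x$layers)

#' Extract layer values at valid cells
#'
#' @param stack An `enm_stack`.
#' @param cells Optional linear cell indices; defaults to all valid cells
#'   (column-major order of `which(stack$mask)`).
#' @param layers Optional character vector of layer names to extract.
#' @return Numeric matrix, one row per cell, one column per layer; the
#'   cell indices used are attached as attribute `"cells"`.
#' @export
stack_values <- function(stack, cells = NULL, layers = NULL) {
  if (is.null(cells)) cells <- which(stack$mask)
  if (is.null(layers)) layers <- names(stack$layers)
  missing <- setdiff(layers, names(stack$layers))
  if (length(missing))
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "))
  out <- vapply(layers, function(nm) stack$layers[[nm]][cells],
                numeric(length(cells)))
  out <- matrix(out, nrow = length(cells),
                dimnames = list(NULL, layers))
  attr(out, "cells") <- cells
  out
}

#' Restrict a stack to a subset of its layers
#' @param stack An `enm_stack`.
#' @param layers Character vector of layer names to keep.
#' @return An `enm_stack` with only the requested layers.
#' @export
subset_stack <- function(stack, layers) {
  missing <- setdiff(layers, names(stack$layers))
  if (length(missing))
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "))
  enm_stack(stack$grid, stack$layers[layers], stack$mask)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every GIS. `NA` cells are
#' written as the nodata value.
#'
#' @param mat Numeric matrix in map orientation (row 1 = north).
#' @param grid The `enm_grid` georeference.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(mat, grid, path, nodata = -9999) {
  stopifnot(all(dim(mat) == c(grid$nrow, grid$ncol)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @return List with `values` (matrix, `NA` at nodata cells) and `grid`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("not an ESRI ASCII grid: ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == nodata] <- NA
  grid <- enm_grid(vals[["nrows"]], vals[["ncols"]], vals[["cellsize"]],
                   vals[["xllcorner"]], vals[["yllcorner"]])
  list(values = m, grid = grid)
}

#' Write a layer stack as a directory of ASCII grids
#'
#' One `.asc` per layer plus `layers.txt` (layer order manifest) and
#' `mask.asc` (0/1 validity raster).
#'
#' @param stack An `enm_stack`.
#' @param dir Output directory, created if needed.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    m <- stack$layers[[nm]]
    m[!stack$mask] <- NA
    write_ascii_grid(m, stack$grid, file.path(dir, paste0(nm, ".asc")))
  }
  write_ascii_grid(stack$mask + 0, stack$grid, file.path(dir, "mask.asc"))
  writeLines(names(stack$layers), file.path(dir, "layers.txt"))
  invisible(dir)
}

#' Read a layer stack written by [write_stack()]
#' @param dir Directory containing `layers.txt` and per-layer `.asc` files.
#' @return An `enm_stack`.
#' @export
read_stack <- function(dir) {
  nms <- readLines(file.path(dir, "layers.txt"))
  layers <- list()
  grid <- NULL
  for (nm in nms) {
    g <- read_ascii_grid(file.path(dir, paste0(nm, ".asc")))
    layers[[nm]] <- g$values
    grid <- g$grid
  }
  maskfile <- file.path(dir, "mask.asc")
  mask <- if (file.exists(maskfile)) read_ascii_grid(maskfile)$values == 1
          else !Reduce(`|`, lapply(layers, is.na))
  enm_stack(grid, layers, mask)
}
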