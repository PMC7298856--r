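#' Filter collinear layers by pairwise Pearson correlation
#'
#' Computes Pearson correlations between all layer pairs over the masked
#' cells and removes layers greedily until no retained pair has
#' `|r| >= r_max`. At each step the layer dropped is the one (among those
#' in the worst violating pair) with the larger mean absolute correlation
#' to all remaining layers; ties break by name order, so the result is
#' deterministic. Constant (zero-variance) layers are removed first with a
#' warning.
#'
#' @param stack An `enm_stack` with >= 2 layers.
#' @param mask Optional logical matrix restricting the cells used
#'   (defaults to the stack mask).
#' @param r_max Correlation threshold; pairs with `|r| >= r_max` are
#'   considered collinear (study default 0.80).
#' @return Character vector of retained layer names, in their original
#'   order; the full correlation matrix is attached as attribute `"r"`.
#' @export
pearson_filter <- function(stack, mask = NULL, r_max = 0.80) {
  if (length(stack$layers) < 2) stop("need at least 2 layers")
  cells <- if (is.null(mask)) which(stack$mask) else
    which(mask & stack$mask)
  if (!length(cells)) stop("empty mask")
  vals <- stack_values(stack, cells)
  sds <- apply(vals, 2, stats::sd)
  keep <- names(stack$layers)
  if (any(sds == 0 | !is.finite(sds))) {
    flat <- keep[sds == 0 | !is.finite(sds)]
    warning("removing constant layer(s): ", paste(flat, collapse = ", "))
    keep <- setdiff(keep, flat)
    if (length(keep) < 2) return(keep)
    vals <- vals[, keep, drop = FALSE]
  }
  R <- stats::cor(vals)
  full_R <- R
  repeat {
    A <- abs(R[keep, keep, drop = FALSE])
    diag(A) <- 0
    if (max(A) < r_max || length(keep) <= 1) break
    w <- which(A == max(A), arr.ind = TRUE)[1, ]
    pair <- keep[sort(w)]
    mac <- rowMeans(A[pair, , drop = FALSE])
    drop <- pair[order(-mac, pair)][1]
    keep <- setdiff(keep, drop)
  }
  out <- intersect(names(stack$layers), keep)
  attr(out, "r") <- full_R
  out
}

#' Enumerate candidate variable sets
#'
#' All subsets of the given layer names of size `>= min_size`, each
#' exactly once. For v names the count is `2^v - sum_{i<min_size} C(v,i)`;
#' seven candidate variables with `min_size = 2` give the study's 120
#' sets.
#'
#' @param layer_names Character vector of available layer names.
#' @param min_size Minimum subset size (>= 2).
#' @return List of character vectors (each a variable set), ordered by
#'   size then lexicographically by member indices.
#' @export
enumerate_variable_sets <- function(layer_names, min_size = 2) {
  stopifnot(min_size >= 2)
  v <- length(layer_names)
  if (v < min_size) {
    warning("fewer layers (", v, ") than min_size (", min_size, ")")
    return(list())
  }
  out <- list()
  for (k in min_size:v)
    out <- c(out, utils::combn(layer_names, k, simplify = FALSE))
  out
}

# bilinear interpolation of a coarse raster at point coordinates;
# constant extrapolation within the half-cell margin at the border
bilinear_at <- function(values, grid, lon, lat) {
  cs <- grid$cellsize
  # fractional column/row positions in cell-center coordinates
  fx <- (lon - (grid$xll + cs / 2)) / cs          # 0 at col-1 center
  fy <- ((grid$yll + grid$nrow * cs - cs / 2) - lat) / cs  # 0 at row-1 center
  fx <- pmin(pmax(fx, 0), grid$ncol - 1)
  fy <- pmin(pmax(fy, 0), grid$nrow - 1)
  j0 <- pmin(floor(fx) + 1, grid$ncol - 1); j1 <- j0 + 1
  i0 <- pmin(floor(fy) + 1, grid$nrow - 1); i1 <- i0 + 1
  tx <- fx - (j0 - 1)
  ty <- fy - (i0 - 1)
  v00 <- values[cbind(i0, j0)]; v01 <- values[cbind(i0, j1)]
  v10 <- values[cbind(i1, j0)]; v11 <- values[cbind(i1, j1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
}

#' Delta-method downscaling of a coarse future layer
#'
#' Classic additive anomaly ("delta") downscaling: the coarse-resolution
#' future-minus-baseline anomaly is bilinearly interpolated to the fine
#' cell centers and added to the fine baseline climatology. Exactly the
#' identity when the anomaly is zero, and linear in the anomaly. For
#' bounded variables such as relative humidity, pass `clip` to constrain
#' the output (e.g. `c(0, 100)`).
#'
#' @param coarse_baseline,coarse_future `enm_raster`s on one shared coarse
#'   grid.
#' @param fine_baseline `enm_raster` whose extent is nested in the coarse
#'   extent.
#' @param clip Optional length-2 numeric `c(lo, hi)` applied to the output.
#' @return `enm_raster` on the fine grid: baseline + interpolated anomaly.
#' @export
delta_downscale <- function(coarse_baseline, coarse_future, fine_baseline,
                            clip = NULL) {
  if (!grids_identical(coarse_baseline$grid, coarse_future$grid))
    stop("coarse baseline and future grids differ")
  cg <- coarse_baseline$grid; fg <- fine_baseline$grid
  c_ext <- c(cg$xll, cg$xll + cg$ncol * cg$cellsize,
             cg$yll, cg$yll + cg$nrow * cg$cellsize)
  f_ext <- c(fg$xll, fg$xll + fg$ncol * fg$cellsize,
             fg$yll, fg$yll + fg$nrow * fg$cellsize)
  tol <- 1e-9
  if (f_ext[1] < c_ext[1] - tol || f_ext[2] > c_ext[2] + tol ||
      f_ext[3] < c_ext[3] - tol || f_ext[4] > c_ext[4] + tol)
    stop("fine grid extent is not nested in the coarse extent")
  anom <- coarse_future$values - coarse_baseline$values
  cc <- cell_centers(fg)
  interp <- bilinear_at(anom, cg, cc$longitude, cc$latitude)
  out <- fine_baseline$values + matrix(interp, fg$nrow, fg$ncol)
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  enm_raster(out, fg)
}

#' Crop a stack to an accessible area
#'
#' Masks all layers to the accessible-area cells; values outside become
#' no-data and the stack mask is intersected with the area mask.
#'
#' @param stack An `enm_stack`.
#' @param area An `accessible_area` (or a logical matrix on the same grid).
#' @return The cropped `enm_stack`.
#' @export
crop_stack <- function(stack, area) {
  amask <- if (inherits(area, "accessible_area")) {
    if (!grids_identical(stack$grid, area$grid))
      stop("stack and accessible-area grids differ")
    area$mask
  } else area
  stopifnot(all(dim(amask) == c(stack$grid$nrow, stack$grid$ncol)))
  newmask <- stack$mask & amask
  if (!any(newmask)) stop("stack and accessible area do not intersect")
  layers <- lapply(stack$layers, function(m) { m[!newmask] <- NA; m })
  enm_stack(stack$grid, layers, newmask)
}
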