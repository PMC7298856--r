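#' Construct an occurrence set
#'
#' An occurrence set is a data.frame of point records (decimal-degree
#' WGS84 coordinates) with a `split` label per record
#' (`calibration`, `evaluation`, `independent`, or `NA` before splitting).
#' Exact coordinate duplicates are dropped at construction because spatial
#' thinning assumes distinct points.
#'
#' @param df data.frame with at least `longitude` and `latitude` columns;
#'   optional `species`, `source`, `split`.
#' @param dedupe Drop exact coordinate duplicates (default `TRUE`).
#' @return data.frame of class `occurrence_set` with columns
#'   `species, longitude, latitude, source, split`.
#' @export
occurrence_set <- function(df, dedupe = TRUE) {
  need <- c("longitude", "latitude")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence table is missing column(s): ",
         paste(missing, collapse = ", "))
  lon <- as.numeric(df$longitude)
  lat <- as.numeric(df$latitude)
  bad <- which(!is.finite(lon) | !is.finite(lat) |
                 lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (length(bad))
    stop("invalid coordinates at row(s): ", paste(bad, collapse = ", "))
  out <- data.frame(
    species = as.character(df$species %||% rep("unknown", length(lon))),
    longitude = lon, latitude = lat,
    source = as.character(df$source %||% rep(NA_character_, length(lon))),
    split = as.character(df$split %||% rep(NA_character_, length(lon))),
    stringsAsFactors = FALSE)
  if (dedupe && nrow(out) > 0) {
    dup <- duplicated(out[, c("longitude", "latitude")])
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Load occurrence records from CSV
#'
#' Expects at least `longitude` and `latitude` columns; records are
#' range-validated and exact coordinate duplicates dropped. An empty file
#' yields an empty set with a warning.
#'
#' @param path CSV path.
#' @return An [occurrence_set()].
#' @export
load_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("no occurrence records in ", path)
    return(occurrence_set(data.frame(longitude = numeric(),
                                     latitude = numeric())))
  }
  occurrence_set(df)
}

#' Write an occurrence set to CSV
#' @param occ An [occurrence_set()].
#' @param path Output CSV path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Spatially thin occurrence records to a minimum separation
#'
#' Removes records until every retained pair is at least `d_km` apart by
#' great-circle distance, keeping as many records as possible. The search
#' is a randomized greedy: repeatedly delete one member of a violating
#' pair, preferring the record with more neighbours within `d_km` (random
#' tie-break), restarted `restarts` times from the seeded RNG; the largest
#' retained set wins. The returned set always satisfies the minimum
#' distance certificate (verifiable post hoc in O(n^2)).
#'
#' @param occ An [occurrence_set()].
#' @param d_km Minimum pairwise distance in km (> 0); the study default is
#'   22 km, matching a ~0.2-degree working grid.
#' @param seed Integer seed.
#' @param restarts Number of randomized restarts (default 100).
#' @return The thinned [occurrence_set()].
#' @export
thin_occurrences <- function(occ, d_km = 22, seed = 1L, restarts = 100L) {
  stopifnot(d_km > 0)
  n <- nrow(occ)
  if (n <= 1) return(occ)
  D <- haversine_matrix(occ$longitude, occ$latitude)
  conflict <- D < d_km
  diag(conflict) <- FALSE
  if (!any(conflict)) return(occ)
  best <- integer(0)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      keep <- rep(TRUE, n)
      deg <- rowSums(conflict)
      while (TRUE) {
        active <- which(keep & deg > 0)
        if (!length(active)) break
        # drop the record with most remaining conflicts; random tie-break
        worst <- active[deg[active] == max(deg[active])]
        drop <- if (length(worst) == 1) worst else sample(worst, 1)
        keep[drop] <- FALSE
        nb <- which(conflict[drop, ] & keep)
        deg[nb] <- deg[nb] - 1L
        deg[drop] <- 0L
      }
      if (sum(keep) > length(best)) best <- which(keep)
    }
  })
  out <- occ[best, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(occ)
  out
}

#' Split records into calibration and evaluation sets
#'
#' A seeded random partition: `round(fraction * n)` records (round half
#' up) become the calibration set, the remainder the evaluation set. The
#' two sets are disjoint and their union is the input.
#'
#' @param occ An [occurrence_set()] with >= 2 records.
#' @param fraction Calibration fraction in (0, 1); study default 0.5.
#' @param seed Integer seed.
#' @return List with elements `calibration` and `evaluation`, both
#'   [occurrence_set()]s with their `split` column filled in.
#' @export
split_calibration <- function(occ, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(occ)
  if (n < 2) stop("need at least 2 records to split")
  n_cal <- as.integer(floor(fraction * n + 0.5))  # round half up
  n_cal <- max(1L, min(n - 1L, n_cal))
  idx <- with_seed(seed, sample.int(n, n_cal))
  cal <- occ[sort(idx), , drop = FALSE]
  ev <- occ[setdiff(seq_len(n), idx), , drop = FALSE]
  cal$split <- "calibration"
  ev$split <- "evaluation"
  rownames(cal) <- rownames(ev) <- NULL
  class(cal) <- class(ev) <- class(occ)
  list(calibration = cal, evaluation = ev)
}

#' Build the accessible-area (M) mask around occurrences
#'
#' The accessible area approximates the region reachable by the species
#' and is used as the calibration/background extent. A grid cell belongs
#' to the mask iff its center lies within `B_km` (great-circle) of at
#' least one occurrence; the study default is a 200 km buffer.
#'
#' @param occ A non-empty [occurrence_set()].
#' @param grid An `enm_grid`.
#' @param B_km Buffer radius in km (>= 0).
#' @return List of class `accessible_area`: `mask` (logical matrix),
#'   `buffer_km`, `grid`.
#' @export
build_accessible_area <- function(occ, grid, B_km = 200) {
  stopifnot(B_km >= 0)
  if (nrow(occ) == 0) stop("cannot build an accessible area without occurrences")
  cc <- cell_centers(grid)
  within <- rep(FALSE, nrow(cc))
  # cheap bounding prefilter per occurrence, exact haversine inside it
  lat_pad <- B_km / 110.574 + grid$cellsize
  for (k in seq_len(nrow(occ))) {
    lon0 <- occ$longitude[k]; lat0 <- occ$latitude[k]
    lon_pad <- B_km / (111.32 * max(0.05, cos(pmin(89, abs(lat0)) * pi / 180))) +
      grid$cellsize
    cand <- which(!within &
                    abs(cc$latitude - lat0) <= lat_pad &
                    abs(cc$longitude - lon0) <= lon_pad)
    if (!length(cand)) next
    d <- haversine_km(cc$longitude[cand], cc$latitude[cand], lon0, lat0)
    within[cand[d <= B_km]] <- TRUE
  }
  # B = 0 still claims the containing cell of each occurrence
  own <- cell_index(grid, occ$longitude, occ$latitude)
  within[own[!is.na(own)]] <- TRUE
  mask <- matrix(within, grid$nrow, grid$ncol)
  structure(list(mask = mask, buffer_km = B_km, grid = grid),
            class = "accessible_area")
}
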