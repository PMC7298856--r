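#' Final model: median of bootstrap replicates, projected to scenarios
#'
#' Refits the selected parameterization on `n_boot` bootstrap resamples
#' (with replacement, same n) of the calibration occurrences and projects
#' each replicate onto every target stack; the final prediction per stack
#' is the cell-wise median across replicates. Replicates whose fit fails
#' are dropped with a warning; at least half must succeed.
#'
#' @param cal_stack Calibration `enm_stack` (accessible area).
#' @param cal_occ Calibration [occurrence_set()].
#' @param variables,classes,rm The selected parameterization.
#' @param target_stacks Named list of `enm_stack`s to project onto
#'   (conventionally including `present`).
#' @param n_boot Number of bootstrap replicates (study default 10).
#' @param seed Integer seed.
#' @param resample Set `FALSE` to refit on the full calibration data in
#'   every replicate (used to verify median invariance).
#' @param scale Output scale (default cloglog).
#' @param bg_max,knots Fitting controls (see [calibrate_candidates()]).
#' @return List of class `projection_set`: `projections` (named list of
#'   `enm_raster`), `models` (the replicate fits), `scale`.
#' @export
bootstrap_median_model <- function(cal_stack, cal_occ, variables, classes,
                                   rm, target_stacks, n_boot = 10L,
                                   seed = 1L, resample = TRUE,
                                   scale = "cloglog", bg_max = 10000L,
                                   knots = 10) {
  stopifnot(n_boot >= 1, length(target_stacks) >= 1)
  if (is.null(names(target_stacks)))
    stop("target_stacks must be named")
  cells <- which(cal_stack$mask)
  if (length(cells) > bg_max)
    cells <- sort(with_seed(derive_seed(seed, "background"),
                            sample(cells, bg_max)))
  bg <- stack_values(cal_stack, cells, layers = variables)
  idx <- cell_index(cal_stack$grid, cal_occ$longitude, cal_occ$latitude)
  ok <- !is.na(idx)
  ok[ok] <- cal_stack$mask[idx[ok]]
  pres <- stack_values(cal_stack, idx[ok], layers = variables)
  n <- nrow(pres)
  boot_idx <- with_seed(derive_seed(seed, "boot"), {
    lapply(seq_len(n_boot), function(b)
      if (resample) sample.int(n, n, replace = TRUE) else seq_len(n))
  })
  models <- list()
  preds <- list()
  for (b in seq_len(n_boot)) {
    fit <- tryCatch(
      fit_maxent(pres[boot_idx[[b]], , drop = FALSE], bg,
                 classes = classes, rm = rm, knots = knots),
      error = function(e) {
        warning("bootstrap replicate ", b, " failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    models[[length(models) + 1L]] <- fit
    preds[[length(preds) + 1L]] <-
      lapply(target_stacks, function(s) predict(fit, s, scale = scale))
  }
  if (length(models) < ceiling(n_boot / 2))
    stop("fewer than half of the bootstrap replicates fitted successfully")
  projections <- lapply(names(target_stacks), function(nm) {
    arr <- vapply(preds, function(p) p[[nm]]$values,
                  target_stacks[[nm]]$layers[[1]])
    arr <- array(arr, dim = c(dim(target_stacks[[nm]]$layers[[1]]),
                              length(preds)))
    med <- apply(arr, c(1, 2), stats::median)
    enm_raster(med, target_stacks[[nm]]$grid)
  })
  names(projections) <- names(target_stacks)
  structure(list(projections = projections, models = models,
                 scale = scale, n_boot = n_boot,
                 n_succeeded = length(models)),
            class = "projection_set")
}

#' Mobility-oriented parity (MOP) extrapolation analysis
#'
#' Quantifies how far each projection cell's multivariate environment
#' lies from the calibration cloud. Distances are Euclidean after
#' per-variable scaling by the calibration range; the MOP distance of a
#' projection cell is the mean distance to its nearest
#' `reference_fraction` of calibration cells, and similarity is
#' `1 - distance / max(distance)` over the projection. Cells with any
#' variable outside the calibration min-max are flagged as strict
#' extrapolation.
#'
#' @param cal_stack Calibration `enm_stack`.
#' @param proj_stack Projection `enm_stack` with the same variable names.
#' @param reference_fraction Fraction of nearest calibration cells
#'   averaged (default 0.1).
#' @param sample_cap Calibration cells are subsampled (seeded) to at most
#'   this many (default 5000).
#' @param seed Integer seed for the subsample.
#' @param chunk Projection cells processed per block (memory control).
#' @return List of class `mop_surface`: `similarity` (`enm_raster` in
#'   [0, 1]), `distance` (`enm_raster`), `strict` (logical matrix).
#' @export
mop <- function(cal_stack, proj_stack, reference_fraction = 0.1,
                sample_cap = 5000L, seed = 1L, chunk = 512L) {
  stopifnot(reference_fraction > 0, reference_fraction <= 1)
  if (!setequal(names(cal_stack$layers), names(proj_stack$layers)))
    stop("calibration and projection stacks have different variables")
  vars <- names(cal_stack$layers)
  cal_cells <- which(cal_stack$mask)
  if (!length(cal_cells)) stop("empty calibration mask")
  cal <- stack_values(cal_stack, cal_cells, layers = vars)
  if (nrow(cal) > sample_cap)
    cal <- cal[with_seed(seed, sort(sample.int(nrow(cal), sample_cap))), ,
               drop = FALSE]
  lo <- apply(cal, 2, min); hi <- apply(cal, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  calz <- sweep(sweep(cal, 2, lo), 2, span, "/")
  proj_cells <- which(proj_stack$mask)
  proj <- stack_values(proj_stack, proj_cells, layers = vars)
  strict_v <- rowSums(sweep(proj, 2, lo, "<") |
                        sweep(proj, 2, hi, ">")) > 0
  projz <- sweep(sweep(proj, 2, lo), 2, span, "/")
  n_ref <- max(1L, ceiling(reference_fraction * nrow(calz)))
  cal_sq <- rowSums(calz^2)
  dist_v <- numeric(nrow(projz))
  for (start in seq(1, nrow(projz), by = chunk)) {
    ii <- start:min(start + chunk - 1, nrow(projz))
    G <- projz[ii, , drop = FALSE] %*% t(calz)
    D2 <- pmax(outer(rowSums(projz[ii, , drop = FALSE]^2), cal_sq, "+") -
                 2 * G, 0)
    if (n_ref >= ncol(D2)) {
      dist_v[ii] <- rowMeans(sqrt(D2))
    } else {
      dist_v[ii] <- apply(D2, 1, function(r)
        mean(sqrt(sort.int(r, partial = n_ref)[seq_len(n_ref)])))
    }
  }
  dmax <- max(dist_v)
  sim_v <- if (dmax > 0) 1 - dist_v / dmax else rep(1, length(dist_v))
  g <- proj_stack$grid
  simil <- matrix(NA_real_, g$nrow, g$ncol)
  dists <- matrix(NA_real_, g$nrow, g$ncol)
  strict <- matrix(NA, g$nrow, g$ncol)
  simil[proj_cells] <- sim_v
  dists[proj_cells] <- dist_v
  strict[proj_cells] <- strict_v
  structure(list(similarity = enm_raster(simil, g),
                 distance = enm_raster(dists, g),
                 strict = strict),
            class = "mop_surface")
}

#' Binarize a suitability prediction at the E-percentile threshold
#'
#' The threshold is the `(floor(E * n) + 1)`-th smallest suitability at
#' the calibration occurrences (see [omission_threshold()]); cells with
#' prediction >= threshold are suitable. By construction the calibration
#' omission of the binary map is <= E.
#'
#' @param pred `enm_raster` of continuous predictions.
#' @param cal_suit Suitability values at the calibration occurrences (on
#'   `pred`'s scale).
#' @param E Acceptable omission error (study default 0.05).
#' @return List of class `binary_map`: `binary` (logical matrix, `NA`
#'   outside valid cells), `threshold`, `grid`.
#' @export
binarize <- function(pred, cal_suit, E = 0.05) {
  thr <- omission_threshold(cal_suit, E)
  b <- pred$values >= thr
  structure(list(binary = b, threshold = thr, grid = pred$grid),
            class = "binary_map")
}

#' GCM ensemble agreement map
#'
#' Per-cell count of ensemble members predicting suitable, with the
#' agreement cutoff `ceiling(cutoff_frac * G)` — 12 for the study's 20
#' GCMs at 60%.
#'
#' @param binaries List of `binary_map`s (or logical matrices) on one
#'   grid.
#' @param cutoff_frac Agreement fraction (default 0.6).
#' @return List of class `agreement_map`: `counts` (integer matrix),
#'   `G`, `cutoff`, `grid`.
#' @export
agreement <- function(binaries, cutoff_frac = 0.6) {
  stopifnot(length(binaries) >= 1)
  grid <- NULL
  mats <- lapply(binaries, function(b) {
    if (inherits(b, "binary_map")) {
      if (!is.null(grid) && !grids_identical(grid, b$grid))
        stop("binary maps are on different grids")
      grid <<- b$grid
      b$binary
    } else b
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("binary maps are on different grids")
  counts <- Reduce(`+`, lapply(mats, function(m) {
    m[is.na(m)] <- FALSE
    m + 0L
  }))
  G <- length(mats)
  structure(list(counts = counts, G = G,
                 cutoff = ceiling(cutoff_frac * G), grid = grid),
            class = "agreement_map")
}

#' Classify present-to-future suitability change
#'
#' Five classes from the present binary map and the future ensemble
#' agreement: stable suitable with strong agreement; presently suitable
#' but weakening (below the agreement cutoff); strong-agreement gain;
#' weak (partial-agreement) gain; and unsuitable throughout. Integer
#' codes: 0 unsuitable, 1 suitable-weakening, 2 stable-suitable-strong,
#' 3 gain-weak, 4 gain-strong.
#'
#' @param present A `binary_map` of present-day suitability.
#' @param agree An `agreement_map` of future ensemble votes.
#' @return List of class `change_map`: `classes` (integer matrix, `NA`
#'   outside valid cells), `labels` (code -> name), `grid`.
#' @export
classify_change <- function(present, agree) {
  if (!all(dim(present$binary) == dim(agree$counts)))
    stop("present map and agreement map are on different grids")
  p <- present$binary
  cnt <- agree$counts
  cls <- matrix(NA_integer_, nrow(p), ncol(p))
  valid <- !is.na(p)
  strong <- cnt >= agree$cutoff
  cls[valid & p & strong] <- 2L
  cls[valid & p & !strong] <- 1L
  cls[valid & !p & strong] <- 4L
  cls[valid & !p & !strong & cnt > 0] <- 3L
  cls[valid & !p & cnt == 0] <- 0L
  labels <- c(`0` = "unsuitable", `1` = "suitable-weakening",
              `2` = "stable-suitable-strong", `3` = "gain-weak",
              `4` = "gain-strong")
  structure(list(classes = cls, labels = labels, grid = present$grid,
                 cutoff = agree$cutoff, G = agree$G),
            class = "change_map")
}
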