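#' Specification for the synthetic study system
#'
#' Describes a synthetic analogue of the real study inputs: a stack of
#' partially correlated, spatially autocorrelated climate layers on a
#' regular 0.2-degree grid; an ensemble of pseudo-GCM future stacks that
#' are baseline + scenario trend + per-GCM noise; a known ("truth")
#' suitability surface from which occurrences are sampled; and right-skewed
#' cattle-abundance and region rasters for the exposure overlay. Defaults
#' mirror the modelled study system: 7 candidate climate variables, 20
#' pseudo-GCMs, two emissions scenarios (rcp45, rcp85) and two periods
#' (2050, 2070), with 5 of the 7 layers active in the truth model.
#'
#' @param nrow,ncol Grid dimensions.
#' @param cellsize Cell size in degrees (default 0.2).
#' @param xll,yll Lower-left corner of the grid (degrees).
#' @param n_layers Number of environmental layers (>= 2).
#' @param correlation Target pairwise Pearson correlation between layers:
#'   a scalar (applied to every pair) or a full positive semi-definite
#'   correlation matrix.
#' @param kernel_sigma Gaussian smoothing kernel width (in cells) giving
#'   the layers mild spatial autocorrelation.
#' @param layer_means,layer_sds Per-layer location and scale used to put
#'   the standardized fields on climate-like units (recycled).
#' @param truth_active Indices of the layers that drive the truth
#'   suitability surface (default the first 5 of 7).
#' @param truth_intercept,truth_linear,truth_quadratic Coefficients of the
#'   truth linear predictor on standardized layers (recycled over
#'   `truth_active`); suitability is the cloglog transform
#'   `1 - exp(-exp(eta))`, so the generating process lies inside the fitted
#'   linear+quadratic feature family.
#' @param n_gcm Number of pseudo-GCMs in the future ensemble.
#' @param rcps,periods Scenario labels.
#' @param scenario_shifts Named list `rcp.period -> per-layer additive
#'   shift`; by default a warming-like trend scaled by `layer_sds`, twice
#'   as strong under rcp85 and 1.5x stronger by 2070.
#' @param gcm_noise_sd Per-layer standard deviation of the additive
#'   per-GCM offsets (recycled).
#' @param n_regions Number of contiguous reporting regions.
#' @param seed Integer seed making every generated object reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nrow = 80, ncol = 80, cellsize = 0.2,
                           xll = -60, yll = -25,
                           n_layers = 7, correlation = 0.3,
                           kernel_sigma = 0.75,
                           layer_means = c(24, 55, 12, 1100, 35, 60, 70),
                           layer_sds = c(4, 15, 6, 350, 25, 20, 12),
                           truth_active = seq_len(min(5, n_layers)),
                           truth_intercept = 0.5,
                           truth_linear = 0,
                           truth_quadratic = -1,
                           n_gcm = 20,
                           rcps = c("rcp45", "rcp85"),
                           periods = c("2050", "2070"),
                           scenario_shifts = NULL,
                           gcm_noise_sd = NULL,
                           n_regions = 6,
                           seed = 1L) {
  if (n_layers < 2) stop("n_layers must be >= 2")
  if (n_gcm < 1) stop("n_gcm must be >= 1")
  if (cellsize <= 0) stop("cellsize must be > 0")
  C <- correlation_matrix(correlation, n_layers)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite")
  layer_means <- rep_len(layer_means, n_layers)
  layer_sds <- rep_len(layer_sds, n_layers)
  if (is.null(gcm_noise_sd)) gcm_noise_sd <- 0.15 * layer_sds
  gcm_noise_sd <- rep_len(gcm_noise_sd, n_layers)
  if (is.null(scenario_shifts)) {
    rcp_fac <- stats::setNames(seq_along(rcps), rcps)       # 1, 2, ...
    per_fac <- stats::setNames(1 + 0.5 * (seq_along(periods) - 1), periods)
    scenario_shifts <- list()
    for (r in rcps) for (p in periods)
      scenario_shifts[[paste(r, p, sep = ".")]] <-
        0.3 * layer_sds * rcp_fac[[r]] * per_fac[[p]]
  }
  for (key in names(scenario_shifts))
    scenario_shifts[[key]] <- rep_len(scenario_shifts[[key]], n_layers)
  structure(list(
    grid = enm_grid(nrow, ncol, cellsize, xll, yll),
    n_layers = n_layers, correlation = C, kernel_sigma = kernel_sigma,
    layer_means = layer_means, layer_sds = layer_sds,
    truth_active = truth_active,
    truth_coefficients = list(
      intercept = truth_intercept,
      linear = rep_len(truth_linear, length(truth_active)),
      quadratic = rep_len(truth_quadratic, length(truth_active))),
    n_gcm = n_gcm, rcps = rcps, periods = periods,
    scenario_shifts = scenario_shifts, gcm_noise_sd = gcm_noise_sd,
    n_regions = n_regions, seed = as.integer(seed)),
    class = "synthetic_spec")
}

correlation_matrix <- function(correlation, n_layers) {
  if (is.matrix(correlation)) {
    stopifnot(nrow(correlation) == n_layers,
              ncol(correlation) == n_layers)
    return(correlation)
  }
  C <- matrix(correlation, n_layers, n_layers)
  diag(C) <- 1
  C
}

# row/column Gaussian smoothing operator (rows normalized to sum 1)
smoothing_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

#' Generate a synthetic environmental layer stack
#'
#' Builds `n_layers` Gaussian-random-field layers with the requested
#' cross-layer Pearson correlation structure: white-noise fields are mixed
#' through the matrix square root of the target correlation matrix, then
#' each layer is smoothed with a separable Gaussian kernel (which preserves
#' cross-layer correlation), re-standardized over valid cells and rescaled
#' to `layer_means`/`layer_sds`. Deterministic for a fixed spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An `enm_stack` with layers named `env1 ... envK`.
#' @export
gen_env_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- spec$grid
  n_cell <- g$nrow * g$ncol
  eg <- eigen(spec$correlation, symmetric = TRUE)
  mixer <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)),
                               spec$n_layers) %*% t(eg$vectors)
  Kr <- smoothing_operator(g$nrow, spec$kernel_sigma)
  Kc <- smoothing_operator(g$ncol, spec$kernel_sigma)
  layers <- with_seed(derive_seed(spec$seed, "simulate"), {
    Z <- matrix(stats::rnorm(n_cell * spec$n_layers), n_cell)
    Z <- Z %*% t(mixer)
    lapply(seq_len(spec$n_layers), function(k) {
      f <- Kr %*% matrix(Z[, k], g$nrow, g$ncol) %*% Kc
      f <- (f - mean(f)) / stats::sd(f)
      spec$layer_means[k] + spec$layer_sds[k] * f
    })
  })
  names(layers) <- paste0("env", seq_len(spec$n_layers))
  enm_stack(g, layers)
}

#' Truth suitability surface of the synthetic system
#'
#' Evaluates the generating model on a stack: a linear + quadratic
#' combination of the standardized active layers passed through the cloglog
#' link `1 - exp(-exp(eta))`, giving suitability in [0, 1]. Used as ground
#' truth for parameter-recovery checks and for sampling occurrences.
#'
#' @param stack An `enm_stack` (typically from [gen_env_stack()]).
#' @param spec The [synthetic_spec()] holding the truth coefficients.
#' @return An object of class `truth_surface`: list with `values` (matrix
#'   of suitability, `NA` outside the mask), `grid`, and `coefficients`.
#' @export
truth_surface <- function(stack, spec) {
  cells <- which(stack$mask)
  vals <- stack_values(stack, cells)
  act <- spec$truth_active
  co <- spec$truth_coefficients
  eta <- rep(co$intercept, length(cells))
  for (k in seq_along(act)) {
    z <- vals[, act[k]]
    z <- (z - mean(z)) / stats::sd(z)
    eta <- eta + co$linear[k] * z + co$quadratic[k] * z^2
  }
  suit <- 1 - exp(-exp(eta))
  m <- matrix(NA_real_, stack$grid$nrow, stack$grid$ncol)
  m[cells] <- suit
  structure(list(values = m, grid = stack$grid, coefficients = co,
                 active_layers = names(stack$layers)[act]),
            class = "truth_surface")
}

#' Generate pseudo-GCM future stacks
#'
#' Each future stack is `baseline + scenario shift + per-GCM noise`, where
#' the shift is the per-layer additive trend for that RCP x period and the
#' noise is an independent per-(GCM, scenario, layer) offset with standard
#' deviation `gcm_noise_sd`.
#'
#' @param baseline An `enm_stack` on the spec's grid.
#' @param spec A [synthetic_spec()].
#' @return Named list of `enm_stack`s keyed `gcm<i>_<rcp>_<period>`; the
#'   key table is attached as attribute `"index"` (data.frame with columns
#'   gcm, rcp, period, key).
#' @export
gen_future_stacks <- function(baseline, spec) {
  if (!grids_identical(baseline$grid, spec$grid))
    stop("baseline grid does not match the spec grid")
  idx <- expand.grid(gcm = seq_len(spec$n_gcm), rcp = spec$rcps,
                     period = spec$periods, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  idx$key <- sprintf("gcm%02d_%s_%s", idx$gcm, idx$rcp, idx$period)
  out <- with_seed(derive_seed(spec$seed, "future"), {
    lapply(seq_len(nrow(idx)), function(r) {
      shift <- spec$scenario_shifts[[paste(idx$rcp[r], idx$period[r],
                                           sep = ".")]]
      eps <- stats::rnorm(spec$n_layers, 0, spec$gcm_noise_sd)
      layers <- lapply(seq_len(spec$n_layers), function(k)
        baseline$layers[[k]] + shift[k] + eps[k])
      names(layers) <- names(baseline$layers)
      enm_stack(baseline$grid, layers, baseline$mask)
    })
  })
  names(out) <- idx$key
  attr(out, "index") <- idx
  out
}

#' Sample occurrence records from a truth surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' truth suitability; each record is placed at the chosen cell's center
#' (no sub-cell jitter), which removes raster-lookup ambiguity downstream.
#'
#' @param truth A [truth_surface()].
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @param species Species label written into the table.
#' @return An `occurrence_set` (see [occurrence_set()]).
#' @export
sample_occurrences <- function(truth, n, seed = 1L,
                               species = "synthetic_vector") {
  stopifnot(inherits(truth, "truth_surface"), n >= 0)
  cells <- which(!is.na(truth$values))
  p <- truth$values[cells]
  if (n > 0 && sum(p) <= 0)
    stop("degenerate truth surface: all suitability values are zero")
  if (n == 0)
    return(occurrence_set(data.frame(species = character(),
                                     longitude = numeric(),
                                     latitude = numeric())))
  pick <- with_seed(seed, sample(cells, n, replace = TRUE, prob = p))
  cc <- cell_centers(truth$grid, pick)
  occurrence_set(data.frame(species = species,
                            longitude = cc$longitude,
                            latitude = cc$latitude),
                 dedupe = FALSE)
}

#' Generate synthetic cattle-abundance and region rasters
#'
#' The cattle field is lognormal (a smoothed Gaussian field exponentiated),
#' giving the right-skewed abundance distribution of real livestock
#' density data, in head per 10 km^2. Regions are contiguous
#' longitude-band blocks partitioning the valid cells, standing in for
#' zoogeographic realms.
#'
#' @param spec A [synthetic_spec()].
#' @param mask Optional validity mask (defaults to all cells).
#' @param log_mean,log_sd Location/scale of the log-abundance field.
#' @return List with `cattle` (matrix, head per 10 km^2) and `regions`
#'   (integer matrix 1..n_regions, with region names as attribute
#'   `"region_names"`).
#' @export
gen_cattle_and_regions <- function(spec, mask = NULL,
                                   log_mean = log(10), log_sd = 1.5) {
  g <- spec$grid
  if (is.null(mask)) mask <- matrix(TRUE, g$nrow, g$ncol)
  Kr <- smoothing_operator(g$nrow, spec$kernel_sigma)
  Kc <- smoothing_operator(g$ncol, spec$kernel_sigma)
  cattle <- with_seed(derive_seed(spec$seed, "cattle"), {
    f <- Kr %*% matrix(stats::rnorm(g$nrow * g$ncol), g$nrow, g$ncol) %*% Kc
    f <- (f - mean(f)) / stats::sd(f)
    exp(log_mean + log_sd * f)
  })
  cattle[!mask] <- NA
  k <- max(2L, as.integer(spec$n_regions))
  band <- pmin(k, 1L + ((col(mask) - 1L) * k) %/% g$ncol)
  regions <- matrix(band, g$nrow, g$ncol)
  regions[!mask] <- NA_integer_
  attr(regions, "region_names") <- paste0("region_", seq_len(k))
  list(cattle = cattle, regions = regions)
}
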