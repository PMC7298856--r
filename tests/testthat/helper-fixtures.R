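# Shared in-code fixtures: everything is generated, nothing is stored.

# small environmental stack with independent random layers
make_test_stack <- function(nrow = 20, ncol = 20, n_layers = 3, seed = 1,
                            cellsize = 0.2, xll = -55, yll = -15) {
  grid <- enm_grid(nrow, ncol, cellsize, xll, yll)
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(k)
    matrix(rnorm(nrow * ncol, mean = 10 * k, sd = 2), nrow, ncol))
  names(layers) <- paste0("env", seq_len(n_layers))
  enm_stack(grid, layers)
}

# occurrence set at arbitrary coordinates
make_occ <- function(lon, lat) {
  occurrence_set(data.frame(longitude = lon, latitude = lat),
                 dedupe = FALSE)
}

# occurrences placed at the centers of the given cells of a grid
occ_at_cells <- function(grid, cells) {
  cc <- cell_centers(grid, cells)
  make_occ(cc$longitude, cc$latitude)
}

# brute-force maximum subset of points with all pairwise distances >= d_km
brute_force_thin_max <- function(occ, d_km) {
  n <- nrow(occ)
  D <- haversine_matrix(occ$longitude, occ$latitude)
  best <- 0L
  for (code in 0:(2^n - 1)) {
    keep <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (length(keep) <= best) next
    sub <- D[keep, keep, drop = FALSE]
    if (all(sub[upper.tri(sub)] >= d_km)) best <- length(keep)
  }
  best
}

# deterministic micro-world for the exposure-table tests: a random present
# binary map, two change maps, lognormal cattle and two regions
make_exposure_fixture <- function(nrow = 50, ncol = 50, seed = 21) {
  grid <- enm_grid(nrow, ncol, 0.2, 0, 0)
  set.seed(seed)
  pres <- matrix(runif(nrow * ncol) < 0.4, nrow, ncol)
  present <- structure(list(binary = pres, threshold = 0.5, grid = grid),
                       class = "binary_map")
  mk_change <- function() {
    cls <- matrix(0L, nrow, ncol)
    cls[pres] <- sample(c(1L, 2L), sum(pres), replace = TRUE)
    gain_pool <- which(!pres)
    gains <- sample(gain_pool, length(gain_pool) %/% 3)
    cls[gains] <- sample(c(3L, 4L), length(gains), replace = TRUE)
    structure(list(classes = cls, grid = grid, cutoff = 12L, G = 20L),
              class = "change_map")
  }
  change <- list(rcp45 = mk_change(), rcp85 = mk_change())
  cattle <- matrix(rlnorm(nrow * ncol, log(10), 1.5), nrow, ncol)
  regions <- matrix(rep(1:2, each = nrow * ncol / 2), nrow, ncol)
  attr(regions, "region_names") <- c("west", "east")
  list(present = present, change = change,
       cats = categorize_cattle(cattle), regions = regions,
       cattle = cattle)
}

# a deterministic fitted toy model + stack for prediction-level tests
make_toy_fit <- function(seed = 11, n_pres = 150, classes = c("l", "q"),
                         rm = 1, nrow = 40, ncol = 40) {
  spec <- synthetic_spec(nrow = nrow, ncol = ncol, seed = seed)
  st <- gen_env_stack(spec)
  tr <- truth_surface(st, spec)
  occ <- sample_occurrences(tr, n_pres, seed = seed + 1)
  cells <- which(st$mask)
  bg <- stack_values(st, cells)
  idx <- cell_index(st$grid, occ$longitude, occ$latitude)
  pres <- stack_values(st, idx)
  model <- fit_maxent(pres, bg, classes = classes, rm = rm)
  list(spec = spec, stack = st, truth = tr, occ = occ, pres = pres,
       bg = bg, model = model, cells = cells)
}
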