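test_that("generated stacks reproduce the requested correlation structure", {
  # independent layers: all pairwise |r| small
  spec0 <- synthetic_spec(nrow = 100, ncol = 100, correlation = 0,
                          seed = 42)
  v0 <- stack_values(gen_env_stack(spec0))
  r0 <- cor(v0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)
  # strongly correlated pair
  spec95 <- synthetic_spec(nrow = 100, ncol = 100, n_layers = 2,
                           correlation = 0.95, seed = 42)
  v95 <- stack_values(gen_env_stack(spec95))
  expect_gte(cor(v95)[1, 2], 0.85)
  expect_lte(cor(v95)[1, 2], 1.0)
  # general target recovered within +/- 0.1
  spec <- synthetic_spec(nrow = 100, ncol = 100, correlation = 0.3,
                         seed = 7)
  v <- stack_values(gen_env_stack(spec))
  r <- cor(v)
  expect_true(all(abs(r[upper.tri(r)] - 0.3) < 0.1))
})

test_that("generators are deterministic in the spec seed", {
  spec <- synthetic_spec(nrow = 30, ncol = 30, seed = 5)
  s1 <- gen_env_stack(spec)
  s2 <- gen_env_stack(spec)
  expect_identical(s1$layers, s2$layers)
  aux1 <- gen_cattle_and_regions(spec)
  aux2 <- gen_cattle_and_regions(spec)
  expect_identical(aux1, aux2)
  tr <- truth_surface(s1, spec)
  expect_identical(sample_occurrences(tr, 50, seed = 3),
                   sample_occurrences(tr, 50, seed = 3))
})

test_that("non-PSD correlation matrices are rejected", {
  C <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(synthetic_spec(n_layers = 3, correlation = C),
               "positive semi-definite")
})

test_that("future stacks are baseline + shift + per-GCM noise", {
  # zero shift, zero noise: futures equal baseline exactly
  zero_shifts <- list(rcp45.2050 = rep(0, 4), rcp45.2070 = rep(0, 4),
                      rcp85.2050 = rep(0, 4), rcp85.2070 = rep(0, 4))
  spec <- synthetic_spec(nrow = 15, ncol = 15, n_layers = 4,
                         n_gcm = 3, scenario_shifts = zero_shifts,
                         gcm_noise_sd = 0, seed = 2)
  base <- gen_env_stack(spec)
  fut <- gen_future_stacks(base, spec)
  expect_length(fut, 3 * 2 * 2)
  expect_equal(fut[[1]]$layers, base$layers)
  # known shift on layer 1, no noise: constant difference raster
  shifts <- zero_shifts
  shifts$rcp85.2070 <- c(2, 0, 0, 0)
  spec2 <- synthetic_spec(nrow = 15, ncol = 15, n_layers = 4, n_gcm = 2,
                          scenario_shifts = shifts, gcm_noise_sd = 0,
                          seed = 2)
  fut2 <- gen_future_stacks(base, spec2)
  idx <- attr(fut2, "index")
  key <- idx$key[idx$rcp == "rcp85" & idx$period == "2070"][1]
  diff1 <- fut2[[key]]$layers$env1 - base$layers$env1
  expect_equal(range(diff1), c(2, 2), tolerance = 1e-12)
  expect_equal(fut2[[key]]$layers$env2, base$layers$env2)
  # full ensemble size: 20 GCMs x 2 RCPs x 2 periods = 80
  spec3 <- synthetic_spec(nrow = 5, ncol = 5, n_gcm = 20, seed = 3)
  base3 <- gen_env_stack(spec3)
  expect_length(gen_future_stacks(base3, spec3), 80)
  # grid mismatch rejected
  expect_error(gen_future_stacks(base3, spec2), "grid")
})

test_that("across-GCM mean anomaly tracks the specified shift", {
  spec <- synthetic_spec(nrow = 10, ncol = 10, n_layers = 3, n_gcm = 20,
                         gcm_noise_sd = 0.5, seed = 9)
  base <- gen_env_stack(spec)
  fut <- gen_future_stacks(base, spec)
  idx <- attr(fut, "index")
  keys <- idx$key[idx$rcp == "rcp45" & idx$period == "2050"]
  anom1 <- vapply(keys, function(k)
    mean(fut[[k]]$layers$env1 - base$layers$env1), 0)
  shift1 <- spec$scenario_shifts[["rcp45.2050"]][1]
  expect_lt(abs(mean(anom1) - shift1), 3 * 0.5 / sqrt(20))
})

test_that("occurrence sampling follows the truth surface", {
  spec <- synthetic_spec(nrow = 10, ncol = 10, seed = 4)
  st <- gen_env_stack(spec)
  # suitability 1 in a single cell: all records land there
  one <- matrix(0, 10, 10)
  one[4, 7] <- 1
  tr1 <- structure(list(values = one, grid = st$grid), class = "truth_surface")
  occ1 <- sample_occurrences(tr1, 10, seed = 1)
  expect_equal(nrow(occ1), 10)
  expect_equal(unique(cell_index(st$grid, occ1$longitude, occ1$latitude)),
               which(one == 1))
  # n = 0 is an empty set; all-zero truth errors
  expect_equal(nrow(sample_occurrences(tr1, 0)), 0)
  tr0 <- structure(list(values = matrix(0, 10, 10), grid = st$grid),
                   class = "truth_surface")
  expect_error(sample_occurrences(tr0, 5), "degenerate")
  # uniform truth: per-cell counts consistent with a uniform multinomial
  spec_u <- synthetic_spec(nrow = 25, ncol = 25, truth_linear = 0,
                           truth_quadratic = 0, seed = 6)
  st_u <- gen_env_stack(spec_u)
  tr_u <- truth_surface(st_u, spec_u)
  expect_equal(sd(tr_u$values), 0)
  occ_u <- sample_occurrences(tr_u, 5000, seed = 2)
  counts <- tabulate(cell_index(st_u$grid, occ_u$longitude,
                                occ_u$latitude), nbins = 625)
  gof <- suppressWarnings(chisq.test(counts, p = rep(1 / 625, 625)))
  expect_gt(gof$p.value, 0.001)
})

test_that("cattle and region rasters have the documented structure", {
  spec <- synthetic_spec(nrow = 20, ncol = 20, n_regions = 2, seed = 8)
  aux <- gen_cattle_and_regions(spec)
  expect_true(all(aux$cattle >= 0, na.rm = TRUE))
  # right skew of the lognormal field
  expect_gt(mean(aux$cattle), median(aux$cattle))
  expect_setequal(unique(c(aux$regions)), c(1L, 2L))
  expect_false(anyNA(aux$regions))
})
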