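test_that("pearson filter removes collinear layers and keeps independent ones", {
  st <- make_test_stack(30, 30, 3, seed = 1)
  # duplicate layer: exactly one of the pair survives
  st$layers$env4 <- st$layers$env1
  st <- enm_stack(st$grid, st$layers)
  kept <- pearson_filter(st, r_max = 0.80)
  expect_length(intersect(c("env1", "env4"), kept), 1)
  # independent random layers all survive
  st2 <- make_test_stack(40, 40, 5, seed = 2)
  expect_setequal(pearson_filter(st2, r_max = 0.80),
                  names(st2$layers))
  # constant layer flagged and removed
  st3 <- make_test_stack(20, 20, 2, seed = 3)
  st3$layers$flat <- matrix(1, 20, 20)
  st3 <- enm_stack(st3$grid, st3$layers)
  expect_warning(kept3 <- pearson_filter(st3), "constant")
  expect_false("flat" %in% kept3)
})

test_that("filter output never violates the threshold (constructed stack)", {
  # 4 layers with a known correlation structure: env2 = env1 + small noise,
  # env3 = -env1 + noise (high |r|), env4 independent
  grid <- enm_grid(50, 50, 0.2, 0, 0)
  set.seed(5)
  base <- matrix(rnorm(2500), 50, 50)
  layers <- list(env1 = base,
                 env2 = base + matrix(rnorm(2500, sd = 0.1), 50, 50),
                 env3 = -base + matrix(rnorm(2500, sd = 0.1), 50, 50),
                 env4 = matrix(rnorm(2500), 50, 50))
  st <- enm_stack(grid, layers)
  kept <- pearson_filter(st, r_max = 0.80)
  vals <- stack_values(st, layers = kept)
  R <- abs(cor(vals))
  diag(R) <- 0
  expect_lt(max(R), 0.80)
  expect_true("env4" %in% kept)
  # deterministic: re-running gives the identical retained set
  expect_identical(kept, pearson_filter(st, r_max = 0.80))
})

test_that("variable-set enumeration matches the closed-form count", {
  expect_length(enumerate_variable_sets(letters[1:7]), 120)
  expect_length(enumerate_variable_sets(letters[1:2]), 1)
  expect_length(enumerate_variable_sets(letters[1:5]), 26)
  for (v in 2:9) for (ms in 2:3) {
    if (v < ms) next
    sets <- enumerate_variable_sets(letters[1:v], ms)
    expected <- 2^v - sum(choose(v, 0:(ms - 1)))
    expect_length(sets, expected)
    expect_false(anyDuplicated(vapply(sets, paste, "", collapse = "+")) > 0)
    expect_true(all(lengths(sets) >= ms))
  }
  expect_warning(none <- enumerate_variable_sets("a", 2), "fewer")
  expect_length(none, 0)
})

test_that("delta downscaling is exact for zero and uniform anomalies", {
  coarse_grid <- enm_grid(6, 6, 1, -60, -20)
  fine_grid <- enm_grid(20, 20, 0.2, -59, -19)
  set.seed(7)
  cb <- enm_raster(matrix(rnorm(36, 20, 5), 6, 6), coarse_grid)
  fb <- enm_raster(matrix(rnorm(400, 20, 5), 20, 20), fine_grid)
  # zero anomaly: identity
  out0 <- delta_downscale(cb, cb, fb)
  expect_equal(out0$values, fb$values)
  # uniform +2 anomaly everywhere
  cf <- enm_raster(cb$values + 2, coarse_grid)
  out2 <- delta_downscale(cb, cf, fb)
  expect_equal(out2$values, fb$values + 2)
  # linearity in the anomaly
  cf3 <- enm_raster(cb$values + 3 * (cf$values - cb$values), coarse_grid)
  out3 <- delta_downscale(cb, cf3, fb)
  expect_equal(out3$values - fb$values, 3 * (out2$values - fb$values))
})

test_that("delta downscaling matches the direct bilinear formula at probes", {
  coarse_grid <- enm_grid(8, 8, 1, -60, -20)
  fine_grid <- enm_grid(25, 25, 0.2, -58.5, -18.5)
  set.seed(8)
  anom <- matrix(rnorm(64), 8, 8)
  cb <- enm_raster(matrix(rnorm(64), 8, 8), coarse_grid)
  cf <- enm_raster(cb$values + anom, coarse_grid)
  fb <- enm_raster(matrix(0, 25, 25), fine_grid)
  out <- delta_downscale(cb, cf, fb)
  cc <- cell_centers(fine_grid)
  set.seed(9)
  probes <- sample(625, 20)
  for (p in probes) {
    x <- cc$longitude[p]; y <- cc$latitude[p]
    # independent bilinear evaluation in cell-center coordinates
    gx <- (x - (-60 + 0.5)) / 1
    gy <- ((-20 + 8 - 0.5) - y) / 1
    j0 <- min(floor(gx) + 1, 7); i0 <- min(floor(gy) + 1, 7)
    tx <- gx - (j0 - 1); ty <- gy - (i0 - 1)
    want <- (1 - ty) * ((1 - tx) * anom[i0, j0] + tx * anom[i0, j0 + 1]) +
      ty * ((1 - tx) * anom[i0 + 1, j0] + tx * anom[i0 + 1, j0 + 1])
    expect_equal(out$values[p], want, tolerance = 1e-9)
  }
  # extent violation is an error
  far_grid <- enm_grid(25, 25, 0.2, -70, -18.5)
  expect_error(delta_downscale(cb, cf, enm_raster(matrix(0, 25, 25),
                                                  far_grid)), "nested")
  # clipping for bounded variables such as relative humidity
  rh <- enm_raster(matrix(99, 25, 25), fine_grid)
  big <- enm_raster(cb$values + 50, coarse_grid)
  clipped <- delta_downscale(cb, big, rh, clip = c(0, 100))
  expect_true(all(clipped$values <= 100))
})

test_that("cropping to an accessible area masks layers and validates grids", {
  st <- make_test_stack(20, 20, 2, seed = 4)
  full <- structure(list(mask = matrix(TRUE, 20, 20), buffer_km = 0,
                         grid = st$grid), class = "accessible_area")
  same <- crop_stack(st, full)
  expect_equal(stack_values(same), stack_values(st))
  checker <- matrix((row(matrix(0, 20, 20)) + col(matrix(0, 20, 20))) %% 2
                    == 0, 20, 20)
  cropped <- crop_stack(st, checker)
  expect_equal(sum(cropped$mask), sum(checker))
  expect_equal(nrow(stack_values(cropped)), sum(checker))
  empty <- matrix(FALSE, 20, 20)
  expect_error(crop_stack(st, empty), "intersect")
})
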