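test_that("bootstrap median model reduces to the obvious special cases", {
  fit <- make_toy_fit(seed = 41, nrow = 30, ncol = 30)
  targets <- list(present = fit$stack)
  # n_boot = 1: output equals the single replicate's prediction
  one <- bootstrap_median_model(fit$stack, fit$occ, fit$model$vars,
                                c("l", "q"), 1, targets, n_boot = 1,
                                seed = 2)
  single <- predict(one$models[[1]], fit$stack)
  expect_equal(one$projections$present$values, single$values)
  # resampling disabled: all replicates identical, median equals any one
  same <- bootstrap_median_model(fit$stack, fit$occ, fit$model$vars,
                                 c("l", "q"), 1, targets, n_boot = 4,
                                 seed = 2, resample = FALSE)
  expect_equal(same$projections$present$values,
               predict(same$models[[1]], fit$stack)$values)
  # seeded reproducibility
  a <- bootstrap_median_model(fit$stack, fit$occ, fit$model$vars,
                              c("l", "q"), 1, targets, n_boot = 5,
                              seed = 7)
  b <- bootstrap_median_model(fit$stack, fit$occ, fit$model$vars,
                              c("l", "q"), 1, targets, n_boot = 5,
                              seed = 7)
  expect_identical(a$projections, b$projections)
})

test_that("MOP equals the brute-force all-pairs computation on small grids", {
  spec1 <- synthetic_spec(nrow = 10, ncol = 10, n_layers = 3, seed = 3)
  spec2 <- synthetic_spec(nrow = 10, ncol = 10, n_layers = 3, seed = 4)
  s1 <- gen_env_stack(spec1)
  s2 <- gen_env_stack(spec2)
  names(s2$layers) <- names(s1$layers)
  mo <- mop(s1, s2, reference_fraction = 0.1)
  cal <- stack_values(s1); proj <- stack_values(s2)
  lo <- apply(cal, 2, min); hi <- apply(cal, 2, max); span <- hi - lo
  calz <- sweep(sweep(cal, 2, lo), 2, span, "/")
  projz <- sweep(sweep(proj, 2, lo), 2, span, "/")
  nref <- ceiling(0.1 * nrow(calz))
  dv <- apply(projz, 1, function(r)
    mean(sort(sqrt(colSums((t(calz) - r)^2)))[seq_len(nref)]))
  sim_oracle <- 1 - dv / max(dv)
  expect_equal(mo$similarity$values[which(s2$mask)], sim_oracle,
               tolerance = 1e-9)
})

test_that("MOP similarity, strict extrapolation and invariances behave", {
  spec <- synthetic_spec(nrow = 12, ncol = 12, n_layers = 3, seed = 6)
  st <- gen_env_stack(spec)
  # projecting the calibration stack onto itself: cells identical to a
  # calibration cell have distance 0 somewhere, similarity max = 1
  self <- mop(st, st, reference_fraction = 1 / sum(st$mask))
  expect_equal(max(self$similarity$values, na.rm = TRUE), 1)
  expect_false(any(self$strict, na.rm = TRUE))
  # a variable pushed above its calibration max flags strict extrapolation
  out <- st
  out$layers$env1[3, 3] <- max(st$layers$env1) + 10
  out <- enm_stack(st$grid, out$layers, st$mask)
  mo <- mop(st, out, reference_fraction = 0.1)
  expect_true(mo$strict[3, 3])
  expect_true(all(mo$similarity$values >= 0 & mo$similarity$values <= 1,
                  na.rm = TRUE))
  # similarity invariant under affine rescaling of a single variable
  resc <- function(s) {
    s$layers$env2 <- 100 + 7 * s$layers$env2
    enm_stack(s$grid, s$layers, s$mask)
  }
  mo_raw <- mop(st, out, reference_fraction = 0.1)
  mo_scl <- mop(resc(st), resc(out), reference_fraction = 0.1)
  expect_equal(mo_scl$similarity$values, mo_raw$similarity$values,
               tolerance = 1e-9)
  expect_error(mop(subset_stack(st, c("env1", "env2")), out), "variables")
})

test_that("binarization satisfies the E-percentile omission guarantee", {
  grid <- enm_grid(4, 5, 0.2, 0, 0)
  pred <- enm_raster(matrix(seq(0.05, 1, by = 0.05), 4, 5), grid)
  cal_suit <- seq(0.05, 1, by = 0.05)
  bin <- binarize(pred, cal_suit, 0.05)
  expect_equal(bin$threshold, 0.10)
  expect_equal(mean(cal_suit < bin$threshold), 1 / 20)
  bin0 <- binarize(pred, cal_suit, 0)
  expect_equal(bin0$threshold, min(cal_suit))
  expect_equal(mean(cal_suit < bin0$threshold), 0)
  # random fixtures across E values
  set.seed(5)
  for (E in c(0.01, 0.05, 0.1)) {
    v <- runif(83)
    thr <- binarize(pred, v, E)$threshold
    expect_lte(mean(v < thr), E)
  }
})

test_that("ensemble agreement counts votes and applies the 60% cutoff", {
  grid <- enm_grid(5, 5, 0.2, 0, 0)
  set.seed(8)
  mats <- lapply(1:20, function(i)
    matrix(runif(25) > 0.5, 5, 5))
  bins <- lapply(mats, function(m)
    structure(list(binary = m, threshold = 0.5, grid = grid),
              class = "binary_map"))
  ag <- agreement(bins, 0.6)
  expect_equal(ag$cutoff, 12)
  expect_equal(ag$G, 20)
  expect_equal(ag$counts, Reduce(`+`, lapply(mats, `+`, 0L)))
  all_on <- agreement(rep(bins[1], 3))
  expect_true(all(all_on$counts[mats[[1]]] == 3))
  expect_error(agreement(list(bins[[1]],
                              structure(list(binary = matrix(TRUE, 4, 4),
                                             grid = enm_grid(4, 4)),
                                        class = "binary_map"))), "grid")
})

test_that("change classification partitions the valid cells", {
  grid <- enm_grid(4, 4, 0.2, 0, 0)
  pres <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 4)
  cnt <- matrix(c(15L, 5L, 15L, 5L, 0L, 20L, 3L, 0L), 4, 4)
  present <- structure(list(binary = pres, threshold = 0.5, grid = grid),
                       class = "binary_map")
  ag <- structure(list(counts = cnt, G = 20L, cutoff = 12L, grid = grid),
                  class = "agreement_map")
  cm <- classify_change(present, ag)
  # spot checks against the class definitions
  expect_equal(cm$classes[pres & cnt >= 12][1], 2L)  # stable strong
  expect_equal(cm$classes[pres & cnt < 12][1], 1L)   # weakening
  expect_equal(cm$classes[!pres & cnt >= 12][1], 4L) # gain strong
  expect_equal(cm$classes[!pres & cnt > 0 & cnt < 12][1], 3L) # gain weak
  expect_equal(cm$classes[!pres & cnt == 0][1], 0L)  # unsuitable
  # partition: every valid cell has exactly one class
  expect_false(anyNA(cm$classes))
  expect_equal(sum(table(cm$classes)), 16)
  # median projection invariance to replicate order is a property of the
  # cellwise median itself
  set.seed(1)
  reps <- lapply(1:5, function(i) matrix(runif(16), 4, 4))
  med1 <- apply(simplify2array(reps), c(1, 2), median)
  med2 <- apply(simplify2array(rev(reps)), c(1, 2), median)
  expect_equal(med1, med2)
})
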