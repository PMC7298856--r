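test_that("omission rate is the fraction of evaluation points below threshold", {
  grid <- enm_grid(1, 145, 0.2, 0, 0)
  pred <- enm_raster(matrix(seq(0.001, 1, length.out = 145), 1, 145), grid)
  occ <- occ_at_cells(grid, 1:145)
  thr <- pred$values[1, 12]  # exactly 11 cells fall below
  rate <- omission_rate(pred, occ, thr)
  expect_equal(as.numeric(rate), 11 / 145)
  expect_equal(attr(rate, "n_omitted"), 11)
  # threshold at/below the minimum: zero omission; above max: one
  expect_equal(as.numeric(omission_rate(pred, occ, min(pred$values))), 0)
  expect_equal(as.numeric(omission_rate(pred, occ, 2)), 1)
  # off-grid points are excluded with a warning and reported
  occ_off <- make_occ(c(0.1, 50), c(0.1, 0.1))
  expect_warning(r2 <- omission_rate(pred, occ_off, 0), "excluded")
  expect_equal(attr(r2, "n_used"), 1)
})

test_that("partial ROC handles degenerate and informative predictions", {
  grid <- enm_grid(10, 10, 0.2, 0, 0)
  flat <- enm_raster(matrix(0.5, 10, 10), grid)
  occ <- occ_at_cells(grid, 1:20)
  expect_warning(pr <- partial_roc(flat, occ, seed = 1), "constant")
  expect_equal(pr$auc_ratio, 1)
  expect_equal(pr$p, 1)
  # a prediction equal to the truth that generated the points is significant
  spec <- synthetic_spec(nrow = 50, ncol = 50, seed = 31)
  st <- gen_env_stack(spec)
  tr <- truth_surface(st, spec)
  pts <- sample_occurrences(tr, 100, seed = 8)
  pr2 <- partial_roc(enm_raster(tr$values, tr$grid), pts,
                     iterations = 500, seed = 5)
  expect_lt(pr2$p, 0.05)
  expect_gt(pr2$auc_ratio, 1)
  # deterministic under a fixed seed
  pr3 <- partial_roc(enm_raster(tr$values, tr$grid), pts,
                     iterations = 500, seed = 5)
  expect_identical(pr2$ratios, pr3$ratios)
})

test_that("AICc matches the closed form and the independent oracle", {
  expect_equal(aicc_value(-50, 2, 100), 4 + 100 + 12 / 97)
  expect_true(is.infinite(aicc_value(-50, 99, 100)))
  expect_true(attr(aicc_value(-50, 99, 100), "undefined"))
  # second, independent evaluation of the formula on random instances
  set.seed(12)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    k <- sample(1:(n - 2), 1)
    lnL <- rnorm(1, -100, 50)
    oracle <- 2 * k - 2 * lnL + (2 * k * (k + 1)) / (n - k - 1)
    expect_equal(aicc_value(lnL, k, n), oracle, tolerance = 1e-9)
  }
})

test_that("omission threshold is the E-percentile rule", {
  vals <- seq(0.05, 1, by = 0.05)
  expect_equal(omission_threshold(vals, 0.05), 0.10)
  expect_equal(omission_threshold(vals, 0), 0.05)
  # random values: calibration omission <= E, threshold maximal with that
  # property among observed values
  set.seed(4)
  for (E in c(0.01, 0.05, 0.1)) {
    v <- runif(137)
    thr <- omission_threshold(v, E)
    expect_lte(mean(v < thr), E)
    larger <- sort(v)[sort(v) > thr]
    if (length(larger)) expect_gt(mean(v < larger[1]), E)
  }
})

test_that("candidate calibration covers the grid deterministically", {
  spec <- synthetic_spec(nrow = 40, ncol = 40, n_layers = 4, seed = 51)
  st <- gen_env_stack(spec)
  tr <- truth_surface(st, spec)
  occ <- sample_occurrences(tr, 120, seed = 3)
  sp <- split_calibration(occ, 0.5, seed = 1)
  sets <- list(c("env1", "env2"), c("env3", "env4"))
  classes <- list("l", c("l", "q"))
  cands <- calibrate_candidates(st, sp$calibration, sp$evaluation,
                                sets, classes, rms = c(0.5, 1),
                                proc_iterations = 100, seed = 9)
  expect_s3_class(cands, "candidate_table")
  expect_equal(nrow(cands), 2 * 2 * 2)
  expect_false(any(cands$failed))
  expect_true(all(cands$omission >= 0 & cands$omission <= 1))
  expect_true(all(cands$p >= 0 & cands$p <= 1))
  cands2 <- calibrate_candidates(st, sp$calibration, sp$evaluation,
                                 sets, classes, rms = c(0.5, 1),
                                 proc_iterations = 100, seed = 9)
  expect_identical(cands, cands2)
})

test_that("selection applies significance, omission and AICc in order", {
  tab <- data.frame(
    id = c("A", "B", "C", "D"),
    variables = c("x+y", "x+y", "x+y+z", "x"),
    classes = "lq", rm = 1,
    auc_ratio = c(1.4, 1.3, 1.2, 1.0),
    p = c(0.001, 0.001, 0.001, 0.8),     # D not significant
    omission = c(0.02, 0.04, 0.30, 0.01), # C fails performance
    aicc = c(126.5, 100.0, 90.0, 50.0),
    k = c(4L, 6L, 2L, 1L), failed = FALSE, stringsAsFactors = FALSE)
  class(tab) <- c("candidate_table", "data.frame")
  rep <- select_best(tab)
  expect_equal(rep$best$id, "B")
  expect_equal(rep$delta_aicc, 26.5)
  expect_equal(unname(rep$counts),
               c(4L, 3L, 2L, 1L))
  expect_true(rep$counts["selected"] <= rep$counts["performant"])
  expect_true(rep$counts["performant"] <= rep$counts["significant"])
  expect_true(rep$counts["significant"] <= rep$counts["total"])
  # AICc tie broken by smaller k
  tab2 <- tab
  tab2$aicc <- c(100, 100, 90, 50)
  class(tab2) <- class(tab)
  expect_equal(select_best(tab2)$best$id, "A")
  # nothing significant is an error
  tab3 <- tab; tab3$p <- 0.9
  class(tab3) <- class(tab)
  expect_error(select_best(tab3), "significant")
  # omission fallback is flagged as relaxed
  tab4 <- tab; tab4$omission <- c(0.4, 0.3, 0.2, 0.1)
  class(tab4) <- class(tab)
  rep4 <- select_best(tab4)
  expect_true(rep4$relaxed)
  expect_equal(rep4$best$id, "C")
})
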