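#' Extract prediction values at occurrence points
#'
#' @param pred An `enm_raster` of predictions.
#' @param occ An [occurrence_set()].
#' @return Numeric vector of prediction values at the occurrence cells;
#'   points off-grid or on no-data cells are dropped with a warning and
#'   the dropped count attached as attribute `"n_excluded"`.
#' @export
prediction_at <- function(pred, occ) {
  idx <- cell_index(pred$grid, occ$longitude, occ$latitude)
  vals <- rep(NA_real_, nrow(occ))
  ok <- !is.na(idx)
  vals[ok] <- pred$values[idx[ok]]
  excluded <- sum(is.na(vals))
  if (excluded > 0)
    warning(excluded, " occurrence point(s) off-grid or on no-data cells; excluded")
  out <- vals[!is.na(vals)]
  attr(out, "n_excluded") <- excluded
  out
}

#' Omission rate of evaluation occurrences
#'
#' Fraction of evaluation points whose predicted value falls below the
#' threshold: `(# points with prediction < threshold) / (# points)`.
#'
#' @param pred An `enm_raster` (any monotone scale, matching `threshold`).
#' @param occ Evaluation [occurrence_set()].
#' @param threshold Suitability threshold on `pred`'s scale.
#' @return Omission rate in [0, 1], with attributes `"n_omitted"` and
#'   `"n_used"`.
#' @export
omission_rate <- function(pred, occ, threshold) {
  vals <- prediction_at(pred, occ)
  if (!length(vals)) stop("no evaluation points fall on valid cells")
  n_om <- sum(vals < threshold)
  rate <- n_om / length(vals)
  attr(rate, "n_omitted") <- n_om
  attr(rate, "n_used") <- length(vals)
  rate
}

#' Partial ROC significance test
#'
#' Compares the model's partial AUC — the region of the ROC curve with
#' sensitivity at least `1 - E`, i.e. tolerating at most an omission
#' error `E` — to the random-expectation diagonal over the same range,
#' via bootstrap. Each iteration resamples
#' `ceiling(resample_fraction * n)` evaluation points with replacement and
#' computes the AUC ratio `pAUC_model / pAUC_random`; the p-value is the
#' fraction of iterations with ratio <= 1.
#'
#' The ROC curve is traced over the raster's own value distribution:
#' x = fraction of valid cells predicted suitable at a threshold,
#' y = sensitivity of the (resampled) evaluation points at the same
#' threshold. The integration window — the thresholds at which the full
#' evaluation data keep sensitivity >= 1 - E — is fixed before
#' resampling; selecting it per bootstrap iteration from the resampled
#' (noisier) curve inflates the AUC ratio under the null and makes the
#' test anti-conservative.
#'
#' @param pred An `enm_raster` of continuous predictions.
#' @param occ Evaluation [occurrence_set()] (>= 10 points recommended).
#' @param E Acceptable omission error (study default 0.05).
#' @param iterations Bootstrap iterations (default 500).
#' @param resample_fraction Fraction of points resampled per iteration
#'   (default 0.5).
#' @param seed Integer seed.
#' @param max_thresholds Cap on the number of distinct thresholds used to
#'   trace the curve (quantile-binned above this).
#' @return List: `auc_ratio` (mean bootstrap ratio), `p`, `ratios`
#'   (per-iteration), `n_points`.
#' @export
partial_roc <- function(pred, occ, E = 0.05, iterations = 500L,
                        resample_fraction = 0.5, seed = 1L,
                        max_thresholds = 200L) {
  stopifnot(E > 0, E < 1, iterations >= 1)
  cellvals <- pred$values[!is.na(pred$values)]
  occv <- prediction_at(pred, occ)
  n <- length(occv)
  if (n < 1) stop("no evaluation points on valid cells")
  if (stats::sd(cellvals) == 0) {
    warning("constant prediction surface: partial ROC undefined; ",
            "returning ratio 1, p 1")
    return(list(auc_ratio = 1, p = 1, ratios = rep(1, iterations),
                n_points = n))
  }
  ts <- sort(unique(cellvals))
  if (length(ts) > max_thresholds)
    ts <- sort(unique(stats::quantile(cellvals,
                                      seq(0, 1, length.out = max_thresholds),
                                      names = FALSE)))
  K <- length(ts)
  # fraction of valid cells predicted suitable at each threshold
  area <- 1 - (findInterval(ts, sort(cellvals), left.open = TRUE)) /
    length(cellvals)
  # occurrence bin: largest k with ts[k] <= value (value >= ts[k] iff bin >= k)
  b <- findInterval(occv, ts)
  # fixed integration window: thresholds where the full evaluation data
  # keep sensitivity >= 1 - E (a prefix, since sensitivity is
  # nonincreasing in the threshold)
  sens_full <- rev(cumsum(rev(tabulate(b, nbins = K)))) / n
  kN <- sum(sens_full >= 1 - E)
  if (kN < 2) {
    warning("partial ROC degenerate (no curve above sensitivity 1 - E)")
    return(list(auc_ratio = 1, p = 1, ratios = rep(NA_real_, iterations),
                n_points = n))
  }
  pauc_random <- (area[1]^2 - area[kN]^2) / 2
  d <- area[seq_len(kN - 1)] - area[2:kN]   # >= 0, area descending in k
  m <- ceiling(resample_fraction * n)
  idx <- with_seed(seed,
                   matrix(sample.int(n, m * iterations, replace = TRUE),
                          m, iterations))
  # per-iteration sensitivity at the window thresholds (kN x iterations)
  tab <- vapply(seq_len(iterations),
                function(i) tabulate(b[idx[, i]], nbins = K),
                integer(K))
  tab <- matrix(tab, nrow = K)
  sens <- apply(tab[K:1, , drop = FALSE], 2, cumsum)[K:1, , drop = FALSE] / m
  trap <- d * (sens[seq_len(kN - 1), , drop = FALSE] +
                 sens[2:kN, , drop = FALSE]) / 2
  ratios <- colSums(matrix(trap, nrow = kN - 1)) / pauc_random
  list(auc_ratio = mean(ratios), p = mean(ratios <= 1),
       ratios = ratios, n_points = n)
}

#' Corrected Akaike information criterion
#'
#' `AICc = 2k - 2 lnL + 2k(k+1) / (n - k - 1)`; `+Inf` (with attribute
#' `"undefined"`) when `k >= n - 1`.
#'
#' @param lnL Log-likelihood.
#' @param k Number of parameters.
#' @param n Sample size.
#' @return AICc value.
#' @export
aicc_value <- function(lnL, k, n) {
  if (k >= n - 1) {
    out <- Inf
    attr(out, "undefined") <- TRUE
    return(out)
  }
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc of a fitted Maxent-class model
#'
#' The likelihood is the model's raw output (a probability distribution
#' over the training background) evaluated at the calibration
#' occurrences: `lnL = sum_i log raw(x_i)`, with `k` the number of
#' nonzero feature weights and `n` the number of calibration points used.
#'
#' @param model A `maxent_model`.
#' @param raw_pred `enm_raster` of raw-scale predictions on the
#'   calibration stack.
#' @param occ Calibration [occurrence_set()].
#' @return AICc value (may be `+Inf` with attribute `"undefined"`).
#' @export
aicc_maxent <- function(model, raw_pred, occ) {
  vals <- prediction_at(raw_pred, occ)
  n <- length(vals)
  if (any(vals <= 0)) {
    out <- Inf
    attr(out, "undefined") <- TRUE
    return(out)
  }
  aicc_value(sum(log(vals)), count_parameters(model), n)
}

#' Omission threshold from calibration suitabilities
#'
#' The E-percentile rule used both for binarization and for the
#' performance filter: the threshold is the `(floor(E * n) + 1)`-th
#' smallest calibration suitability, i.e. the largest observed value
#' guaranteeing calibration omission <= E.
#'
#' @param cal_suit Suitability values at calibration occurrences.
#' @param E Acceptable omission error.
#' @return The threshold value.
#' @export
omission_threshold <- function(cal_suit, E = 0.05) {
  stopifnot(length(cal_suit) >= 1, E >= 0, E < 1)
  sort(cal_suit)[floor(E * length(cal_suit)) + 1]
}

#' Evaluate a grid of candidate models
#'
#' Fits one Maxent-class model per (variable set x feature-class subset x
#' regularization multiplier) grid point on the calibration data, and
#' records for each: partial-ROC mean AUC ratio and p-value (evaluation
#' points), omission rate of the evaluation points at the calibration
#' E-percentile threshold, AICc (calibration points, raw scale), and k.
#' Candidates whose fit fails are recorded with `failed = TRUE`, never
#' dropped silently.
#'
#' @param cal_stack Calibration `enm_stack` (cropped to the accessible
#'   area).
#' @param cal_occ,eval_occ Calibration and evaluation
#'   [occurrence_set()]s.
#' @param variable_sets List of character vectors (from
#'   [enumerate_variable_sets()]).
#' @param class_subsets List of feature-class vectors (e.g.
#'   `list("l", c("l","q"), c("l","q","p","t","h"))`).
#' @param rms Numeric vector of regularization multipliers.
#' @param E,alpha Evaluation parameters (acceptable omission error and
#'   significance level).
#' @param proc_iterations,proc_fraction Partial-ROC settings.
#' @param bg_max Background cap: all accessible cells if fewer, else a
#'   seeded uniform sample of this size.
#' @param knots Threshold/hinge knots per variable.
#' @param seed Integer seed.
#' @return data.frame of class `candidate_table`, one row per grid point.
#' @export
calibrate_candidates <- function(cal_stack, cal_occ, eval_occ,
                                 variable_sets, class_subsets, rms,
                                 E = 0.05, alpha = 0.05,
                                 proc_iterations = 500L,
                                 proc_fraction = 0.5,
                                 bg_max = 10000L, knots = 10,
                                 seed = 1L) {
  if (!length(variable_sets) || !length(class_subsets) || !length(rms))
    stop("empty candidate grid")
  cells <- which(cal_stack$mask)
  if (length(cells) > bg_max)
    cells <- sort(with_seed(derive_seed(seed, "background"),
                            sample(cells, bg_max)))
  bg_all <- stack_values(cal_stack, cells)
  cal_idx <- cell_index(cal_stack$grid, cal_occ$longitude, cal_occ$latitude)
  ok <- !is.na(cal_idx)
  ok[ok] <- cal_stack$mask[cal_idx[ok]]
  if (!any(ok)) stop("no calibration occurrences on valid cells")
  pres_all <- stack_values(cal_stack, cal_idx[ok])

  grid <- expand.grid(set = seq_along(variable_sets),
                      cls = seq_along(class_subsets),
                      rm = rms, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    vs <- variable_sets[[grid$set[g]]]
    cls <- class_subsets[[grid$cls[g]]]
    rm_g <- grid$rm[g]
    id <- sprintf("set%03d_%s_rm%g", grid$set[g],
                  paste(cls, collapse = ""), rm_g)
    rec <- data.frame(id = id,
                      variables = paste(vs, collapse = "+"),
                      classes = paste(cls, collapse = ""),
                      rm = rm_g, auc_ratio = NA_real_, p = NA_real_,
                      omission = NA_real_, aicc = NA_real_,
                      k = NA_integer_, failed = FALSE,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      model <- fit_maxent(pres_all[, vs, drop = FALSE],
                          bg_all[, vs, drop = FALSE],
                          classes = cls, rm = rm_g, knots = knots)
      cl_pred <- predict(model, cal_stack, scale = "cloglog")
      raw_pred <- predict(model, cal_stack, scale = "raw")
      cal_suit <- prediction_at(cl_pred, cal_occ)
      thr <- omission_threshold(cal_suit, E)
      om <- omission_rate(cl_pred, eval_occ, thr)
      pr <- partial_roc(cl_pred, eval_occ, E = E,
                        iterations = proc_iterations,
                        resample_fraction = proc_fraction,
                        seed = derive_seed(seed, paste0("proc", g)))
      rec$auc_ratio <- pr$auc_ratio; rec$p <- pr$p
      rec$omission <- as.numeric(om)
      rec$aicc <- as.numeric(aicc_maxent(model, raw_pred, cal_occ))
      rec$k <- count_parameters(model)
      rec
    }, error = function(e) {
      warning("candidate ", id, " failed: ", conditionMessage(e))
      rec$failed <- TRUE
      rec
    })
    rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  if (all(out$failed)) stop("all candidate models failed")
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Select the best candidate model
#'
#' Three-stage rule: keep statistically significant candidates
#' (partial-ROC `p < alpha`), then well-performing ones (omission
#' `<= E`), then choose minimum AICc. Ties on AICc break by smaller k,
#' then fewer variables, then lexicographic id. If no candidate passes
#' the omission filter, the report falls back to minimum omission then
#' AICc and is marked `relaxed`.
#'
#' @param candidates A `candidate_table` from [calibrate_candidates()].
#' @param alpha Significance level (default 0.05).
#' @param E Acceptable omission error (default 0.05).
#' @return List of class `selection_report`: `counts` (total,
#'   significant, performant, selected), `best` (the winning row),
#'   `delta_aicc` to the runner-up, `relaxed` flag.
#' @export
select_best <- function(candidates, alpha = 0.05, E = 0.05) {
  stopifnot(nrow(candidates) >= 1)
  cand <- candidates[!candidates$failed & !is.na(candidates$p), ,
                     drop = FALSE]
  sig <- cand[cand$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0)
    stop("no candidate is statistically significant; expand the grid")
  perf <- sig[!is.na(sig$omission) & sig$omission <= E, , drop = FALSE]
  relaxed <- FALSE
  if (nrow(perf) == 0) {
    relaxed <- TRUE
    min_om <- min(sig$omission, na.rm = TRUE)
    perf <- sig[!is.na(sig$omission) & sig$omission == min_om, ,
                drop = FALSE]
  }
  n_vars <- lengths(strsplit(perf$variables, "+", fixed = TRUE))
  ord <- order(perf$aicc, perf$k, n_vars, perf$id)
  perf <- perf[ord, , drop = FALSE]
  best <- perf[1, , drop = FALSE]
  delta <- if (nrow(perf) >= 2) perf$aicc[2] - perf$aicc[1] else NA_real_
  structure(list(
    counts = c(total = nrow(candidates), significant = nrow(sig),
               performant = if (relaxed) 0L else nrow(perf),
               selected = 1L),
    best = best, delta_aicc = delta, relaxed = relaxed),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(paste0("<selection_report> %d candidates, %d significant, ",
                     "%d performant%s\n  best: %s (AICc %.4f, dAICc %.4f)\n"),
              x$counts["total"], x$counts["significant"],
              x$counts["performant"],
              if (x$relaxed) " [relaxed omission filter]" else "",
              x$best$id, x$best$aicc,
              if (is.na(x$delta_aicc)) NA else x$delta_aicc))
  invisible(x)
}
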