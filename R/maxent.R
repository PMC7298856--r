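#' Fit a Maxent-class presence-background model
#'
#' Maximum-entropy estimation of a Gibbs distribution over background
#' cells: the model's raw output is `P(x) = exp(lambda . f(x)) / Z`, with
#' `Z` summed over the training background, and the feature weights
#' `lambda` maximize the L1-penalized log-likelihood of the presence
#' records,
#' `sum_i log P(x_i) - sum_j beta_j |lambda_j|`.
#' Per-feature penalties follow the Maxent convention: a class-specific,
#' presence-sample-size-dependent base penalty times the feature's
#' presence-sample spread over `sqrt(m)`, all multiplied by the
#' regularization multiplier `rm`. The optimizer is proximal gradient
#' (gradient step on the smooth negative log-likelihood followed by
#' soft-thresholding) with backtracking line search, so the penalized
#' objective is monotone across iterations.
#'
#' @param pres Numeric matrix of presence-cell variable values (rows =
#'   presences, named columns = variables).
#' @param bg Numeric matrix of background-cell values (same columns).
#' @param classes Feature classes, subset of `c("l","q","p","t","h")`.
#' @param rm Regularization multiplier (> 0); study grid
#'   {0.1, 0.3, 0.5, 0.7, 1, 2, 3, 5, 7, 10}.
#' @param knots Threshold/hinge knots per variable.
#' @param max_iter,tol Optimizer budget and convergence tolerance on the
#'   change in the penalized objective.
#' @return Object of class `maxent_model`: feature expansion, `lambda`,
#'   `log_z` (log partition over training background), `entropy` of the
#'   fitted background distribution, objective trace and metadata.
#' @export
fit_maxent <- function(pres, bg, classes = c("l", "q"), rm = 1,
                       knots = 10, max_iter = 1000L, tol = 1e-7) {
  stopifnot(rm > 0)
  if (nrow(pres) < 2) stop("need at least 2 presence records")
  if (any(!is.finite(pres)) || any(!is.finite(bg)))
    stop("non-finite values in presence or background data")
  fe <- build_features(bg, classes, knots)
  Fb <- eval_features(fe, bg)
  Fp <- eval_features(fe, pres, clamp = FALSE)
  m <- nrow(Fp)
  beta <- rm * feature_penalties(fe, Fp)

  pres_mean <- colMeans(Fp)
  lambda <- numeric(n_features(fe))
  obj <- function(lam, logZsum) {
    # negative penalized log-likelihood (to minimize)
    -(sum(Fp %*% lam) - m * logZsum) + sum(beta * abs(lam))
  }
  gibbs <- function(lam) {
    eta <- as.numeric(Fb %*% lam)
    mx <- max(eta)
    w <- exp(eta - mx)
    list(logZsum = mx + log(sum(w)), p = w / sum(w))
  }
  # monotone FISTA: accelerated proximal gradient whose accepted iterates
  # never increase the penalized objective
  smooth <- function(lam, logZsum) -(sum(Fp %*% lam) - m * logZsum)
  st <- gibbs(lambda)
  f_cur <- obj(lambda, st$logZsum)
  trace <- f_cur
  y <- lambda
  st_y <- st
  t_acc <- 1
  step <- 1 / m
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- m * (as.numeric(crossprod(Fb, st_y$p)) - pres_mean)
    f_y <- smooth(y, st_y$logZsum)
    repeat {
      z <- soft_threshold(y - step * grad, step * beta)
      st_z <- gibbs(z)
      dz <- z - y
      # backtracking: quadratic majorization of the smooth part at y
      if (smooth(z, st_z$logZsum) <=
          f_y + sum(grad * dz) + sum(dz^2) / (2 * step) + 1e-12 ||
          step < 1e-12) break
      step <- step / 2
    }
    f_z <- obj(z, st_z$logZsum)
    t_next <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    if (f_z <= f_cur) {
      lambda_new <- z; st_new <- st_z; f_new <- f_z
    } else {
      lambda_new <- lambda; st_new <- st; f_new <- f_cur
    }
    y <- lambda_new + (t_acc / t_next) * (z - lambda_new) +
      ((t_acc - 1) / t_next) * (lambda_new - lambda)
    st_y <- gibbs(y)
    delta <- f_cur - f_new
    lambda <- lambda_new; st <- st_new; f_cur <- f_new
    trace <- c(trace, f_cur)
    t_acc <- t_next
    step <- step * 1.1
    if (it > 1 && delta < tol * (abs(f_cur) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("maxent fit did not converge in ", max_iter, " iterations")
  p_bg <- st$p
  entropy <- -sum(ifelse(p_bg > 0, p_bg * log(p_bg), 0))
  lambda <- stats::setNames(as.numeric(lambda), fe$names)
  structure(list(
    features = fe, lambda = lambda, rm = rm,
    log_zsum = st$logZsum, entropy = entropy,
    n_pres = m, n_bg = nrow(Fb), classes = classes,
    vars = fe$vars, penalties = beta,
    objective_trace = trace, converged = converged),
    class = "maxent_model")
}

# Maxent-style per-feature L1 penalties on the summed-log-likelihood
# scale: the Maxent convention penalizes the *average* log-likelihood by
# base_class(m) * sd_j / sqrt(m), which on the total scale is
# base_class(m) * sd_j * sqrt(m). The presence-sample sd is floored so
# zero-variance features are still penalized.
feature_penalties <- function(fe, Fp) {
  m <- nrow(Fp)
  interp <- function(xs, ys) stats::approx(xs, ys, xout = m, rule = 2)$y
  base_lqp <- interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05))
  base_t <- interp(c(0, 100), c(2, 1))
  base_h <- 0.5
  type <- vapply(fe$defs, function(d) d$type, "")
  base <- ifelse(type %in% c("l", "q", "p"), base_lqp,
                 ifelse(type == "t", base_t, base_h))
  sds <- pmax(apply(Fp, 2, stats::sd), 0.05)
  base * sds * sqrt(m)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d var(s) [%s], classes {%s}, RM %g\n",
                     "  %d/%d nonzero features, entropy %.3f, %s\n"),
              length(x$vars), paste(x$vars, collapse = ", "),
              paste(x$classes, collapse = ""), x$rm,
              count_parameters(x), n_features(x$features), x$entropy,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Number of model parameters (nonzero feature weights)
#'
#' Used as `k` in AICc.
#'
#' @param model A fitted `maxent_model`.
#' @param eps Weights with `|lambda| <= eps` count as zero.
#' @return Integer count of nonzero weights.
#' @export
count_parameters <- function(model, eps = 1e-8) {
  sum(abs(model$lambda) > eps)
}

# raw-scale prediction on a value matrix; normalized by the training
# background partition sum, so raw sums to 1 over the training background
predict_values <- function(model, X, scale = c("cloglog", "raw"),
                           clamp = TRUE) {
  scale <- match.arg(scale)
  missing <- setdiff(model$vars, colnames(X))
  if (length(missing))
    stop("prediction input is missing variable(s): ",
         paste(missing, collapse = ", "))
  Fx <- eval_features(model$features, X, clamp = clamp)
  raw <- exp(as.numeric(Fx %*% model$lambda) - model$log_zsum)
  if (scale == "raw") raw
  else 1 - exp(-exp(model$entropy) * raw)
}

#' Predict suitability over a layer stack
#'
#' @param object A fitted `maxent_model`.
#' @param stack An `enm_stack` containing all model variables.
#' @param scale `"cloglog"` (default; suitability in [0, 1]) or `"raw"`
#'   (Gibbs probability normalized over the training background, used for
#'   AICc).
#' @param clamp Clamp variables to the training range before prediction
#'   (default `TRUE`, the transfer convention; extrapolation risk is
#'   reported separately by [mop()]).
#' @param ... Unused.
#' @return An `enm_raster` of predictions (`NA` outside the stack mask).
#' @export
predict.maxent_model <- function(object, stack, scale = c("cloglog", "raw"),
                                 clamp = TRUE, ...) {
  scale <- match.arg(scale)
  cells <- which(stack$mask)
  X <- stack_values(stack, cells, layers = object$vars)
  pred <- predict_values(object, X, scale, clamp)
  m <- matrix(NA_real_, stack$grid$nrow, stack$grid$ncol)
  m[cells] <- pred
  enm_raster(m, stack$grid)
}

#' Serialize a fitted model to JSON
#'
#' Writes a plain-text lambdas file: feature names, weights, scaling
#' bounds, the log partition value and the background entropy — enough to
#' reconstruct predictions exactly.
#'
#' @param model A `maxent_model`.
#' @param path Output path (`.json`).
#' @export
write_maxent <- function(model, path) {
  fe <- model$features
  jsonlite::write_json(list(
    vars = fe$vars, classes = model$classes, rm = model$rm,
    var_range = as.data.frame(fe$var_range),
    features = data.frame(name = fe$names,
                          lambda = model$lambda,
                          fmin = fe$fmin, fmax = fe$fmax),
    log_zsum = model$log_zsum, entropy = model$entropy,
    n_pres = model$n_pres, n_bg = model$n_bg),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
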