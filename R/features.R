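#' Build a feature expansion from training background values
#'
#' Expands raw environmental variables into the Maxent basis: linear (l),
#' quadratic (q), product (p), threshold (t) and hinge (h) features. Each
#' derived feature is min-max scaled to [0, 1] using the training
#' background, and threshold/hinge knots are placed at evenly spaced
#' quantiles of each variable's background distribution, so every knot
#' lies inside the training range. Feature counts for v variables and K
#' knots: l = v, q = v, p = v(v-1)/2, t = vK, h = 2vK.
#'
#' @param bg Numeric matrix of background cell values (rows = cells,
#'   named columns = variables).
#' @param classes Character vector, subset of `c("l","q","p","t","h")`.
#' @param knots Knots per variable for threshold/hinge features
#'   (default 10).
#' @return An object of class `feature_expansion`.
#' @export
build_features <- function(bg, classes = c("l", "q"), knots = 10) {
  if (!length(classes)) stop("at least one feature class must be enabled")
  classes <- match.arg(classes, c("l", "q", "p", "t", "h"),
                       several.ok = TRUE)
  v <- ncol(bg)
  vars <- colnames(bg)
  if (is.null(vars)) stop("background matrix must have named columns")
  if ("p" %in% classes && v < 2 && identical(classes, "p"))
    stop("product features need at least 2 variables")
  if (any(!is.finite(bg))) stop("non-finite background values")
  rng <- apply(bg, 2, range)
  defs <- list()
  add <- function(type, v1, v2 = NA, knot = NA)
    defs[[length(defs) + 1L]] <<- list(type = type, v1 = v1, v2 = v2,
                                       knot = knot)
  if ("l" %in% classes) for (a in vars) add("l", a)
  if ("q" %in% classes) for (a in vars) add("q", a)
  if ("p" %in% classes && v >= 2)
    for (i in seq_len(v - 1)) for (j in (i + 1):v)
      add("p", vars[i], vars[j])
  qs <- seq_len(knots) / (knots + 1)
  knot_tab <- lapply(vars, function(a)
    unname(stats::quantile(bg[, a], qs, names = FALSE)))
  names(knot_tab) <- vars
  if ("t" %in% classes)
    for (a in vars) for (k in knot_tab[[a]]) add("t", a, knot = k)
  if ("h" %in% classes)
    for (a in vars) for (k in knot_tab[[a]]) {
      add("hf", a, knot = k)   # forward hinge
      add("hr", a, knot = k)   # reverse hinge
    }
  fe <- structure(list(classes = classes, vars = vars, defs = defs,
                       var_range = rng, fmin = NULL, fmax = NULL),
                  class = "feature_expansion")
  raw <- eval_features_raw(fe, bg)
  fe$fmin <- apply(raw, 2, min)
  fe$fmax <- apply(raw, 2, max)
  fe$names <- vapply(defs, function(d) {
    parts <- c(d$type, d$v1,
               if (!is.na(d$v2)) d$v2,
               if (!is.na(d$knot)) sprintf("%.6g", d$knot))
    paste(parts, collapse = ":")
  }, "")
  fe
}

# unscaled derived values, one column per feature definition
eval_features_raw <- function(fe, X) {
  n <- nrow(X)
  out <- matrix(0, n, length(fe$defs))
  for (j in seq_along(fe$defs)) {
    d <- fe$defs[[j]]
    x <- X[, d$v1]
    out[, j] <- switch(d$type,
      l  = x,
      q  = x^2,
      p  = x * X[, d$v2],
      t  = as.numeric(x > d$knot),
      hf = pmax(0, x - d$knot),
      hr = pmax(0, d$knot - x))
  }
  out
}

#' Evaluate a feature expansion on raw variable values
#'
#' @param fe A [build_features()] expansion.
#' @param X Numeric matrix (rows = cells, columns include all expansion
#'   variables).
#' @param clamp Clamp each variable to its training-background range
#'   before expansion (the Maxent transfer convention).
#' @return Numeric matrix, one scaled column per feature.
#' @export
eval_features <- function(fe, X, clamp = FALSE) {
  X <- X[, fe$vars, drop = FALSE]
  if (clamp)
    for (a in fe$vars)
      X[, a] <- pmin(pmax(X[, a], fe$var_range[1, a]), fe$var_range[2, a])
  raw <- eval_features_raw(fe, X)
  span <- fe$fmax - fe$fmin
  span[span == 0] <- 1
  out <- sweep(sweep(raw, 2, fe$fmin), 2, span, "/")
  colnames(out) <- fe$names
  out
}

#' Number of features in an expansion
#' @param fe A `feature_expansion`.
#' @return Integer feature count.
#' @export
n_features <- function(fe) length(fe$defs)
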