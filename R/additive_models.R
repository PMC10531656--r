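#' Fit a smooth additive model of a diversity metric
#'
#' Penalized additive regression (Gaussian family) of a per-site metric
#' on environmental predictors, each entering as a thin-plate regression
#' spline with basis size `k = 3`, optionally with a bivariate
#' thin-plate smooth of the site coordinates to absorb spatial
#' autocorrelation. Smoothing parameters are chosen by GCV by default.
#' Rows with missing response or predictors are dropped (count
#' reported in the fit).
#'
#' @param metrics data.frame with the response, predictors and (if
#'   `spatial`) coordinate columns.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns (may be
#'   empty when `spatial = TRUE`).
#' @param spatial include a bivariate smooth of the coordinates.
#' @param k basis size per univariate smooth (default 3, a deliberately
#'   small basis: effects are forced to be simple smooth shapes).
#' @param spatial_k basis size of the bivariate spatial smooth.
#' @param coord_cols coordinate column names.
#' @param method smoothing-parameter criterion (`"GCV.Cp"` default,
#'   `"REML"` available).
#' @return Object of class `eco_gam`: the mgcv fit plus
#'   `deviance_explained` (percent), `n_used`, `n_dropped`.
#' @export
fit_smooth_model <- function(metrics, response, predictors,
                             spatial = TRUE, k = 3, spatial_k = 30,
                             coord_cols = c("x", "y"),
                             method = "GCV.Cp") {
  if (!response %in% names(metrics)) {
    stop("response '", response, "' not in metrics table")
  }
  need <- c(response, predictors, if (spatial) coord_cols)
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("columns missing: ", paste(miss, collapse = ", "))
  dat <- metrics[need]
  ok <- complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]
  terms <- c(
    sprintf("s(%s, k = %d)", predictors, k),
    if (spatial) sprintf("s(%s, %s, k = %d)", coord_cols[1], coord_cols[2],
                         min(spatial_k, max(10, nrow(dat) - 5)))
  )
  if (!length(terms)) stop("no model terms: give predictors or spatial = TRUE")
  basis_dim <- length(predictors) * (k - 1) +
    (if (spatial) min(spatial_k, max(10, nrow(dat) - 5)) - 1 else 0) + 1
  if (nrow(dat) <= basis_dim) {
    stop("fewer complete rows (", nrow(dat), ") than basis dimension (",
         basis_dim, ")")
  }
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, data = dat, family = stats::gaussian(),
                   method = method)
  de <- 100 * summary(fit)$dev.expl
  if (!is.finite(de)) de <- 0  # constant response: nothing to explain
  structure(list(
    gam = fit,
    response = response,
    predictors = predictors,
    spatial = spatial,
    coord_cols = coord_cols,
    k = k,
    data = dat,
    deviance_explained = de,
    n_used = nrow(dat),
    n_dropped = sum(!ok)
  ), class = "eco_gam")
}

#' @export
print.eco_gam <- function(x, ...) {
  cat("Additive model:", x$response, "~",
      paste(c(x$predictors, if (x$spatial) "s(x,y)"), collapse = " + "), "\n")
  cat(sprintf("  n = %d (%d dropped), deviance explained = %.2f%%\n",
              x$n_used, x$n_dropped, x$deviance_explained))
  invisible(x)
}

#' Spatial-only smooth model
#'
#' Fits the metric against the bivariate coordinate smooth alone, to
#' quantify how much of a pattern is reproducible from location only.
#'
#' @inheritParams fit_smooth_model
#' @return An `eco_gam` object.
#' @export
spatial_only_model <- function(metrics, response, spatial_k = 30,
                               coord_cols = c("x", "y"),
                               method = "GCV.Cp") {
  fit_smooth_model(metrics, response, character(0), spatial = TRUE,
                   spatial_k = spatial_k, coord_cols = coord_cols,
                   method = method)
}

#' Smooth relationship between two diversity metrics
#'
#' Univariate penalized smooth (k = 3) of one metric on another,
#' optionally with the spatial term, e.g. the functional-richness
#' versus species-richness saturation check.
#'
#' @inheritParams fit_smooth_model
#' @param x,y column names of the predictor and response metrics.
#' @return An `eco_gam` object.
#' @export
relate_metrics <- function(metrics, x, y, spatial = FALSE, k = 3,
                           coord_cols = c("x", "y"), method = "GCV.Cp") {
  fit_smooth_model(metrics, response = y, predictors = x,
                   spatial = spatial, k = k, coord_cols = coord_cols,
                   method = method)
}

#' Partial effect of one predictor from an additive-model fit
#'
#' Evaluates the centred smooth term of `predictor` over a grid of its
#' observed range, holding everything else fixed (term-wise prediction).
#'
#' @param fit an `eco_gam` object.
#' @param predictor predictor name.
#' @param n grid size.
#' @return data.frame with `x` (grid) and `effect`.
#' @export
partial_effect <- function(fit, predictor, n = 100) {
  stopifnot(inherits(fit, "eco_gam"))
  if (!predictor %in% fit$predictors) {
    stop("'", predictor, "' is not a smooth term of this model")
  }
  rng <- range(fit$data[[predictor]])
  grid <- fit$data[rep(1, n), , drop = FALSE]
  for (p in setdiff(names(grid), fit$response)) {
    if (is.numeric(grid[[p]])) grid[[p]] <- median(fit$data[[p]])
  }
  grid[[predictor]] <- seq(rng[1], rng[2], length.out = n)
  tm <- predict(fit$gam, newdata = grid, type = "terms")
  col <- grep(paste0("^s\\(", predictor, "\\)$"), colnames(tm))
  if (!length(col)) col <- grep(predictor, colnames(tm), fixed = TRUE)[1]
  data.frame(x = grid[[predictor]], effect = tm[, col])
}
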