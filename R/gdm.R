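#' Monotone I-spline basis
#'
#' Order-2 I-splines (integrals of order-2 M-splines, i.e. piecewise
#' quadratic, once continuously differentiable) with knots at the
#' minimum, median and maximum of `x`. Each of the three basis functions
#' is monotone non-decreasing, 0 at `min(x)` and 1 at `max(x)`; with
#' non-negative coefficients any fitted transform is monotone. Built as
#' reversed cumulative sums of an order-3 B-spline basis.
#'
#' @param x numeric predictor values (at least 2 distinct).
#' @param n_splines number of basis functions (fixed at 3).
#' @param knots optional numeric length-3 vector `(min, interior, max)`;
#'   defaults to the min/median/max of `x`. Values outside the knot span
#'   are clamped.
#' @return Matrix `length(x)` x 3 with attribute `knots`.
#' @export
ispline_basis <- function(x, n_splines = 3, knots = NULL) {
  if (n_splines != 3) stop("the I-spline basis is fixed at 3 functions")
  x <- as.numeric(x)
  if (is.null(knots)) {
    knots <- unname(quantile(x, c(0, 0.5, 1), na.rm = TRUE))
  }
  if (anyNA(x)) stop("predictor contains missing values")
  if (knots[1] >= knots[3]) stop("constant predictor: spline basis undefined")
  if (knots[2] <= knots[1] || knots[2] >= knots[3]) {
    # degenerate median (heavily tied data): fall back to midpoint
    knots[2] <- (knots[1] + knots[3]) / 2
  }
  xc <- pmin(pmax(x, knots[1]), knots[3])
  aug <- c(rep(knots[1], 3), knots[2], rep(knots[3], 3))
  b <- splines::splineDesign(aug, xc, ord = 3)
  # I_i(x) = sum_{j > i} B_j(x) for the order-3 B-splines
  m <- ncol(b)                     # 4 B-splines -> 3 I-splines
  out <- sapply(seq_len(m - 1), function(i) rowSums(b[, (i + 1):m, drop = FALSE]))
  out <- matrix(out, nrow = length(x), ncol = m - 1)
  colnames(out) <- paste0("I", seq_len(m - 1))
  attr(out, "knots") <- knots
  out
}

#' Build the site-pair table for dissimilarity modelling
#'
#' One row per unordered pair of sites present in the dissimilarity
#' matrix: observed dissimilarity, each predictor's value at both sites
#' and the Euclidean geographic distance between site coordinates.
#'
#' @param dissim symmetric dissimilarity matrix with site dimnames.
#' @param env environment table with a `site` column, predictor columns
#'   and planar coordinate columns.
#' @param predictors character vector of predictor column names.
#' @param coord_cols names of the coordinate columns (default
#'   `c("x", "y")`).
#' @return data.frame with columns `site_i`, `site_j`, `d`, `distance`
#'   and `<predictor>_i` / `<predictor>_j` for each predictor.
#' @export
build_site_pairs <- function(dissim, env, predictors,
                             coord_cols = c("x", "y")) {
  dissim <- as.matrix(dissim)
  sites <- rownames(dissim)
  if (is.null(sites)) stop("dissimilarity matrix lacks site names")
  if (!"site" %in% names(env)) stop("environment table lacks a 'site' column")
  missing_sites <- setdiff(sites, env$site)
  if (length(missing_sites)) {
    stop("sites missing from environment table: ",
         paste(head(missing_sites, 5), collapse = ", "))
  }
  miss <- setdiff(c(predictors, coord_cols), names(env))
  if (length(miss)) stop("columns missing from environment table: ",
                         paste(miss, collapse = ", "))
  rownames(env) <- env$site
  env <- env[sites, , drop = FALSE]
  idx <- which(upper.tri(dissim), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  xy <- as.matrix(env[coord_cols])
  out <- data.frame(
    site_i = sites[i], site_j = sites[j],
    d = dissim[idx],
    distance = sqrt(rowSums((xy[i, , drop = FALSE] - xy[j, , drop = FALSE])^2)),
    stringsAsFactors = FALSE
  )
  for (p in predictors) {
    out[[paste0(p, "_i")]] <- env[[p]][i]
    out[[paste0(p, "_j")]] <- env[[p]][j]
  }
  out[!is.na(out$d), , drop = FALSE]
}

# binomial-type deviance of observed d against fitted mu, 0*log(0) = 0
gdm_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# Lawson-Hanson style non-negative least squares on normal equations
nnls_fit <- function(xtx, xty, max_pass = 30 * length(xty)) {
  p <- length(xty)
  x <- numeric(p)
  passive <- logical(p)
  ridge <- 1e-12 * mean(diag(xtx))
  solve_p <- function(set) {
    a <- xtx[set, set, drop = FALSE]
    diag(a) <- diag(a) + ridge
    drop(solve(a, xty[set]))
  }
  tol <- 1e-10 * max(abs(xty), 1)
  for (pass in seq_len(max_pass)) {
    w <- xty - drop(xtx %*% x)
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(p)
      s[passive] <- solve_p(passive)
      if (all(s[passive] > 0)) { x <- s; break }
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      x[x < 1e-14] <- 0
      passive <- passive & x > 0
      if (!any(passive)) { x[] <- 0; break }
    }
  }
  pmax(x, 0)
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise dissimilarity d in `[0, 1]` as
#' `d = 1 - exp(-eta)` with
#' `eta = alpha + sum_k sum_b beta_kb |I_kb(x_ki) - I_kb(x_kj)|`,
#' where `I_kb` are the three monotone I-spline basis functions of
#' predictor k (for geographic distance, the spline is applied to the
#' distance value itself). All coefficients, including the intercept,
#' are constrained non-negative, so fitted transforms are monotone and
#' predicted dissimilarity never decreases when sites grow further
#' apart. Estimation is iteratively reweighted non-negative least
#' squares on the working response, minimising the binomial-type
#' deviance.
#'
#' @param pairs site-pair table from [build_site_pairs()].
#' @param predictors character vector of environmental predictor names
#'   (matching the `_i`/`_j` column pairs).
#' @param geo include the geographic-distance spline (default TRUE).
#' @param max_iter,tol IRLS iteration cap and relative deviance-change
#'   convergence tolerance.
#' @return Object of class `gdm_fit`: intercept, per-predictor
#'   coefficients and knots, deviances, percent deviance explained and
#'   convergence diagnostics.
#' @export
fit_gdm <- function(pairs, predictors, geo = TRUE, max_iter = 100,
                    tol = 1e-8) {
  if (nrow(pairs) < 10) stop("need at least 10 site pairs")
  if (!geo && !length(predictors)) stop("need at least one predictor")
  y <- pairs$d
  if (anyNA(y) || any(y < 0 | y > 1)) {
    stop("observed dissimilarities must lie in [0, 1]")
  }
  terms <- gdm_design(pairs, predictors, geo, knots = NULL)
  X <- cbind(intercept = 1, terms$design)

  if (all(y < 1e-12)) {
    # degenerate: nothing to explain
    coefs <- setNames(numeric(ncol(X)), colnames(X))
    return(structure(list(
      intercept = 0, coefficients = coefs[-1], knots = terms$knots,
      predictors = predictors, geo = geo,
      deviance = 0, null_deviance = 0, deviance_explained = 0,
      converged = TRUE, iterations = 0, n_pairs = nrow(pairs)
    ), class = "gdm_fit"))
  }

  fit_irls <- function(X) {
    p <- ncol(X)
    beta <- numeric(p)
    mu0 <- min(max(mean(y), 1e-4), 1 - 1e-4)
    beta[1] <- if (colnames(X)[1] == "intercept") -log(1 - mu0) else 0
    dev <- gdm_deviance(y, 1 - exp(-drop(X %*% beta)))
    trace <- numeric(0)
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      eta <- drop(X %*% beta)
      mu <- 1 - exp(-eta)
      muc <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
      dmu <- pmax(exp(-eta), 1e-8)
      z <- eta + (y - mu) / dmu
      w <- dmu^2 / (muc * (1 - muc))
      beta_new <- nnls_fit(crossprod(X, X * w), drop(crossprod(X, w * z)))
      dev_new <- gdm_deviance(y, 1 - exp(-drop(X %*% beta_new)))
      trace <- c(trace, dev_new)
      rel <- abs(dev - dev_new) / max(dev, 1e-12)
      beta <- beta_new
      # absolute floor: a (near-)perfect fit has nothing left to improve
      if (rel < tol || dev_new < 1e-9 * length(y)) {
        converged <- TRUE
        dev <- dev_new
        break
      }
      dev <- dev_new
    }
    list(beta = setNames(beta, colnames(X)), deviance = dev,
         converged = converged, iterations = it, trace = trace)
  }

  full <- fit_irls(X)
  if (!full$converged) {
    warning("GDM did not converge within ", max_iter,
            " IRLS iterations; last deviances: ",
            paste(signif(utils::tail(full$trace, 5), 8), collapse = ", "))
  }
  null <- fit_irls(matrix(1, nrow(pairs), 1,
                          dimnames = list(NULL, "intercept")))
  dev_expl <- if (null$deviance <= 1e-12) 0 else {
    100 * (1 - full$deviance / null$deviance)
  }
  structure(list(
    intercept = unname(full$beta[1]),
    coefficients = full$beta[-1],
    knots = terms$knots,
    predictors = predictors,
    geo = geo,
    deviance = full$deviance,
    null_deviance = null$deviance,
    deviance_explained = dev_expl,
    converged = full$converged,
    iterations = full$iterations,
    deviance_trace = full$trace,
    n_pairs = nrow(pairs)
  ), class = "gdm_fit")
}

# shared design construction for fitting and prediction; knots = NULL
# derives knots from the data, otherwise reuses stored knots (values
# clamped to the training range)
gdm_design <- function(pairs, predictors, geo, knots = NULL,
                       warn_extrapolation = FALSE) {
  cols <- list()
  kn <- list()
  clamped <- character(0)
  if (geo) {
    k <- if (is.null(knots)) unname(quantile(pairs$distance, c(0, 0.5, 1))) else knots[["distance"]]
    if (!is.null(knots) && (min(pairs$distance) < k[1] - 1e-12 ||
                            max(pairs$distance) > k[3] + 1e-12)) {
      clamped <- c(clamped, "distance")
    }
    if (k[1] >= k[3]) stop("constant predictor 'distance'")
    b <- ispline_basis(pairs$distance, knots = k)
    colnames(b) <- paste0("distance_", 1:3)
    cols[["distance"]] <- b
    kn[["distance"]] <- k
  }
  for (p in predictors) {
    vi <- pairs[[paste0(p, "_i")]]
    vj <- pairs[[paste0(p, "_j")]]
    if (is.null(vi) || is.null(vj)) {
      stop("pair table lacks columns for predictor '", p, "'")
    }
    k <- if (is.null(knots)) unname(quantile(c(vi, vj), c(0, 0.5, 1))) else knots[[p]]
    if (is.null(k)) stop("unknown predictor '", p, "' (no stored knots)")
    if (k[1] >= k[3]) stop("constant predictor '", p, "'")
    if (!is.null(knots) && (min(c(vi, vj)) < k[1] - 1e-12 ||
                            max(c(vi, vj)) > k[3] + 1e-12)) {
      clamped <- c(clamped, p)
    }
    bi <- ispline_basis(vi, knots = k)
    bj <- ispline_basis(vj, knots = k)
    term <- abs(bi - bj)
    colnames(term) <- paste0(p, "_", 1:3)
    cols[[p]] <- term
    kn[[p]] <- k
  }
  if (warn_extrapolation && length(clamped)) {
    warning("predictor values outside the training range clamped for: ",
            paste(unique(clamped), collapse = ", "))
  }
  list(design = do.call(cbind, cols), knots = kn)
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat("Generalized dissimilarity model on", x$n_pairs, "site pairs\n")
  cat(sprintf("  deviance explained: %.2f%% (%sconverged in %d iterations)\n",
              x$deviance_explained, if (x$converged) "" else "NOT ",
              x$iterations))
  imp <- predictor_importance(x)
  print(imp, row.names = FALSE)
  invisible(x)
}

#' Predictor importance from a fitted GDM
#'
#' The sum of a predictor's three I-spline coefficients measures its
#' contribution to fitted turnover (the height of its transform);
#' shares are normalised sums.
#'
#' @param fit a [fit_gdm()] object.
#' @return data.frame with `predictor`, `importance`, `share`.
#' @export
predictor_importance <- function(fit) {
  stopifnot(inherits(fit, "gdm_fit"))
  terms <- names(fit$knots)
  imp <- vapply(terms, function(p) {
    sum(fit$coefficients[paste0(p, "_", 1:3)])
  }, 0)
  total <- sum(imp)
  data.frame(predictor = terms, importance = unname(imp),
             share = if (total > 0) unname(imp) / total else NA_real_,
             stringsAsFactors = FALSE)
}

#' Predict pairwise dissimilarity from a fitted GDM
#'
#' @param fit a [fit_gdm()] object.
#' @param pairs site-pair table with the predictor `_i`/`_j` columns
#'   (and `distance` when the model includes geography). Values outside
#'   the training range are clamped with a warning.
#' @return Numeric vector of predicted dissimilarities in `[0, 1)`.
#' @export
predict_dissimilarity <- function(fit, pairs) {
  stopifnot(inherits(fit, "gdm_fit"))
  terms <- gdm_design(pairs, fit$predictors, fit$geo, knots = fit$knots,
                      warn_extrapolation = TRUE)
  X <- terms$design
  beta <- fit$coefficients[colnames(X)]
  beta[is.na(beta)] <- 0
  eta <- fit$intercept + drop(X %*% beta)
  1 - exp(-eta)
}

#' Evaluate fitted I-spline transforms on a grid
#'
#' @param fit a [fit_gdm()] object.
#' @param n grid points per predictor.
#' @return data.frame with `predictor`, `x`, `f` (partial transform
#'   height), suitable for plotting the fitted splines.
#' @export
gdm_transforms <- function(fit, n = 200) {
  stopifnot(inherits(fit, "gdm_fit"))
  out <- lapply(names(fit$knots), function(p) {
    k <- fit$knots[[p]]
    x <- seq(k[1], k[3], length.out = n)
    b <- ispline_basis(x, knots = k)
    f <- drop(b %*% fit$coefficients[paste0(p, "_", 1:3)])
    data.frame(predictor = p, x = x, f = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Partition GDM deviance into environment, geography and shared
#'
#' Fits the full model (environment + geography), an environment-only
#' model and a geography-only model on the same pairs, then splits the
#' full model's percent deviance explained into
#' `unique_env = full - geo_only`, `unique_geo = full - env_only` and
#' `shared = env_only + geo_only - full`.
#'
#' @param pairs site-pair table from [build_site_pairs()].
#' @param env_predictors character vector of environmental predictors.
#' @param ... passed to [fit_gdm()].
#' @return List with the three fits and a `partition` data.frame
#'   (percent deviance: full, env_only, geo_only, unique_env,
#'   unique_geo, shared).
#' @export
partition_deviance <- function(pairs, env_predictors, ...) {
  full <- fit_gdm(pairs, env_predictors, geo = TRUE, ...)
  env_only <- fit_gdm(pairs, env_predictors, geo = FALSE, ...)
  geo_only <- fit_gdm(pairs, character(0), geo = TRUE, ...)
  if (!full$converged || !env_only$converged || !geo_only$converged) {
    stop("a GDM sub-model failed to converge; cannot partition deviance")
  }
  f <- full$deviance_explained
  e <- env_only$deviance_explained
  g <- geo_only$deviance_explained
  partition <- data.frame(
    component = c("full", "env_only", "geo_only",
                  "unique_env", "unique_geo", "shared"),
    deviance_explained = c(f, e, g, f - g, f - e, e + g - f)
  )
  list(full = full, env_only = env_only, geo_only = geo_only,
       partition = partition)
}

#' RGB ordination of a predicted dissimilarity matrix
#'
#' Principal coordinates of the predicted site-by-site dissimilarities;
#' the first three axes are min-max scaled to `[0, 1]` and read as red,
#' green and blue channels, so sites with similar predicted composition
#' receive similar colours. Constant axes (or missing positive axes)
#' map to 0.5.
#'
#' @param pred_matrix symmetric predicted dissimilarity matrix with
#'   site dimnames.
#' @return data.frame with `site`, ordination scores `axis1..axis3` and
#'   channels `R`, `G`, `B`.
#' @export
rgb_ordination <- function(pred_matrix) {
  d <- as.matrix(pred_matrix)
  if (max(abs(d - t(d))) > 1e-8) stop("predicted matrix must be symmetric")
  sites <- rownames(d)
  if (is.null(sites)) sites <- paste0("site", seq_len(nrow(d)))
  n <- nrow(d)
  scores <- matrix(0, n, 3)
  off <- d[upper.tri(d)]
  informative <- length(off) > 0 && diff(range(off)) > 1e-12
  if (!informative) {
    # all pairs equally dissimilar (a regular simplex): the ordination
    # carries no gradient, so every site gets the neutral colour
    return(data.frame(site = sites, axis1 = 0, axis2 = 0, axis3 = 0,
                      R = 0.5, G = 0.5, B = 0.5, stringsAsFactors = FALSE))
  }
  if (max(d) > 0) {
    g <- dc_center(-0.5 * ((d + t(d)) / 2)^2)
    e <- eigen((g + t(g)) / 2, symmetric = TRUE)
    pos <- which(e$values > 1e-10 * max(abs(e$values)))
    navail <- min(3, length(pos))
    if (navail < 3) {
      warning("only ", navail, " positive ordination axes; remaining ",
              "channels set to 0.5")
    }
    for (a in seq_len(navail)) {
      scores[, a] <- e$vectors[, pos[a]] * sqrt(e$values[pos[a]])
    }
  }
  ch <- apply(scores, 2, function(v) {
    r <- range(v)
    if (diff(r) < 1e-12) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  })
  data.frame(site = sites,
             axis1 = scores[, 1], axis2 = scores[, 2], axis3 = scores[, 3],
             R = ch[, 1], G = ch[, 2], B = ch[, 3],
             stringsAsFactors = FALSE)
}

#' Square matrix from predicted pair dissimilarities
#'
#' @param pairs pair table with `site_i`, `site_j`.
#' @param values per-pair values (e.g. predictions), defaults to
#'   `pairs$d`.
#' @return Symmetric matrix over the union of sites, zero diagonal.
#' @export
pairs_to_matrix <- function(pairs, values = pairs$d) {
  sites <- sort(unique(c(pairs$site_i, pairs$site_j)))
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  i <- match(pairs$site_i, sites)
  j <- match(pairs$site_j, sites)
  m[cbind(i, j)] <- values
  m[cbind(j, i)] <- values
  m
}
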