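#' Species richness per site
#'
#' @param community binary site-by-species matrix.
#' @return Named integer vector of row sums.
#' @export
species_richness <- function(community) {
  community <- validate_community(community)
  rowSums(community)
}

#' Convex-hull functional richness (FRic) per site
#'
#' For each site, the volume of the convex hull spanned by the unique
#' trait-space coordinates of the species present (first `m_axes` PCoA
#' axes), standardised by the hull volume of the entire species pool so
#' that values lie in `[0, 1]`. Sites whose unique points are fewer than
#' `m_axes + 1` or affinely degenerate yield `NA`.
#'
#' @param community binary site-by-species matrix; columns must match
#'   the trait-space species.
#' @param space a [trait_space()] object (or any list with `coordinates`).
#' @param m_axes number of trait-space axes used for the hulls.
#' @return Named numeric vector of FRic values in `[0, 1]` (`NA` where
#'   degenerate).
#' @export
functional_richness <- function(community, space, m_axes = 3) {
  community <- validate_community(community)
  coords <- space_coordinates(space, m_axes)
  coords <- coords[colnames(community), , drop = FALSE]
  pool <- cpp_hull_volume(coords)
  if (is.na(pool) || pool <= 0) {
    stop("species-pool hull volume is zero or degenerate in ", m_axes,
         " axes; trait space cannot support FRic")
  }
  v <- cpp_site_hull_volumes(coords, community)
  setNames(v / pool, rownames(community))
}

space_coordinates <- function(space, m_axes) {
  coords <- if (is.list(space)) {
    if (!is.null(space$all_coordinates) &&
        ncol(space$all_coordinates) >= m_axes) {
      space$all_coordinates
    } else {
      space$coordinates
    }
  } else {
    as.matrix(space)
  }
  if (m_axes > ncol(coords)) {
    stop("m_axes (", m_axes, ") exceeds available trait-space axes (",
         ncol(coords), ")")
  }
  if (is.null(rownames(coords))) stop("trait-space coordinates lack species ids")
  coords[, seq_len(m_axes), drop = FALSE]
}

#' Fixed-margin randomization of a binary community matrix
#'
#' Shuffles presences with 2x2 checkerboard swaps, preserving every row
#' (site richness) and column (species prevalence) sum exactly. The
#' chain starts from the observed matrix and performs
#' `burn_in_factor * fill` accepted swaps (fill = number of presences),
#' with a trial cap for matrices that admit few or no swaps.
#'
#' @param community binary site-by-species matrix.
#' @param burn_in_factor accepted swaps per presence (default 10).
#' @param seed optional integer seed for reproducibility.
#' @return Randomized binary matrix with identical margins.
#' @export
swap_randomize <- function(community, burn_in_factor = 10, seed = NULL) {
  community <- validate_community(community)
  run <- function() {
    fill <- sum(community)
    target <- max(1L, as.integer(burn_in_factor * fill))
    cpp_checkerboard_swap(community, target, max_trials = 1000 * fill + 1e4)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Standardized effect size of a per-site metric under the swap null
#'
#' SES_i = (obs_i - mean(null_i)) / sd(null_i) over `n_randomizations`
#' fixed-margin randomizations. Each randomization is an independent
#' chain restarted from the observed matrix with a fresh seed derived
#' from `seed`. Sites with zero null standard deviation give `NA` with
#' a warning.
#'
#' @param community binary site-by-species matrix.
#' @param metric function mapping a binary matrix to a per-site numeric
#'   vector.
#' @param n_randomizations number of null draws (>= 2; the atlas-scale
#'   default is 1000).
#' @param seed master integer seed.
#' @param burn_in_factor accepted swaps per presence for each chain.
#' @return List with `ses`, `observed`, `null_mean`, `null_sd`.
#' @export
ses_metric <- function(community, metric, n_randomizations = 1000,
                       seed = 1, burn_in_factor = 10) {
  community <- validate_community(community)
  if (n_randomizations < 2) stop("n_randomizations must be at least 2")
  obs <- metric(community)
  seeds <- derive_seeds(seed, n_randomizations)
  nulls <- matrix(NA_real_, n_randomizations, length(obs))
  for (r in seq_len(n_randomizations)) {
    rnd <- swap_randomize(community, burn_in_factor = burn_in_factor,
                          seed = seeds[r])
    nulls[r, ] <- metric(rnd)
  }
  mu <- colMeans(nulls, na.rm = TRUE)
  sdv <- apply(nulls, 2, sd, na.rm = TRUE)
  ses <- (obs - mu) / sdv
  degenerate <- !is.na(sdv) & sdv == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " site(s) with zero null standard deviation; ",
            "SES set to NA there")
    ses[degenerate] <- NA_real_
  }
  list(ses = setNames(ses, names(obs)), observed = obs,
       null_mean = mu, null_sd = sdv)
}

#' SES of convex-hull functional richness
#'
#' @inheritParams ses_metric
#' @inheritParams functional_richness
#' @return List as from [ses_metric()].
#' @export
ses_functional_richness <- function(community, space, m_axes = 3,
                                    n_randomizations = 1000, seed = 1,
                                    burn_in_factor = 10) {
  ses_metric(
    community,
    function(m) functional_richness(m, space, m_axes = m_axes),
    n_randomizations = n_randomizations, seed = seed,
    burn_in_factor = burn_in_factor
  )
}

# expand one master seed into per-stage seeds, kept within 32-bit range
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}

#' Shannon diversity of land-cover shares
#'
#' H = -sum(p log p) over the cover classes with positive share, after
#' renormalising the shares to sum to one. Zero shares contribute 0.
#'
#' @param cover numeric vector of shares, or a matrix/data.frame with
#'   one row per site.
#' @return Shannon index (scalar or per-row vector), in nats.
#' @export
shannon_heterogeneity <- function(cover) {
  h1 <- function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || any(p < 0)) stop("cover shares must be non-negative")
    s <- sum(p)
    if (s <= 0) stop("at least one cover share must be positive")
    p <- p[p > 0] / s
    -sum(p * log(p))
  }
  if (is.matrix(cover) || is.data.frame(cover)) {
    apply(as.matrix(cover), 1, h1)
  } else {
    h1(cover)
  }
}

#' Iterative VIF screening of predictors
#'
#' Computes the variance inflation factor VIF_k = 1 / (1 - R^2_k) of
#' each predictor regressed on all the others and repeatedly drops the
#' predictor with the largest VIF while any VIF is at or above the
#' threshold (the vifstep procedure). Perfectly collinear predictors
#' have infinite VIF and are dropped first.
#'
#' @param env data.frame holding the predictors.
#' @param predictors character vector of column names to screen.
#' @param threshold drop while max VIF >= threshold (default 10).
#' @return List with `retained`, `dropped` (in drop order) and `trace`
#'   (data.frame of step, predictor, VIF at drop time).
#' @export
vif_screen <- function(env, predictors, threshold = 10) {
  if (length(predictors) < 2) stop("need at least two predictors")
  miss <- setdiff(predictors, names(env))
  if (length(miss)) stop("predictors not in table: ", paste(miss, collapse = ", "))
  x <- as.matrix(env[predictors])
  if (nrow(x) < length(predictors) + 1) {
    stop("need more sites than predictors")
  }
  const <- predictors[apply(x, 2, function(v) sd(v) == 0)]
  if (length(const)) {
    stop("constant predictor(s): ", paste(const, collapse = ", "))
  }
  keep <- predictors
  dropped <- character(0)
  trace <- data.frame(step = integer(0), predictor = character(0),
                      vif = numeric(0))
  step <- 0L
  repeat {
    vifs <- vapply(keep, function(p) {
      fit <- lm(x[, p] ~ x[, setdiff(keep, p), drop = FALSE])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
    if (max(vifs) < threshold || length(keep) == 1) break
    worst <- names(which.max(vifs))
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, predictor = worst,
                                     vif = unname(vifs[worst])))
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  list(retained = keep, dropped = dropped, trace = trace,
       final_vif = if (length(keep) > 1) vapply(keep, function(p) {
         fit <- lm(x[, p] ~ x[, setdiff(keep, p), drop = FALSE])
         r2 <- suppressWarnings(summary(fit)$r.squared)
         if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
       }, 0) else setNames(1, keep))
}
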