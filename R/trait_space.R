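#' @name trait-levels
#' @title Categorical trait levels
#' @description Level sets for the four categorical butterfly traits used
#'   throughout the package: wing-span class (mm), voltinism class
#'   (generations per year), overwintering stage and diet breadth.
#' @keywords internal
NULL

trait_levels <- list(
  wing_span     = c("20-30", "31-40", "41-50", "51-60", ">60"),
  voltinism     = c("1", "2", "3", "4", "5"),
  overwintering = c("egg", "larvae", "pupae", "adult"),
  diet          = c("monophagous", "broad oligophagous", "polyphagous")
)

trait_names <- names(trait_levels)

# round half away from zero; base round() uses banker's rounding, which
# would send 30.5 down to 30 instead of up into the next class
round_half_up <- function(x) floor(x + 0.5)

#' Bin continuous traits into categorical classes
#'
#' Wing span (mm) is rounded to the nearest integer (halves round up) and
#' mapped to the classes 20-30, 31-40, 41-50, 51-60 and >60; rounding
#' first closes the unit gaps between the integer-edged classes.
#' Voltinism is rounded the same way and clamped to 1..5. Overwintering
#' stage and diet must already be categorical and are validated against
#' their level sets.
#'
#' @param raw data.frame with columns `species`, `wing_span` (mm,
#'   continuous), `voltinism` (generations/yr, continuous),
#'   `overwintering` and `diet`.
#' @return data.frame with column `species` and the four traits as
#'   factors with the package-wide level sets.
#' @export
bin_continuous_traits <- function(raw) {
  req <- c("species", "wing_span", "voltinism", "overwintering", "diet")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("raw trait table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(raw$species)) stop("duplicate species identifiers")
  ws <- round_half_up(as.numeric(raw$wing_span))
  bad <- which(is.na(ws) | ws < 20)
  if (length(bad)) {
    stop("wing span below 20 mm (or missing) for species: ",
         paste(raw$species[bad], collapse = ", "))
  }
  ws_class <- cut(ws, breaks = c(19.5, 30.5, 40.5, 50.5, 60.5, Inf),
                  labels = trait_levels$wing_span, right = TRUE)
  volt <- round_half_up(as.numeric(raw$voltinism))
  if (anyNA(volt)) {
    stop("missing voltinism for species: ",
         paste(raw$species[is.na(volt)], collapse = ", "))
  }
  volt <- pmin(pmax(volt, 1L), 5L)
  ow <- as.character(raw$overwintering)
  if (!all(ow %in% trait_levels$overwintering)) {
    bad <- raw$species[!ow %in% trait_levels$overwintering]
    stop("invalid overwintering stage for species: ",
         paste(bad, collapse = ", "))
  }
  diet <- as.character(raw$diet)
  if (!all(diet %in% trait_levels$diet)) {
    bad <- raw$species[!diet %in% trait_levels$diet]
    stop("invalid diet category for species: ", paste(bad, collapse = ", "))
  }
  data.frame(
    species = as.character(raw$species),
    wing_span = factor(ws_class, levels = trait_levels$wing_span),
    voltinism = factor(as.character(volt), levels = trait_levels$voltinism),
    overwintering = factor(ow, levels = trait_levels$overwintering),
    diet = factor(diet, levels = trait_levels$diet),
    stringsAsFactors = FALSE
  )
}

validate_trait_table <- function(traits) {
  req <- c("species", trait_names)
  miss <- setdiff(req, names(traits))
  if (length(miss)) stop("trait table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (tr in trait_names) {
    vals <- as.character(traits[[tr]])
    if (anyNA(vals)) {
      stop("missing value for trait '", tr, "' in species: ",
           paste(traits$species[is.na(vals)], collapse = ", "))
    }
    bad <- !vals %in% trait_levels[[tr]]
    if (any(bad)) {
      stop("invalid level for trait '", tr, "' in species: ",
           paste(traits$species[bad], collapse = ", "))
    }
  }
  invisible(traits)
}

#' Gower distance between species with categorical traits
#'
#' With all four traits categorical the Gower distance reduces to the
#' proportion of mismatching traits, so values lie on the grid
#' \{0, 0.25, 0.5, 0.75, 1\}.
#'
#' @param traits categorical trait table as from [bin_continuous_traits()].
#' @return Symmetric species-by-species distance matrix with zero
#'   diagonal.
#' @export
gower_distance <- function(traits) {
  validate_trait_table(traits)
  sp <- as.character(traits$species)
  n <- length(sp)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (tr in trait_names) {
    v <- as.character(traits[[tr]])
    d <- d + outer(v, v, "!=")
  }
  d / length(trait_names)
}

#' Principal coordinates embedding of a distance matrix
#'
#' Classical PCoA: eigendecomposition of the double-centred Gram matrix.
#' When negative eigenvalues occur (non-Euclidean distances) a Cailliez
#' or Lingoes correction can be applied; `"auto"` applies Cailliez
#' whenever a negative eigenvalue exceeds 1e-8 in magnitude.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal.
#' @param m_axes number of coordinate axes to return.
#' @param correction one of `"auto"`, `"none"`, `"lingoes"`, `"cailliez"`.
#' @return List with `coordinates` (n x `m_axes`), `eigenvalues`
#'   (all axes, non-increasing), `correction_applied` and, for checking,
#'   `all_coordinates` over every positive-eigenvalue axis.
#' @export
pcoa_embed <- function(d, m_axes = 3,
                       correction = c("auto", "none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-10) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("obj", seq_len(n))

  if (max(d) == 0) {
    coords <- matrix(0, n, m_axes, dimnames = list(ids, paste0("A", seq_len(m_axes))))
    return(list(coordinates = coords, eigenvalues = rep(0, n),
                correction_applied = "none", all_coordinates = coords))
  }

  decomp <- function(dd) {
    g <- dc_center(-0.5 * dd^2)
    eigen((g + t(g)) / 2, symmetric = TRUE)
  }

  e <- decomp(d)
  tolneg <- 1e-8
  applied <- "none"
  if (correction %in% c("auto", "cailliez", "lingoes") &&
      min(e$values) < -tolneg) {
    applied <- if (correction == "lingoes") "lingoes" else "cailliez"
    dcor <- if (applied == "cailliez") {
      correct_distance_cailliez(d)
    } else {
      correct_distance_lingoes(d)
    }
    e <- decomp(dcor)
    attr(applied, "constant") <- attr(dcor, "constant")
    d <- dcor
  }
  pos <- which(e$values > 1e-8 * max(abs(e$values)))
  if (m_axes > length(pos)) {
    stop("m_axes exceeds the number of positive eigenvalues (maximum ",
         length(pos), ")")
  }
  all_coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(all_coords) <- list(ids, paste0("A", seq_along(pos)))
  coords <- all_coords[, seq_len(m_axes), drop = FALSE]
  list(coordinates = coords, eigenvalues = e$values,
       correction_applied = applied, all_coordinates = all_coords,
       corrected_distance = d)
}

# Cailliez: smallest constant c so that d_ij + c (i != j) is Euclidean;
# largest real eigenvalue of the 2n x 2n companion problem
correct_distance_cailliez <- function(d) {
  n <- nrow(d)
  del1 <- dc_center(-0.5 * d^2)
  del2 <- dc_center(-0.5 * d)
  z <- rbind(cbind(matrix(0, n, n), 2 * del1),
             cbind(-diag(n), -4 * del2))
  ev <- eigen(z, only.values = TRUE)$values
  cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
  out <- d + cc
  diag(out) <- 0
  attr(out, "constant") <- cc
  out
}

# Lingoes: subtract twice the smallest (most negative) eigenvalue from
# squared distances
correct_distance_lingoes <- function(d) {
  e <- eigen(dc_center(-0.5 * d^2), symmetric = TRUE, only.values = TRUE)
  cc <- -min(e$values)
  out <- sqrt(d^2 + 2 * cc)
  diag(out) <- 0
  attr(out, "constant") <- cc
  out
}

dc_center <- function(m) {
  m <- sweep(m, 1, rowMeans(m))
  mm <- sweep(m, 2, colMeans(m))
  mm
}

#' Build the trait space used by functional richness and beta-diversity
#'
#' Computes the Gower distance among species and embeds it by PCoA.
#'
#' @inheritParams gower_distance
#' @inheritParams pcoa_embed
#' @return Object of class `trait_space`: list with `species`, `gower`,
#'   `coordinates`, `eigenvalues`, `correction_applied`.
#' @export
trait_space <- function(traits, m_axes = 3, correction = "auto") {
  g <- gower_distance(traits)
  emb <- pcoa_embed(g, m_axes = m_axes, correction = correction)
  structure(
    list(species = rownames(g), gower = g,
         coordinates = emb$coordinates,
         all_coordinates = emb$all_coordinates,
         eigenvalues = emb$eigenvalues,
         correction_applied = emb$correction_applied),
    class = "trait_space"
  )
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Trait space:", length(x$species), "species,",
      ncol(x$coordinates), "retained axes (of",
      ncol(x$all_coordinates), "positive);",
      "correction:", as.character(x$correction_applied), "\n")
  invisible(x)
}
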