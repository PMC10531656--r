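#' Pairwise taxonomic Jaccard dissimilarity
#'
#' d_ij = (b + c) / (a + b + c) where a is the number of shared species
#' and b, c the numbers unique to each site. Pairs of two empty sites
#' are undefined (`NA`).
#'
#' @param community binary site-by-species matrix.
#' @return Symmetric site-by-site matrix in `[0, 1]` with zero diagonal
#'   and attribute `facet = "taxonomic"`.
#' @export
taxonomic_jaccard <- function(community) {
  community <- validate_community(community)
  m <- community
  a <- m %*% t(m)                       # shared
  s <- rowSums(m)
  uni <- outer(s, s, "+") - a           # a + b + c
  d <- (uni - a) / uni
  d[uni == 0] <- NA_real_               # both sites empty
  diag(d) <- ifelse(s == 0, NA_real_, 0)
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "facet") <- "taxonomic"
  d
}

#' Pairwise functional Jaccard dissimilarity from hull overlap
#'
#' Each site is represented by the convex hull of its species' unique
#' trait-space coordinates (first `m_axes` axes). With hull volumes
#' V_a, V_b and intersection volume V_s, the dissimilarity is
#' d = (V_a + V_b - 2 V_s) / (V_a + V_b - V_s), the Jaccard index on
#' volumes. Sites with fewer than `min_species` species, fewer than
#' `m_axes + 1` unique points, or a degenerate hull are excluded and
#' reported.
#'
#' @inheritParams functional_richness
#' @param m_axes trait-space dimensionality (default 2: intersection
#'   volumes are exact and fast in the plane; 3--4 are supported).
#' @param min_species minimum species per site (default 5).
#' @return Symmetric matrix over the retained sites, attribute
#'   `facet = "functional"`; excluded sites in attribute `excluded`
#'   (data.frame with a reason per site).
#' @export
functional_jaccard <- function(community, space, m_axes = 2,
                               min_species = 5) {
  community <- validate_community(community)
  if (m_axes >= min_species) {
    stop("m_axes must be below min_species: a ", m_axes,
         "-dimensional hull needs at least ", m_axes + 1, " points")
  }
  coords <- space_coordinates(space, m_axes)
  coords <- coords[colnames(community), , drop = FALSE]

  n <- nrow(community)
  pts <- vector("list", n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- coords[community[i, ] == 1, , drop = FALSE]
    if (nrow(p) > 0) p <- unique(round(p, 12))
    if (sum(community[i, ]) < min_species) {
      reason[i] <- sprintf("fewer than %d species", min_species)
    } else if (nrow(p) < m_axes + 1 || is.na(cpp_hull_volume(p))) {
      reason[i] <- "degenerate hull (too few unique points or flat set)"
    } else {
      pts[[i]] <- p
    }
  }
  keep <- which(is.na(reason))
  excluded <- data.frame(site = rownames(community)[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  vols <- vapply(keep, function(i) cpp_hull_volume(pts[[i]]), 0)

  k <- length(keep)
  d <- matrix(0, k, k, dimnames = list(rownames(community)[keep],
                                       rownames(community)[keep]))
  if (k > 1) {
    for (ii in seq_len(k - 1)) {
      for (jj in (ii + 1):k) {
        vs <- cpp_hull_intersection_volume(pts[[keep[ii]]], pts[[keep[jj]]])
        vs <- min(vs, vols[ii], vols[jj])
        dd <- (vols[ii] + vols[jj] - 2 * vs) / (vols[ii] + vols[jj] - vs)
        d[ii, jj] <- d[jj, ii] <- min(max(dd, 0), 1)
      }
    }
  }
  attr(d, "facet") <- "functional"
  attr(d, "excluded") <- excluded
  attr(d, "m_axes") <- m_axes
  d
}

#' Condensed pair table from a dissimilarity matrix
#'
#' @param d symmetric dissimilarity matrix with dimnames.
#' @return data.frame with columns `site_i`, `site_j`, `d`, one row per
#'   unordered pair.
#' @export
dissimilarity_pairs <- function(d) {
  d <- as.matrix(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(site_i = rownames(d)[idx[, 1]],
             site_j = colnames(d)[idx[, 2]],
             d = d[idx],
             stringsAsFactors = FALSE)
}
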