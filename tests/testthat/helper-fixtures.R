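# Fixtures are built in code; nothing is read from disk.

# trait table in which every species has a distinct 4-trait combination
distinct_trait_table <- function(n) {
  grid <- expand.grid(
    wing_span = ecoredundancy:::trait_levels$wing_span,
    voltinism = ecoredundancy:::trait_levels$voltinism,
    overwintering = ecoredundancy:::trait_levels$overwintering,
    diet = ecoredundancy:::trait_levels$diet,
    stringsAsFactors = FALSE
  )
  stopifnot(n <= nrow(grid))
  out <- grid[seq_len(n), ]
  out <- data.frame(species = sprintf("sp%02d", seq_len(n)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# trait table realising a given species -> entity assignment (entities
# get distinct combinations; species in an entity share one)
trait_table_for_assignment <- function(assignment) {
  combos <- distinct_trait_table(max(assignment))
  out <- combos[assignment, ]
  out$species <- sprintf("sp%02d", seq_along(assignment))
  rownames(out) <- NULL
  out
}

# one-site community over the given species
one_site_community <- function(species, present = species) {
  m <- matrix(0L, 1, length(species),
              dimnames = list("site1", species))
  m[1, present] <- 1L
  m
}

# Monte-Carlo rejection estimate of a hull volume (independent oracle:
# only hull membership is shared with the implementation under test)
mc_hull_volume <- function(pts, n = 2e5) {
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  q <- sapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]))
  mean(in_hull(pts, q)) * prod(hi - lo)
}

mc_intersection_volume <- function(a, b, n = 2e5) {
  lo <- pmin(apply(a, 2, min), apply(b, 2, min))
  hi <- pmax(apply(a, 2, max), apply(b, 2, max))
  q <- sapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]))
  mean(in_hull(a, q) & in_hull(b, q)) * prod(hi - lo)
}

# canonical set partitions of S items into at most max_blocks blocks,
# one row per partition (first-occurrence labelling)
enumerate_partitions <- function(S, max_blocks = 4) {
  if (S == 1) return(matrix(1L, 1, 1))
  canonical <- function(v) match(v, unique(v))
  g <- as.matrix(expand.grid(rep(list(seq_len(max_blocks)), S)))
  canon <- unique(t(apply(g, 1, canonical)))
  canon[apply(canon, 1, max) <= max_blocks, , drop = FALSE]
}

# environment table for hand-built communities
toy_environment <- function(sites, temperature = seq_along(sites)) {
  data.frame(site = sites, temperature = temperature,
             x = seq_along(sites), y = rev(seq_along(sites)),
             stringsAsFactors = FALSE)
}

# planar coordinate "trait space" for geometric beta-diversity tests
coord_space <- function(coords) {
  stopifnot(!is.null(rownames(coords)))
  coords
}
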