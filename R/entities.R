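#' Assign species to functional entities
#'
#' A functional entity is a unique combination of the four categorical
#' trait values; species sharing all four values belong to the same
#' entity. Entity identifiers are stable: entities are numbered in
#' lexicographic order of their trait combination.
#'
#' @param traits categorical trait table (columns `species`, `wing_span`,
#'   `voltinism`, `overwintering`, `diet`).
#' @return Object of class `fe_partition`: list with `entity` (named
#'   character vector, species -> entity id), `combinations` (data.frame,
#'   one row per entity with its trait values and size) and `n_entities`.
#' @export
assign_functional_entities <- function(traits) {
  validate_trait_table(traits)
  key <- apply(traits[trait_names], 1, paste, collapse = "|")
  combos <- sort(unique(key))
  ids <- setNames(sprintf("FE%03d", seq_along(combos)), combos)
  entity <- setNames(unname(ids[key]), as.character(traits$species))
  parts <- do.call(rbind, strsplit(combos, "|", fixed = TRUE))
  combinations <- data.frame(
    entity = unname(ids),
    setNames(as.data.frame(parts, stringsAsFactors = FALSE), trait_names),
    size = as.integer(table(entity)[ids]),
    stringsAsFactors = FALSE
  )
  structure(list(entity = entity, combinations = combinations,
                 n_entities = length(combos)),
            class = "fe_partition")
}

#' @export
print.fe_partition <- function(x, ...) {
  cat("Functional entities:", x$n_entities, "entities over",
      length(x$entity), "species\n")
  invisible(x)
}

#' Functional redundancy of a community
#'
#' Mean number of species per functional entity present in the
#' community: FR = S / FE, where S is species richness and FE the number
#' of entities present. FR is 1 when every entity is a singleton and
#' equals S when all species share one entity.
#'
#' @param entity_counts integer vector of species counts per entity
#'   present (all >= 1), e.g. `c(2, 1, 3)`.
#' @return FR in `[1, S]`; `NA` for an empty community.
#' @export
functional_redundancy <- function(entity_counts) {
  entity_counts <- check_entity_counts(entity_counts)
  if (!length(entity_counts)) return(NA_real_)
  sum(entity_counts) / length(entity_counts)
}

#' Functional vulnerability of a community
#'
#' Proportion of the functional entities present that contain exactly
#' one species: FV = (FE - sum(min(n_i - 1, 1))) / FE. FV is 0 when
#' every entity has at least two species and 1 when all are singletons.
#'
#' @inheritParams functional_redundancy
#' @return FV in `[0, 1]`; `NA` for an empty community.
#' @export
functional_vulnerability <- function(entity_counts) {
  entity_counts <- check_entity_counts(entity_counts)
  fe <- length(entity_counts)
  if (!fe) return(NA_real_)
  (fe - sum(pmin(entity_counts - 1, 1))) / fe
}

check_entity_counts <- function(entity_counts) {
  entity_counts <- as.integer(entity_counts)
  if (anyNA(entity_counts) || any(entity_counts < 1)) {
    stop("entity counts must be positive integers")
  }
  entity_counts
}

# per-site entity size profile: list of integer count vectors
site_entity_profiles <- function(community, partition) {
  community <- validate_community(community)
  sp <- colnames(community)
  missing_sp <- setdiff(sp, names(partition$entity))
  if (length(missing_sp)) {
    stop("species absent from the entity partition: ",
         paste(missing_sp, collapse = ", "))
  }
  ent <- partition$entity[sp]
  lapply(seq_len(nrow(community)), function(i) {
    present <- community[i, ] == 1
    if (!any(present)) return(integer(0))
    as.integer(table(ent[present]))
  })
}

#' Per-site redundancy metrics table
#'
#' Computes species richness S, number of functional entities present
#' FE, functional redundancy FR = S/FE and functional vulnerability FV
#' (singleton-entity fraction) for every site. Empty sites yield `NA`
#' metrics (occupied cells only enter the atlas-style analysis).
#'
#' @param community binary site-by-species matrix.
#' @param partition entity partition from [assign_functional_entities()].
#' @return data.frame with columns `site`, `S`, `FE`, `FR`, `FV`.
#' @export
redundancy_metrics <- function(community, partition) {
  community <- validate_community(community)
  profiles <- site_entity_profiles(community, partition)
  data.frame(
    site = rownames(community),
    S = vapply(profiles, sum, 0L),
    FE = vapply(profiles, length, 0L),
    FR = vapply(profiles, functional_redundancy, 0),
    FV = vapply(profiles, functional_vulnerability, 0),
    stringsAsFactors = FALSE
  )
}

validate_community <- function(community) {
  m <- as.matrix(community)
  if (is.null(rownames(m))) rownames(m) <- paste0("site", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate site identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate species identifiers")
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)[1, , drop = TRUE]
    stop("community matrix must be binary; offending entry at site '",
         rownames(m)[bad[1]], "', species '", colnames(m)[bad[2]], "'")
  }
  storage.mode(m) <- "integer"
  m
}
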