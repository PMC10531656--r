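#' Read a community matrix from CSV
#'
#' Expects a header row with the site-id column first and one column
#' per species; entries must be 0/1.
#'
#' @param path CSV file path.
#' @return Validated binary site-by-species integer matrix.
#' @export
read_community <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("community file needs a site column plus species")
  sites <- as.character(df[[1]])
  if (anyDuplicated(sites)) stop("duplicate site identifiers in ", path)
  m <- as.matrix(df[-1])
  if (anyDuplicated(colnames(m))) stop("duplicate species identifiers in ", path)
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-binary value in community file at site '", sites[bad[1, 1]],
         "', species '", colnames(m)[bad[1, 2]], "'")
  }
  rownames(m) <- sites
  storage.mode(m) <- "integer"
  m
}

#' Write a community matrix to CSV
#'
#' @param community binary site-by-species matrix.
#' @param path output CSV path.
#' @export
write_community <- function(community, path) {
  community <- validate_community(community)
  df <- data.frame(site = rownames(community), community,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' Read a raw trait table from CSV
#'
#' Columns: `species`, `wing_span`, `voltinism`, `overwintering`,
#' `diet`. Categorical traits already binned (factor levels matching
#' the package level sets) are also accepted.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read an environment table from CSV
#'
#' @param path CSV file path; must contain a `site` column.
#' @return data.frame.
#' @export
read_environment <- function(path) {
  env <- read.csv(path, stringsAsFactors = FALSE)
  if (!"site" %in% names(env)) stop("environment table lacks a 'site' column")
  env$site <- as.character(env$site)
  env
}

#' Write a synthetic dataset to a directory
#'
#' Writes `community.csv`, `traits.csv`, `environment.csv` and
#' `truth.txt` (key-value ground truth).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("community.csv", "traits.csv",
                            "environment.csv", "truth.txt"))
  write_community(dataset$community, paths[1])
  write.csv(dataset$traits, paths[2], row.names = FALSE)
  write.csv(dataset$environment, paths[3], row.names = FALSE)
  tr <- dataset$truth
  lines <- c(
    paste0("preset: ", tr$preset),
    paste0("driver: ", tr$driver),
    paste0("seed: ", tr$seed),
    paste0("optimum_", tr$niches$species, ": ", tr$niches$optimum),
    paste0("breadth_", tr$niches$species, ": ", tr$niches$breadth)
  )
  writeLines(lines, paths[4])
  invisible(paths)
}

default_gdm_predictors <- function(env) {
  cand <- c("temperature", cover_classes, "heterogeneity", "population",
            "elev_mean", "elev_sd")
  intersect(cand, names(env))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input validation, trait binning (when traits are
#' continuous), Gower/PCoA trait space, functional entities, per-site
#' alpha metrics with SES of FRic, VIF predictor screening, additive
#' models, taxonomic and functional beta-diversity (>= `min_species`
#' filter), GDM for both facets, deviance partitioning and RGB
#' ordination. All outputs are written as CSV under `out_dir` together
#' with a JSON manifest of stages, seeds and row counts.
#'
#' @param community binary site-by-species matrix.
#' @param traits raw or binned trait table.
#' @param env environment table (with `site`, predictors, `x`, `y`).
#' @param out_dir output directory.
#' @param m_axes_fric axes for FRic hulls (default 3).
#' @param m_axes_beta axes for functional beta-diversity hulls
#'   (default 2).
#' @param n_randomizations swap-null draws for SES.
#' @param min_species beta-diversity species filter (default 5).
#' @param vif_threshold VIF screening threshold (default 10).
#' @param max_pairs cap on site pairs entering each GDM (seeded
#'   subsample above it).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return Invisibly, a list with the main result objects and the
#'   manifest.
#' @export
run_pipeline <- function(community, traits, env, out_dir,
                         m_axes_fric = 3, m_axes_beta = 2,
                         n_randomizations = 199, min_species = 5,
                         vif_threshold = 10, max_pairs = 2e6,
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ecoredundancy",
                   version = as.character(utils::packageVersion("ecoredundancy")),
                   seed = seed, stages = list())
  t_all <- proc.time()[3]
  stage_notes <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    message(sprintf("[%s] running...", name))
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(
      list(status = "completed",
           seconds = round(proc.time()[3] - t0, 2)),
      stage_notes[[name]]
    )
    res
  }

  community <- stage("read_inputs", {
    m <- validate_community(community)
    if (!all(rownames(m) %in% env$site)) stop("sites missing from environment")
    m
  })

  traits_binned <- stage("bin_traits", {
    if (is.numeric(traits$wing_span)) bin_continuous_traits(traits) else {
      validate_trait_table(traits)
      traits
    }
  })

  space <- stage("trait_space", {
    trait_space(traits_binned, m_axes = max(m_axes_fric, m_axes_beta))
  })

  partition <- stage("functional_entities", {
    assign_functional_entities(traits_binned)
  })

  metrics <- stage("alpha_metrics", {
    red <- redundancy_metrics(community, partition)
    red$FRic <- unname(functional_richness(community, space, m_axes_fric))
    ses <- ses_functional_richness(community, space, m_axes = m_axes_fric,
                                   n_randomizations = n_randomizations,
                                   seed = derive_seeds(seed, 1))
    red$SES_FRic <- unname(ses$ses)
    out <- merge(red, env, by = "site", sort = FALSE)
    write.csv(out, file.path(out_dir, "alpha_metrics.csv"),
              row.names = FALSE)
    out
  })

  screened <- stage("vif_screen", {
    preds <- default_gdm_predictors(env)
    sc <- vif_screen(env, preds, threshold = vif_threshold)
    write.csv(data.frame(predictor = c(sc$retained, sc$dropped),
                         status = c(rep("retained", length(sc$retained)),
                                    rep("dropped", length(sc$dropped)))),
              file.path(out_dir, "vif_screen.csv"), row.names = FALSE)
    sc
  })

  gams <- stage("additive_models", {
    fits <- list()
    for (resp in c("S", "FRic", "FR", "FV")) {
      f <- tryCatch(
        fit_smooth_model(metrics, resp, screened$retained, spatial = TRUE,
                         spatial_k = max(10, min(30, nrow(metrics) %/% 4))),
        error = function(e) NULL)
      if (!is.null(f)) fits[[resp]] <- f
    }
    summ <- if (length(fits)) {
      do.call(rbind, lapply(names(fits), function(r) {
        data.frame(response = r,
                   deviance_explained = fits[[r]]$deviance_explained,
                   n = fits[[r]]$n_used)
      }))
    } else {
      data.frame(response = character(0), deviance_explained = numeric(0),
                 n = integer(0))
    }
    write.csv(summ, file.path(out_dir, "gam_summary.csv"), row.names = FALSE)
    fits
  })

  betas <- stage("beta_diversity", {
    occupied <- community[rowSums(community) > 0, , drop = FALSE]
    dt <- taxonomic_jaccard(occupied)
    df <- functional_jaccard(occupied, space, m_axes = m_axes_beta,
                             min_species = min_species)
    if (nrow(df) < 3) {
      stage_notes[["beta_diversity"]] <-
        list(note = "all sites below the species filter; beta stages skipped")
      list(taxonomic = dt, functional = NULL)
    } else {
      write.csv(dissimilarity_pairs(df),
                file.path(out_dir, "beta_functional_pairs.csv"),
                row.names = FALSE)
      write.csv(attr(df, "excluded"),
                file.path(out_dir, "beta_excluded_sites.csv"),
                row.names = FALSE)
      write.csv(dissimilarity_pairs(dt),
                file.path(out_dir, "beta_taxonomic_pairs.csv"),
                row.names = FALSE)
      list(taxonomic = dt, functional = df)
    }
  })

  gdms <- stage("gdm", {
    if (is.null(betas$functional)) {
      stage_notes[["gdm"]] <- list(note = "skipped: no functional beta matrix")
      NULL
    } else {
      preds <- screened$retained
      fits <- list()
      for (facet in c("taxonomic", "functional")) {
        dmat <- betas[[facet]]
        keep <- rownames(betas$functional)
        dmat <- dmat[keep, keep]
        pairs <- build_site_pairs(dmat, env, preds)
        if (nrow(pairs) > max_pairs) {
          warning("subsampling ", max_pairs, " of ", nrow(pairs), " pairs")
          pairs <- withr::with_seed(derive_seeds(seed, 2),
                                    pairs[sample(nrow(pairs), max_pairs), ])
        }
        part <- partition_deviance(pairs, preds)
        imp <- predictor_importance(part$full)
        write.csv(imp, file.path(out_dir, paste0("gdm_importance_",
                                                 facet, ".csv")),
                  row.names = FALSE)
        write.csv(part$partition,
                  file.path(out_dir, paste0("gdm_partition_", facet, ".csv")),
                  row.names = FALSE)
        write.csv(gdm_transforms(part$full),
                  file.path(out_dir, paste0("gdm_splines_", facet, ".csv")),
                  row.names = FALSE)
        pred <- predict_dissimilarity(part$full, pairs)
        rgb <- rgb_ordination(pairs_to_matrix(pairs, pred))
        write.csv(rgb, file.path(out_dir, paste0("gdm_rgb_", facet, ".csv")),
                  row.names = FALSE)
        fits[[facet]] <- list(partition = part, importance = imp, rgb = rgb)
      }
      fits
    }
  })

  manifest$elapsed_seconds <- round(proc.time()[3] - t_all, 2)
  write_manifest(manifest, out_dir)
  invisible(list(metrics = metrics, screened = screened, gams = gams,
                 betas = betas, gdms = gdms, manifest = manifest))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# minimal flat "key: value" config reader for the CLI (no YAML
# dependency); lists are comma-separated
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
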