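#' Landscape generator configuration
#'
#' Describes a rectangular grid of sites with a latitudinal temperature
#' gradient, compositional land cover whose class weights shift along
#' the gradient (so cover correlates with temperature, as cropland does
#' in the warm south-east of Britain), log-normal human population and
#' elevation increasing towards the cold end. Defaults emulate a
#' British-scale 10-km atlas window: mean annual temperature spanning
#' 5--11 degrees C with 0.5 degrees C of local noise.
#'
#' @param n_rows,n_cols grid shape; `n_sites = n_rows * n_cols`. Row 1
#'   is the warm (southern) edge.
#' @param temp_range `(min, max)` mean annual temperature, degrees C.
#' @param temp_noise_sd Gaussian noise around the gradient, degrees C.
#' @param cover_concentration positive Dirichlet weights for the six
#'   cover classes (forest, cropland, grassland, other, water,
#'   settlement).
#' @param cover_gradient_tilt per-class exponents applied as
#'   `weight * exp(tilt * warmness)`; the default makes cropland rise
#'   and forest/other fall towards the warm end.
#' @param pop_scale median human population per site.
#' @param elev_params `(mean, sd)` of site mean elevation, metres.
#' @param seed integer seed.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 20, n_cols = 10,
                             temp_range = c(5, 11),
                             temp_noise_sd = 0.5,
                             cover_concentration = c(
                               forest = 2, cropland = 2, grassland = 2,
                               other = 1, water = 0.5, settlement = 0.5),
                             cover_gradient_tilt = c(
                               forest = -0.8, cropland = 1.2, grassland = 0,
                               other = -0.8, water = 0, settlement = 0.4),
                             pop_scale = 1e4,
                             elev_params = c(150, 80),
                             seed = 1) {
  if (n_rows < 1 || n_cols < 1) stop("invalid config: grid must be positive")
  if (temp_range[1] >= temp_range[2]) {
    stop("invalid config: temp_range must be increasing")
  }
  if (any(cover_concentration <= 0)) {
    stop("invalid config: cover concentration weights must be positive")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 temp_range = temp_range, temp_noise_sd = temp_noise_sd,
                 cover_concentration = cover_concentration,
                 cover_gradient_tilt = cover_gradient_tilt,
                 pop_scale = pop_scale, elev_params = elev_params,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

cover_classes <- c("forest", "cropland", "grassland", "other", "water",
                   "settlement")

#' Generate a synthetic landscape (environment table)
#'
#' One row per grid cell: temperature decreasing with row index
#' (latitude proxy) plus noise, Dirichlet land-cover shares that sum to
#' one, Shannon land-use heterogeneity, log-normal population,
#' elevation mean/SD, and cell-centroid coordinates (in cell units).
#'
#' @param cfg a [landscape_config()].
#' @return data.frame (`environment table`) with columns `site`,
#'   `temperature`, the six cover fractions, `heterogeneity`,
#'   `population`, `elev_mean`, `elev_sd`, `x`, `y`.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  withr::with_seed(cfg$seed, {
    rows <- rep(seq_len(cfg$n_rows), each = cfg$n_cols)
    cols <- rep(seq_len(cfg$n_cols), times = cfg$n_rows)
    n <- length(rows)
    warm <- if (cfg$n_rows > 1) 1 - (rows - 1) / (cfg$n_rows - 1) else rep(1, n)
    temp <- cfg$temp_range[1] + warm * diff(cfg$temp_range) +
      rnorm(n, 0, cfg$temp_noise_sd)

    conc <- outer(warm, cfg$cover_gradient_tilt[cover_classes]) |> exp()
    conc <- sweep(conc, 2, cfg$cover_concentration[cover_classes], "*")
    g <- matrix(rgamma(n * length(cover_classes), shape = conc),
                n, length(cover_classes))
    cover <- g / rowSums(g)
    colnames(cover) <- cover_classes

    env <- data.frame(
      site = sprintf("s%04d", seq_len(n)),
      temperature = temp,
      cover,
      heterogeneity = shannon_heterogeneity(cover),
      population = rlnorm(n, log(cfg$pop_scale), 1),
      elev_mean = pmax(0, cfg$elev_params[1] * (0.4 + 1.2 * (1 - warm)) +
                         rnorm(n, 0, cfg$elev_params[2] / 2)),
      elev_sd = rlnorm(n, log(cfg$elev_params[2]), 0.5),
      x = cols - 0.5,
      y = rows - 0.5,
      stringsAsFactors = FALSE
    )
    env
  })
}

#' Default trait-category sampling probabilities
#'
#' Category probabilities per trait, loosely shaped like a north
#' temperate butterfly fauna: mid-sized wings dominate, most species
#' are univoltine, overwintering mostly as larva or pupa, diet mostly
#' oligophagous.
#'
#' @return Named list of probability vectors (each sums to 1).
#' @export
default_trait_probs <- function() {
  list(
    wing_span = c("20-30" = 0.20, "31-40" = 0.30, "41-50" = 0.25,
                  "51-60" = 0.15, ">60" = 0.10),
    voltinism = c("1" = 0.55, "2" = 0.30, "3" = 0.10, "4" = 0.04,
                  "5" = 0.01),
    overwintering = c(egg = 0.10, larvae = 0.45, pupae = 0.35,
                      adult = 0.10),
    diet = c(monophagous = 0.25, "broad oligophagous" = 0.50,
             polyphagous = 0.25)
  )
}

#' Species-pool generator configuration
#'
#' @param n_species pool size (default 57, the size of the British
#'   butterfly pool; must be >= 5).
#' @param trait_level_probs named list of per-trait category
#'   probabilities (names must match the trait level sets).
#' @param niche_breadth_range `(min, max)` Gaussian thermal niche SD,
#'   degrees C.
#' @param detection_baseline occupancy probability at the thermal
#'   optimum.
#' @param optimum_shape shape parameter of the Beta distribution that
#'   places thermal optima within the landscape temperature range;
#'   values > 1 skew optima towards the warm end (the pool is mildly
#'   warm-adapted, which produces the south-to-north richness decline).
#' @param seed integer seed.
#' @return A `species_pool_config` list.
#' @export
species_pool_config <- function(n_species = 57,
                                trait_level_probs = default_trait_probs(),
                                niche_breadth_range = c(1.5, 4),
                                detection_baseline = 0.8,
                                optimum_shape = 2,
                                seed = 1) {
  if (n_species < 5) stop("invalid config: n_species must be at least 5")
  for (tr in trait_names) {
    p <- trait_level_probs[[tr]]
    if (is.null(p) || !length(p)) {
      stop("invalid config: empty trait level set for '", tr, "'")
    }
    if (!all(names(p) %in% trait_levels[[tr]])) {
      stop("invalid config: unknown levels for trait '", tr, "'")
    }
    if (abs(sum(p) - 1) > 1e-8) {
      stop("invalid config: probabilities for '", tr, "' must sum to 1")
    }
  }
  if (detection_baseline <= 0 || detection_baseline > 1) {
    stop("invalid config: detection_baseline must be in (0, 1]")
  }
  structure(list(n_species = as.integer(n_species),
                 trait_level_probs = trait_level_probs,
                 niche_breadth_range = niche_breadth_range,
                 detection_baseline = detection_baseline,
                 optimum_shape = optimum_shape,
                 seed = as.integer(seed)),
            class = "species_pool_config")
}

#' Generate a trait-structured species pool with thermal niches
#'
#' Each species receives four categorical traits sampled independently
#' from the configured category probabilities, a Gaussian thermal niche
#' optimum inside the landscape's temperature range and a niche breadth
#' drawn uniformly from `niche_breadth_range`. Niche parameters are the
#' generator's ground truth.
#'
#' @param cfg a [species_pool_config()].
#' @param landscape environment table from [generate_landscape()].
#' @return List with `traits` (categorical trait table) and `niches`
#'   (data.frame: species, optimum, breadth, baseline).
#' @export
generate_species_pool <- function(cfg, landscape) {
  stopifnot(inherits(cfg, "species_pool_config"))
  trange <- range(landscape$temperature)
  withr::with_seed(cfg$seed, {
    n <- cfg$n_species
    sp <- sprintf("sp%03d", seq_len(n))
    traits <- data.frame(species = sp, stringsAsFactors = FALSE)
    for (tr in trait_names) {
      p <- cfg$trait_level_probs[[tr]]
      traits[[tr]] <- factor(
        sample(names(p), n, replace = TRUE, prob = p),
        levels = trait_levels[[tr]]
      )
    }
    u <- stats::rbeta(n, cfg$optimum_shape, 1)
    niches <- data.frame(
      species = sp,
      optimum = trange[1] + u * diff(trange),
      breadth = runif(n, cfg$niche_breadth_range[1],
                      cfg$niche_breadth_range[2]),
      baseline = cfg$detection_baseline,
      stringsAsFactors = FALSE
    )
    list(traits = traits, niches = niches)
  })
}

#' Generate niche-based communities
#'
#' Occurrence of species j at site i is Bernoulli with probability
#' `baseline * exp(-(T_i - opt_j)^2 / (2 * breadth_j^2))`.
#'
#' @param landscape environment table.
#' @param pool list from [generate_species_pool()].
#' @param seed integer seed.
#' @return Binary site-by-species matrix.
#' @export
generate_communities <- function(landscape, pool, seed = 1) {
  niches <- pool$niches
  if (!identical(as.character(pool$traits$species),
                 as.character(niches$species))) {
    stop("trait table and niche table disagree on species identifiers")
  }
  withr::with_seed(as.integer(seed), {
    pmat <- occupancy_probability(landscape$temperature, niches)
    m <- matrix(rbinom(length(pmat), 1, pmat), nrow(pmat), ncol(pmat))
    dimnames(m) <- list(landscape$site, niches$species)
    storage.mode(m) <- "integer"
    m
  })
}

#' Niche-model occupancy probabilities
#'
#' @param temperature per-site temperatures.
#' @param niches niche table (`optimum`, `breadth`, `baseline`).
#' @return Matrix of probabilities, sites x species.
#' @export
occupancy_probability <- function(temperature, niches) {
  outer(temperature, seq_len(nrow(niches)), function(t, j) {
    niches$baseline[j] * exp(-(t - niches$optimum[j])^2 /
                               (2 * niches$breadth[j]^2))
  })
}

#' Bundled benchmark datasets with known ground truth
#'
#' Presets:
#' * `"default"`: latitudinal temperature gradient, gradient-tilted
#'   land cover, warm-skewed thermal niches -- every downstream stage
#'   runs on it.
#' * `"single-driver-temperature"`: temperature is spatially shuffled
#'   (no latitudinal structure), cover is flat, and narrow thermal
#'   niches make temperature the only turnover driver; geographic
#'   distance carries no signal.
#' * `"no-structure"`: occupancy is iid Bernoulli(0.3) for every
#'   species at every site, independent of the environment.
#'
#' @param name preset id.
#' @param n_sites number of sites (grid of 10 columns).
#' @param seed integer seed.
#' @return List of class `synthetic_dataset`: `community`, `traits`,
#'   `environment`, `truth` (generating parameters incl. the turnover
#'   driver identity).
#' @export
make_benchmark_dataset <- function(name = c("default",
                                            "single-driver-temperature",
                                            "no-structure"),
                                   n_sites = 200, seed = 1) {
  presets <- c("default", "single-driver-temperature", "no-structure")
  if (!is.character(name) || !name[1] %in% presets) {
    stop("unknown preset '", name[1], "'; available presets: ",
         paste(presets, collapse = ", "))
  }
  name <- name[1]
  seed <- as.integer(seed)
  n_cols <- 10
  n_rows <- ceiling(n_sites / n_cols)
  if (n_rows * n_cols != n_sites) {
    stop("n_sites must be a multiple of ", n_cols)
  }
  lc <- landscape_config(n_rows = n_rows, n_cols = n_cols, seed = seed)
  if (name == "single-driver-temperature") {
    lc$cover_gradient_tilt[] <- 0
    lc$temp_noise_sd <- 0.2
  }
  env <- generate_landscape(lc)
  if (name == "single-driver-temperature") {
    # decouple temperature from geography: permute it across sites
    env$temperature <- withr::with_seed(seed + 101L,
                                        sample(env$temperature))
    env$heterogeneity <- shannon_heterogeneity(env[cover_classes])
  }
  pc <- species_pool_config(seed = seed + 1L)
  if (name == "single-driver-temperature") {
    pc$niche_breadth_range <- c(0.8, 1.6)
    pc$detection_baseline <- 0.9
  }
  pool <- generate_species_pool(pc, env)
  if (name == "no-structure") {
    comm <- withr::with_seed(seed + 2L, {
      m <- matrix(rbinom(nrow(env) * pc$n_species, 1, 0.3),
                  nrow(env), pc$n_species,
                  dimnames = list(env$site, pool$traits$species))
      storage.mode(m) <- "integer"
      m
    })
    driver <- "none"
  } else {
    comm <- generate_communities(env, pool, seed = seed + 2L)
    driver <- "temperature"
  }
  structure(list(
    community = comm,
    traits = pool$traits,
    environment = env,
    truth = list(preset = name, driver = driver, niches = pool$niches,
                 landscape_config = lc, pool_config = pc, seed = seed)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (preset '", x$truth$preset, "'): ",
      nrow(x$community), " sites x ", ncol(x$community), " species\n",
      sep = "")
  invisible(x)
}
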