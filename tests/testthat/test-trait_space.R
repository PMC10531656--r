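test_that("wing-span binning matches an exhaustive enumeration oracle", {
  # oracle: explicit if-else chain after round-half-up, independent of
  # the cut()-based implementation
  oracle_class <- function(v) {
    r <- floor(v + 0.5)
    if (r <= 30) "20-30"
    else if (r <= 40) "31-40"
    else if (r <= 50) "41-50"
    else if (r <= 60) "51-60"
    else ">60"
  }
  vals <- seq(20, 70, by = 0.1)
  raw <- data.frame(species = sprintf("s%04d", seq_along(vals)),
                    wing_span = vals, voltinism = 1,
                    overwintering = "egg", diet = "monophagous")
  got <- as.character(bin_continuous_traits(raw)$wing_span)
  expect_identical(got, vapply(vals, oracle_class, ""))
})

test_that("binning handles the documented category examples", {
  raw <- data.frame(species = c("a", "b", "c"),
                    wing_span = c(35, 65, 30.5),
                    voltinism = c(1.2, 4.7, 9),
                    overwintering = "larvae", diet = "polyphagous")
  b <- bin_continuous_traits(raw)
  expect_equal(as.character(b$wing_span), c("31-40", ">60", "31-40"))
  # voltinism rounded then clamped to 1..5
  expect_equal(as.character(b$voltinism), c("1", "5", "5"))
})

test_that("binning rejects out-of-range and invalid categorical values", {
  raw <- data.frame(species = c("tiny", "ok"), wing_span = c(15, 30),
                    voltinism = 1, overwintering = "egg",
                    diet = "monophagous")
  expect_error(bin_continuous_traits(raw), "tiny")
  raw2 <- data.frame(species = "x", wing_span = 30, voltinism = 1,
                     overwintering = "hibernation", diet = "monophagous")
  expect_error(bin_continuous_traits(raw2), "overwintering")
})

test_that("Gower distance equals mismatch proportion on all 300 combinations", {
  tab <- distinct_trait_table(300)
  d <- gower_distance(tab)
  expect_true(isSymmetric(d))
  expect_equal(max(abs(diag(d))), 0)
  # brute-force oracle on a random subset of pairs
  set.seed(42)
  ii <- sample(300, 60)
  for (a in ii[1:30]) {
    for (b in ii[31:60]) {
      mism <- sum(vapply(ecoredundancy:::trait_names, function(tr) {
        as.character(tab[[tr]][a]) != as.character(tab[[tr]][b])
      }, NA))
      expect_identical(d[a, b], mism / 4)
    }
  }
  expect_true(all(d %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("Gower distance agrees with cluster::daisy on random tables", {
  skip_if_not_installed("cluster")
  set.seed(7)
  tab <- distinct_trait_table(300)[sample(300, 40), ]
  tab$species <- sprintf("sp%02d", 1:40)
  d <- gower_distance(tab)
  ref <- as.matrix(cluster::daisy(
    data.frame(lapply(tab[ecoredundancy:::trait_names], factor)),
    metric = "gower"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12)
})

test_that("gower_distance reports missing values with species and trait", {
  tab <- distinct_trait_table(4)
  tab$diet[2] <- NA
  expect_error(gower_distance(tab), "diet")
  expect_error(gower_distance(tab), "sp02")
})

test_that("PCoA round-trips distances from known planar points", {
  set.seed(11)
  for (rep in 1:5) {
    p <- matrix(rnorm(24), 12, 2)
    d <- as.matrix(dist(p))
    emb <- pcoa_embed(d, m_axes = 2, correction = "none")
    expect_lt(max(abs(as.matrix(dist(emb$all_coordinates)) - d)), 1e-8)
  }
})

test_that("PCoA of an equilateral triple has two equal positive eigenvalues", {
  d <- matrix(0.6, 3, 3)
  diag(d) <- 0
  emb <- pcoa_embed(d, m_axes = 2, correction = "none")
  ev <- emb$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  expect_gt(ev[1], 0)
  expect_lt(abs(ev[3]), 1e-10)
})

test_that("PCoA handles the degenerate and over-asked cases", {
  z <- matrix(0, 4, 4)
  emb <- pcoa_embed(z, m_axes = 3)
  expect_true(all(emb$coordinates == 0))
  d <- as.matrix(dist(cbind(1:5)))  # rank-1 configuration
  expect_error(pcoa_embed(d, m_axes = 4, correction = "none"), "maximum")
})

test_that("Cailliez correction makes Gower distances Euclidean", {
  tab <- distinct_trait_table(25)
  g <- gower_distance(tab)
  emb <- pcoa_embed(g, m_axes = 3, correction = "auto")
  if (emb$correction_applied != "none") {
    const <- attr(emb$correction_applied, "constant")
    expected <- g + const
    diag(expected) <- 0
    expect_lt(max(abs(as.matrix(dist(emb$all_coordinates)) - expected)), 1e-6)
  }
  # eigenvalues agree with the ape reference implementation (repeated
  # eigenvalues make eigenVECTORS rotation-ambiguous, so only spectra
  # and reconstructed distances are comparable)
  ref <- ape::pcoa(as.dist(g), correction = "cailliez")
  ours <- trait_space(tab, m_axes = 3, correction = "cailliez")
  ref_ev <- ref$values$Corr_eig
  k <- min(5, length(ref_ev))
  expect_equal(sort(ours$eigenvalues, decreasing = TRUE)[1:k],
               sort(ref_ev, decreasing = TRUE)[1:k], tolerance = 1e-6)
  expect_lt(max(abs(as.matrix(dist(ours$all_coordinates)) -
                      as.matrix(dist(ref$vectors.cor)))), 1e-6)
})

test_that("trait_space bundles Gower and coordinates consistently", {
  tab <- distinct_trait_table(30)
  sp <- trait_space(tab, m_axes = 3)
  expect_s3_class(sp, "trait_space")
  expect_identical(rownames(sp$coordinates), tab$species)
  expect_equal(ncol(sp$coordinates), 3)
  expect_true(all(diff(sp$eigenvalues) <= 1e-10))
})
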