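test_that("species richness is row sums and permutation-invariant", {
  m <- matrix(c(0, 0, 0, 1, 1, 1, 1, 0, 1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("sp", 1:3)))
  expect_equal(unname(species_richness(m)), c(0, 3, 2))
  perm <- m[, c(3, 1, 2)]
  expect_equal(unname(species_richness(perm)), c(0, 3, 2))
})

test_that("FRic self-normalises and scales with sub-hull area", {
  # pool: 2x2 square corners (area 4) + inner unit square corners
  pool <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2),
                c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.5), c(0.5, 1.5))
  rownames(pool) <- paste0("sp", 1:8)
  cm <- rbind(all = rep(1L, 8),
              inner = c(0, 0, 0, 0, 1, 1, 1, 1))
  colnames(cm) <- rownames(pool)
  fr <- functional_richness(cm, pool, m_axes = 2)
  expect_equal(unname(fr["all"]), 1)
  expect_equal(unname(fr["inner"]), 0.25)   # unit square over area 4
})

test_that("FRic yields NA for sub-dimensional sites and stays in [0,1]", {
  pool <- cbind(c(0, 1, 0, 1, 0.5), c(0, 0, 1, 1, 0.5))
  rownames(pool) <- paste0("sp", 1:5)
  cm <- rbind(pair = c(1, 1, 0, 0, 0),       # 2 points: degenerate in 2D
              dup  = c(1, 0, 0, 0, 1),       # 2 distinct points
              good = c(1, 1, 1, 0, 0))
  colnames(cm) <- rownames(pool)
  fr <- functional_richness(cm, pool, m_axes = 2)
  expect_true(is.na(fr["pair"]) && is.na(fr["dup"]))
  expect_true(fr["good"] > 0 && fr["good"] <= 1)
  expect_error(functional_richness(cm, pool, m_axes = 3), "m_axes")
})

test_that("FRic never decreases when a species is added to a site", {
  set.seed(17)
  coords <- matrix(rnorm(57 * 3), 57, 3,
                   dimnames = list(paste0("sp", 1:57), NULL))
  cm <- matrix(rbinom(57 * 20, 1, 0.4), 20, 57,
               dimnames = list(paste0("s", 1:20), rownames(coords)))
  fr0 <- functional_richness(cm, coords, m_axes = 3)
  for (rep in 1:20) {
    i <- sample(20, 1)
    absent <- which(cm[i, ] == 0)
    if (!length(absent)) next
    cm2 <- cm
    cm2[i, sample(absent, 1)] <- 1L
    fr1 <- functional_richness(cm2, coords, m_axes = 3)
    if (!is.na(fr0[i])) expect_gte(fr1[i], fr0[i] - 1e-12)
  }
  expect_true(all(fr0 >= 0 & fr0 <= 1, na.rm = TRUE))
})

test_that("swap randomization preserves both margins exactly", {
  set.seed(23)
  for (rep in 1:10) {
    m <- matrix(rbinom(30 * 20, 1, runif(1, 0.2, 0.6)), 30, 20)
    r <- swap_randomize(m, seed = rep)
    expect_identical(unname(rowSums(r)), unname(rowSums(m)))
    expect_identical(unname(colSums(r)), unname(colSums(m)))
    expect_true(all(r %in% 0:1))
  }
})

test_that("swap randomization respects forced margins and reaches both 2x2 states", {
  # a full row of ones can never move
  m <- rbind(rep(1L, 6), matrix(rbinom(24, 1, 0.5), 4, 6))
  r <- swap_randomize(m, seed = 3)
  expect_identical(unname(r[1, ]), unname(m[1, ]))
  # the 2x2 identity has exactly two margin-preserving states; every
  # attempted checkerboard swap is accepted here, so an odd accepted-swap
  # target lands on the anti-diagonal and an even one returns home
  id2 <- diag(1L, 2)
  one_swap <- swap_randomize(id2, burn_in_factor = 0.5, seed = 1)  # 1 swap
  expect_equal(unname(unclass(one_swap)), rbind(c(0L, 1L), c(1L, 0L)))
  two_swaps <- swap_randomize(id2, burn_in_factor = 1, seed = 1)   # 2 swaps
  expect_equal(unname(unclass(two_swaps)), unname(unclass(diag(1L, 2))))
  expect_equal(unname(rowSums(one_swap)), c(1, 1))
  expect_equal(unname(colSums(one_swap)), c(1, 1))
})

test_that("seeded swaps are reproducible and chains differ across seeds", {
  m <- matrix(rbinom(200, 1, 0.4), 20, 10)
  expect_identical(swap_randomize(m, seed = 9), swap_randomize(m, seed = 9))
  expect_false(identical(swap_randomize(m, seed = 9),
                         swap_randomize(m, seed = 10)))
})

test_that("SES is degenerate for metrics invariant under the null", {
  set.seed(4)
  m <- matrix(rbinom(300, 1, 0.5), 20, 15)
  expect_warning(
    res <- ses_metric(m, function(x) rowSums(x), n_randomizations = 20,
                      seed = 2),
    "zero null standard deviation")
  expect_true(all(is.na(res$ses)))
  expect_error(ses_metric(m, rowSums, n_randomizations = 1), "at least 2")
})

test_that("SES centres a metric that the null leaves distributionally stable", {
  # column-sum weighted richness varies across swaps; observed value is
  # itself a draw from the null when the matrix is unstructured
  set.seed(8)
  m <- matrix(rbinom(40 * 25, 1, 0.35), 40, 25)
  w <- runif(25)
  metric <- function(x) as.numeric(x %*% w)
  res <- ses_metric(m, metric, n_randomizations = 60, seed = 5)
  expect_lt(abs(mean(res$ses, na.rm = TRUE)), 0.5)
})

test_that("Shannon heterogeneity handles shares, zeros and errors", {
  expect_equal(shannon_heterogeneity(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_heterogeneity(rep(0.25, 4)), log(4))
  expect_equal(shannon_heterogeneity(c(0.5, 0.5, 0, 0, 0)), log(2))
  # renormalisation: shares not summing to one
  expect_equal(shannon_heterogeneity(c(2, 2)), log(2))
  m <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(unname(shannon_heterogeneity(m)), c(0, log(2)))
  expect_error(shannon_heterogeneity(c(0, 0)), "positive")
  expect_error(shannon_heterogeneity(c(-1, 2)), "non-negative")
})

test_that("VIF screening retains orthogonal and drops collinear predictors", {
  set.seed(31)
  n <- 120
  env <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sc <- vif_screen(env, c("a", "b", "c"))
  expect_setequal(sc$retained, c("a", "b", "c"))
  expect_true(all(sc$final_vif < 1.5))

  env$dup <- env$a
  sc2 <- vif_screen(env, c("a", "b", "dup"))
  expect_equal(length(sc2$dropped), 1)
  expect_true(sc2$dropped %in% c("a", "dup"))
  expect_true(is.infinite(sc2$trace$vif[1]))
})

test_that("compositional cover triggers a drop (exact linear dependence)", {
  set.seed(32)
  g <- matrix(rgamma(100 * 6, 2), 100, 6)
  cover <- g / rowSums(g)
  env <- as.data.frame(cover)
  names(env) <- paste0("c", 1:6)
  sc <- vif_screen(env, names(env))
  expect_gte(length(sc$dropped), 1)
  expect_true(is.infinite(sc$trace$vif[1]))
})
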