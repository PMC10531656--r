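test_that("I-spline basis satisfies its boundary and monotonicity contract", {
  set.seed(14)
  for (rep in 1:5) {
    x <- sort(runif(200, -3, 7))
    b <- ispline_basis(x)
    expect_equal(unname(b[1, ]), rep(0, 3))
    expect_equal(unname(b[nrow(b), ]), rep(1, 3))
    expect_true(all(diff(b[, 1]) >= -1e-12))
    expect_true(all(diff(b[, 2]) >= -1e-12))
    expect_true(all(diff(b[, 3]) >= -1e-12))
  }
  expect_error(ispline_basis(rep(2, 10)), "constant")
})

test_that("build_site_pairs enumerates unordered pairs with distances", {
  env <- toy_environment(paste0("s", 1:5))
  d <- matrix(runif(25, 0.1, 0.9), 5, 5,
              dimnames = list(env$site, env$site))
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  pairs <- build_site_pairs(d, env, "temperature")
  expect_equal(nrow(pairs), 10)  # 5 * 4 / 2
  expect_true(all(c("temperature_i", "temperature_j", "distance") %in%
                    names(pairs)))
  # identical coordinates -> zero distance
  env2 <- env
  env2$x[2] <- env2$x[1]; env2$y[2] <- env2$y[1]
  p2 <- build_site_pairs(d, env2, "temperature")
  expect_equal(p2$distance[p2$site_i == "s1" & p2$site_j == "s2"], 0)
  expect_error(build_site_pairs(d, env[-1, ], "temperature"), "s1")
})

test_that("GDM recovers a noiseless monotone single-predictor model", {
  set.seed(21)
  n <- 200
  env <- data.frame(site = paste0("s", 1:n), pred = runif(n, 0, 3),
                    x = runif(n), y = runif(n))
  d <- 1 - exp(-abs(outer(env$pred, env$pred, "-")))
  dimnames(d) <- list(env$site, env$site)
  pairs <- build_site_pairs(d, env, "pred")
  fit <- fit_gdm(pairs, "pred", geo = FALSE)
  expect_true(fit$converged)
  expect_gt(fit$deviance_explained, 95)
  # fitted transform is the identity on pred's range
  tg <- gdm_transforms(fit)
  f <- tg$f[tg$predictor == "pred"]
  x <- tg$x[tg$predictor == "pred"]
  expect_lt(sqrt(mean((f - (x - min(x)))^2)), 0.05)
})

test_that("permuting the response destroys explained deviance", {
  set.seed(22)
  n <- 120
  env <- data.frame(site = paste0("s", 1:n), pred = runif(n, 0, 3),
                    x = runif(n), y = runif(n))
  d <- 1 - exp(-abs(outer(env$pred, env$pred, "-")))
  dimnames(d) <- list(env$site, env$site)
  pairs <- build_site_pairs(d, env, "pred")
  pairs$d <- sample(pairs$d)
  fit <- fit_gdm(pairs, "pred", geo = FALSE)
  expect_lt(fit$deviance_explained, 2)
})

test_that("all-zero dissimilarities give the degenerate zero fit", {
  env <- toy_environment(paste0("s", 1:8))
  d <- matrix(0, 8, 8, dimnames = list(env$site, env$site))
  pairs <- build_site_pairs(d, env, "temperature")
  fit <- fit_gdm(pairs, "temperature")
  expect_equal(fit$intercept, 0)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$deviance_explained, 0)
})

test_that("noise added to the response lowers deviance explained monotonically", {
  set.seed(25)
  n <- 80
  env <- data.frame(site = paste0("s", 1:n), pred = runif(n, 0, 3),
                    x = runif(n), y = runif(n))
  d0 <- 1 - exp(-abs(outer(env$pred, env$pred, "-")))
  dimnames(d0) <- list(env$site, env$site)
  pairs <- build_site_pairs(d0, env, "pred")
  dev <- vapply(c(0, 0.1, 0.3), function(s) {
    p <- pairs
    p$d <- pmin(pmax(p$d + rnorm(nrow(p), 0, s), 0), 1)
    fit_gdm(p, "pred", geo = FALSE)$deviance_explained
  }, 0)
  expect_true(all(diff(dev) < 0))
})

test_that("predictor importance sums coefficients and recovers the true driver", {
  ds <- make_benchmark_dataset("single-driver-temperature", n_sites = 200,
                               seed = 1)
  occ <- ds$community[rowSums(ds$community) > 0, ]
  dt <- taxonomic_jaccard(occ)
  preds <- c("temperature", "forest", "cropland", "population")
  pairs <- build_site_pairs(dt, ds$environment, preds)
  fit <- fit_gdm(pairs, preds, geo = TRUE)
  imp <- predictor_importance(fit)
  # importances are exactly the coefficient sums
  for (p in imp$predictor) {
    expect_equal(imp$importance[imp$predictor == p],
                 unname(sum(fit$coefficients[paste0(p, "_", 1:3)])))
  }
  expect_gt(imp$share[imp$predictor == "temperature"], 0.9)
})

test_that("deviance partition satisfies its arithmetic identity", {
  set.seed(26)
  n <- 60
  env <- data.frame(site = paste0("s", 1:n), pred = runif(n, 0, 3),
                    x = runif(n, 0, 5), y = runif(n, 0, 5))
  d <- 1 - exp(-0.7 * abs(outer(env$pred, env$pred, "-")))
  noise <- matrix(rnorm(n * n, 0, 0.05), n, n)
  noise <- (noise + t(noise)) / 2
  d <- pmin(pmax(d + noise, 0), 1)
  diag(d) <- 0
  dimnames(d) <- list(env$site, env$site)
  pairs <- build_site_pairs(d, env, "pred")
  part <- partition_deviance(pairs, "pred")
  p <- part$partition
  getv <- function(k) p$deviance_explained[p$component == k]
  expect_equal(getv("unique_env") + getv("unique_geo") + getv("shared"),
               getv("full"), tolerance = 1e-9)
  # environment-only turnover: geography adds nothing
  expect_lt(getv("unique_geo"), 2)
  # nested non-negativity
  expect_gte(getv("full") + 1e-6, getv("env_only"))
  expect_gte(getv("full") + 1e-6, getv("geo_only"))
})

test_that("a driver collinear with geography shows up as shared deviance", {
  set.seed(27)
  n <- 60
  # predictor IS the y coordinate: environment and geography coincide
  env <- data.frame(site = paste0("s", 1:n), pred = seq(0, 3, length.out = n),
                    x = 0, y = seq(0, 3, length.out = n))
  d <- 1 - exp(-abs(outer(env$pred, env$pred, "-")))
  dimnames(d) <- list(env$site, env$site)
  pairs <- build_site_pairs(d, env, "pred")
  part <- partition_deviance(pairs, "pred")
  p <- part$partition
  getv <- function(k) p$deviance_explained[p$component == k]
  expect_gt(getv("shared"), getv("full") - 5)
  expect_lt(abs(getv("unique_env")), 5)
  expect_lt(abs(getv("unique_geo")), 5)
})

test_that("prediction honours the link, clamps extrapolation, stays monotone", {
  set.seed(28)
  n <- 60
  env <- data.frame(site = paste0("s", 1:n), pred = runif(n, 0, 3),
                    x = runif(n), y = runif(n))
  d <- 1 - exp(-(0.2 + abs(outer(env$pred, env$pred, "-"))))
  diag(d) <- 0
  dimnames(d) <- list(env$site, env$site)
  pairs <- build_site_pairs(d, env, "pred")
  fit <- fit_gdm(pairs, "pred", geo = FALSE)
  # identical sites -> d = 1 - exp(-alpha)
  same <- pairs[1, ]
  same$pred_j <- same$pred_i
  expect_equal(suppressWarnings(predict_dissimilarity(fit, same)),
               1 - exp(-fit$intercept), tolerance = 1e-12)
  # widening the separation never lowers the prediction
  base <- pairs[3, ]
  seps <- seq(0, 2, length.out = 20)
  preds <- vapply(seps, function(s) {
    p <- base
    p$pred_i <- 0.5
    p$pred_j <- 0.5 + s
    predict_dissimilarity(fit, p)
  }, 0)
  expect_true(all(diff(preds) >= -1e-12))
  # extrapolation warns and clamps
  out <- pairs[1, ]
  out$pred_j <- 99
  expect_warning(predict_dissimilarity(fit, out), "clamped|training range")
})

test_that("RGB ordination maps gradients to colours in [0,1]", {
  # all-equal dissimilarities -> uniform grey
  n <- 8
  d <- matrix(0.4, n, n)
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  rgb0 <- suppressWarnings(rgb_ordination(d))
  expect_true(all(abs(rgb0$G - 0.5) < 1e-9))
  # 1D gradient: first channel monotone along the gradient (up to sign)
  x <- seq(0, 1, length.out = 12)
  d1 <- abs(outer(x, x, "-"))
  dimnames(d1) <- list(paste0("s", 1:12), paste0("s", 1:12))
  rgb1 <- suppressWarnings(rgb_ordination(d1))
  r <- rgb1$R
  expect_true(all(diff(r) >= -1e-9) || all(diff(r) <= 1e-9))
  expect_true(all(rgb1$R >= 0 & rgb1$R <= 1))
  expect_true(all(rgb1$B >= 0 & rgb1$B <= 1))
})

test_that("pairs_to_matrix round-trips dissimilarity_pairs", {
  set.seed(30)
  m <- matrix(runif(16), 4, 4)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  p <- dissimilarity_pairs(m)
  expect_equal(pairs_to_matrix(p), m)
})
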