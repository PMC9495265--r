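test_that("collinearity screen: duplicates, sign symmetry, rank nonlinearity", {
  set.seed(71)
  x <- rnorm(30)
  env <- data.frame(a = x, b = x, c = rnorm(30))
  out <- suppressMessages(collinearity_screen(env))
  expect_identical(nrow(out$dropped), 1L)
  expect_true(out$dropped$variable %in% c("a", "b"))
  expect_equal(out$dropped$rho, 1)

  env2 <- data.frame(a = x, b = -x, c = rnorm(30))
  out2 <- suppressMessages(collinearity_screen(env2))
  expect_equal(out2$dropped$rho, -1)
  expect_identical(ncol(out2$env_reduced), 2L)

  # monotone nonlinear pair: Spearman = 1 even though Pearson < 1
  env3 <- data.frame(a = x, b = x^3, c = rnorm(30))
  expect_lt(abs(cor(env3$a, env3$b)), 1)
  out3 <- suppressMessages(collinearity_screen(env3))
  expect_equal(out3$dropped$rho, 1)
})

test_that("rda_fit: regression identity, null case, saturation", {
  set.seed(72)
  x <- rnorm(25); y <- 2 * x + rnorm(25)
  fit <- rda_fit(matrix(y), matrix(x), n_perm = 0)
  expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-12)

  # X orthogonal to Y by residualisation -> r2 ~ 0
  Y <- matrix(rnorm(25 * 3), 25)
  X <- rnorm(25)
  Xr <- residuals(lm(X ~ Y))
  fit0 <- rda_fit(Y, matrix(Xr), n_perm = 0)
  # residuals are exactly orthogonal to every (centred) response column
  expect_lt(fit0$r2, 1e-10)

  # X spanning Y's own principal axes -> r2 = 1
  Yc <- sweep(Y, 2, colMeans(Y))
  fit1 <- rda_fit(Y, prcomp(Yc)$x[, 1:3], n_perm = 0)
  expect_equal(fit1$r2, 1, tolerance = 1e-10)

  expect_error(rda_fit(Y, diag(25), n_perm = 0), "saturates")
})

test_that("rda_fit matches a per-species OLS oracle", {
  set.seed(73)
  for (i in 1:20) {
    Y <- matrix(rnorm(15 * 8), 15)
    X <- matrix(rnorm(15 * 3), 15)
    fit <- rda_fit(Y, X, n_perm = 0)
    Yc <- sweep(Y, 2, colMeans(Y))
    ssfit <- sum(vapply(seq_len(8), function(j)
      sum(fitted(lm(Yc[, j] ~ scale(X)))^2), numeric(1)))
    expect_equal(fit$r2, ssfit / sum(Yc^2), tolerance = 1e-10)
  }
})

test_that("marginal screen: signal recovery, duplicate symmetry, type-I", {
  set.seed(74)
  n <- 40
  v <- rnorm(n)
  Y <- sapply(1:6, function(j) v * runif(1, 0.8, 1.2) + rnorm(n, 0, 0.4))
  env <- environment_table(data.frame(signal = v, noise1 = rnorm(n),
                                      noise2 = rnorm(n),
                                      row.names = paste0("s", 1:n)))
  scr <- marginal_env_screen(Y, env, n_perm = 199, seed = 1)
  expect_identical(scr$variable[1], "signal")
  expect_true(scr$retained[scr$variable == "signal"])

  env2 <- environment_table(data.frame(s1 = v, s2 = v,
                                       row.names = paste0("s", 1:n)))
  scr2 <- marginal_env_screen(Y, env2, n_perm = 99, seed = 1)
  expect_equal(scr2$r2[1], scr2$r2[2], tolerance = 1e-12)

  # a pure-noise variable is retained at about the nominal rate
  set.seed(75)
  hits <- mean(replicate(300, {
    Yn <- matrix(rnorm(20 * 4), 20)
    en <- environment_table(data.frame(x = rnorm(20),
                                       row.names = paste0("s", 1:20)))
    marginal_env_screen(Yn, en, n_perm = 99)$retained[1]
  }))
  expect_gt(hits, 0.02)
  expect_lt(hits, 0.09)
})

test_that("reduce_connectivity: rank-1 input, orthogonality, PCA oracle", {
  geom <- random_geometry(12, seed = 76)
  # rank-1 connectivity: a single species
  cm1 <- community_matrix(matrix(c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1), 12, 1,
    dimnames = list(geom$site_ids, "sp1")))
  b1 <- connectivity_bundle(cm1, geom, 100)
  ax1 <- reduce_connectivity(b1, include_N = FALSE)
  expect_identical(ncol(ax1), 1L)

  set.seed(76)
  cm <- random_incidence(12, 9)
  b <- connectivity_bundle(cm, geom, 100)
  ax <- reduce_connectivity(b)
  expect_equal(crossprod(ax) - diag(diag(crossprod(ax))),
               matrix(0, ncol(ax), ncol(ax)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # the 90% variance target is met unless the n/3 axis cap binds first
  expect_true(attr(ax, "variance_explained") >= 0.9 ||
                ncol(ax) == floor(nrow(ax) / 3))

  # eigen-decomposition oracle reproduces the axes up to sign
  M <- cbind(b$metric_C, unclass(b$metric_N))
  M <- M[, apply(M, 2, sd) > 0, drop = FALSE]
  Z <- scale(M)
  ev <- eigen(cov(Z), symmetric = TRUE)
  for (j in seq_len(ncol(ax)))
    expect_equal(as.numeric(abs(cor(ax[, j], Z %*% ev$vectors[, j]))), 1,
                 tolerance = 1e-8)
})

test_that("variation partitioning: redundancy, identity, block order", {
  set.seed(77)
  n <- 20
  Y <- matrix(rnorm(n * 5), n)
  E <- matrix(rnorm(n * 2), n)
  S <- matrix(rnorm(n * 2), n)
  C <- matrix(rnorm(n * 2), n)

  # identical E and S blocks: unique fractions vanish, shared = single r2
  vp_dup <- variation_partition(Y, E, E, C, n_perm = 0)
  expect_lt(abs(vp_dup$fractions[["unique_E"]]), 1e-10)
  expect_lt(abs(vp_dup$fractions[["unique_S"]]), 1e-10)
  expect_equal(vp_dup$fractions[["shared_ES"]] +
                 vp_dup$fractions[["shared_ESC"]],
               vp_dup$single[["E"]], tolerance = 1e-10)

  # inclusion-exclusion identity on random instances
  for (i in 1:25) {
    Yr <- matrix(rnorm(n * 4), n)
    vp <- variation_partition(Yr, matrix(rnorm(n * 2), n),
                              matrix(rnorm(n * 3), n),
                              matrix(rnorm(n * 2), n), n_perm = 0)
    expect_equal(sum(vp$fractions[1:7]), vp$total, tolerance = 1e-10)
    expect_equal(vp$fractions[["residual"]], 1 - vp$total, tolerance = 1e-10)
  }

  # permuting block roles permutes the fraction labels, nothing else
  vp1 <- variation_partition(Y, E, S, C, n_perm = 0)
  vp2 <- variation_partition(Y, S, E, C, n_perm = 0)
  expect_equal(vp1$fractions[["unique_E"]], vp2$fractions[["unique_S"]],
               tolerance = 1e-12)
  expect_equal(vp1$fractions[["unique_C"]], vp2$fractions[["unique_C"]],
               tolerance = 1e-12)
  expect_equal(vp1$total, vp2$total, tolerance = 1e-12)
})

test_that("a community built from environment alone puts the variance on E", {
  set.seed(78)
  n <- 40
  E <- matrix(rnorm(n * 2), n)
  Y <- sapply(1:8, function(j)
    E %*% rnorm(2) + rnorm(n, 0, 0.3))
  S <- matrix(rnorm(n * 3), n)
  C <- matrix(rnorm(n * 3), n)
  vp <- variation_partition(Y, E, S, C, n_perm = 199, seed = 1)
  expect_gt(vp$fractions[["unique_E"]], 0.5)
  expect_lt(abs(vp$fractions[["unique_C"]]), 0.1)
  expect_lt(vp$p[["unique_E"]], 0.05)
  expect_gt(vp$p[["unique_C"]], 0.05)
})

test_that("alpha sweep: metric-N-only results are alpha-invariant, runs are
           reproducible", {
  sim <- fixture_small(9)
  cm <- sim$community
  geom <- sim$geometry
  b50 <- connectivity_bundle(cm, geom, 50)
  b300 <- connectivity_bundle(cm, geom, 300)
  axN50 <- reduce_connectivity(b50, include_C = FALSE)
  axN300 <- reduce_connectivity(b300, include_C = FALSE)
  expect_equal(axN50, axN300, ignore_attr = TRUE)

  E <- scale(as.matrix(as.data.frame(sim$environment)[, c("elevation", "AP")]))
  S <- build_mem(geom)$vectors[, 1:2]
  Y <- incidence(cm)
  vpN50 <- variation_partition(Y, E, S, axN50, n_perm = 0, alpha = 50)
  vpN300 <- variation_partition(Y, E, S, axN300, n_perm = 0, alpha = 300)
  expect_equal(vpN50$fractions, vpN300$fractions, tolerance = 1e-12)

  sw1 <- alpha_sweep_varpart(cm, geom, E, S, alpha_grid = c(20, 200),
                             n_perm = 99, seed = 5)
  sw2 <- alpha_sweep_varpart(cm, geom, E, S, alpha_grid = c(20, 200),
                             n_perm = 99, seed = 5)
  expect_identical(sw1$table, sw2$table)
})
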