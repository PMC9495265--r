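test_that("generation is reproducible and validates its configuration", {
  a <- generate_metacommunity(synthetic_config(seed = 5))
  b <- generate_metacommunity(synthetic_config(seed = 5))
  expect_identical(unclass(a$community), unclass(b$community))
  expect_identical(a$geometry$dist, b$geometry$dist)
  expect_identical(as.data.frame(a$environment), as.data.frame(b$environment))

  expect_error(synthetic_config(sorting_weight = 0.5, dispersal_weight = 0.5,
                                noise_weight = 0.2), "sum to 1")
  expect_error(synthetic_config(blocks = c(M = 10, R = 10), n_sites = 30),
               "sum to n_sites")
  expect_error(synthetic_config(kernel_scale = -5), "positive")
})

test_that("the default world has the survey's shape", {
  sim <- generate_metacommunity(synthetic_config(seed = 2))
  cm <- sim$community
  expect_identical(dim(cm), c(78L, 139L))
  expect_identical(as.vector(table(sim$partition)[c("M", "R", "D")]),
                   c(22L, 19L, 37L))
  expect_true(all(rowSums(unclass(cm)) > 0))          # no empty localities
  expect_true(all(colSums(unclass(cm)) > 0))          # no unrecorded species
  expect_identical(names(as.data.frame(sim$environment)),
                   c("elevation", "EVI", "CTI", "HFP", "AMT", "MDTR", "AP"))
  # high beta diversity with a modest nestedness share, as in arid-mosaic
  # bird surveys
  pd <- pairwise_partition(suppressMessages(filter_rare_species(cm)))
  expect_gt(mean(pd$beta_sor), 0.5)
})

test_that("fixture_small is deterministic, valid, and plants a singleton", {
  f1 <- fixture_small(1)
  f2 <- fixture_small(1)
  expect_identical(unclass(f1$community), unclass(f2$community))
  cm <- f1$community
  expect_identical(dim(cm), c(8L, 10L))
  expect_true(all(rowSums(unclass(cm)) > 0))
  expect_true(all(colSums(unclass(cm)) > 0))
  expect_identical(sum(unclass(cm)[, "sp010"] > 0), 1L)
  filtered <- suppressMessages(filter_rare_species(cm, min_sites = 2))
  expect_gte(attr(filtered, "n_removed"), 1L)
})

test_that("occupancy tracks niche availability when sorting operates", {
  sim <- generate_metacommunity(scenario_config("sorting", seed = 3))
  cm <- unclass(sim$community)
  env <- as.data.frame(sim$environment)
  zE <- as.numeric(scale(env$elevation)); zV <- as.numeric(scale(env$EVI))
  mu <- sim$truth$niche_optima
  w <- sim$truth$niche_width
  avail <- vapply(seq_len(nrow(mu)), function(k)
    mean(exp(-((zE - mu[k, 1])^2 + (zV - mu[k, 2])^2) / (2 * w^2))),
    numeric(1))
  occ <- colSums(cm > 0)
  expect_gt(cor(avail, occ, method = "spearman"), 0.3)
})

test_that("environmental fields carry the configured autocorrelation range", {
  # pool the three pure-GRF columns of several replicates and fit an
  # exponential variogram by profile grid search
  range_est <- function(scale_km, seeds) {
    num <- 0; den <- 0
    gh <- list()
    for (s in seeds) {
      cfg <- synthetic_config(seed = s, env_gradient_scale = scale_km)
      sim <- generate_metacommunity(cfg)
      env <- as.data.frame(sim$environment)
      d <- sim$geometry$dist[upper.tri(sim$geometry$dist)]
      for (v in c("CTI", "MDTR", "AP")) {
        z <- as.numeric(scale(env[[v]]))
        g <- 0.5 * outer(z, z, "-")[upper.tri(diag(length(z)))]^2
        gh[[length(gh) + 1]] <- cbind(d, g)
      }
    }
    all <- do.call(rbind, gh)
    bins <- cut(all[, 1], breaks = seq(0, max(all[, 1]), length.out = 15))
    hmid <- tapply(all[, 1], bins, mean)
    gbar <- tapply(all[, 2], bins, mean)
    ok <- !is.na(hmid)
    hmid <- hmid[ok]; gbar <- gbar[ok]
    grid <- seq(10, 400, by = 5)
    sse <- vapply(grid, function(r) {
      basis <- 1 - exp(-hmid / r)
      sill <- sum(gbar * basis) / sum(basis^2)
      sum((gbar - sill * basis)^2)
    }, numeric(1))
    grid[which.min(sse)]
  }
  est <- range_est(100, seeds = 1:4)
  expect_gt(est, 50)
  expect_lt(est, 150)
})

test_that("the planted EVI-AMT collinearity is flagged at threshold 0.9", {
  for (s in 1:5) {
    sim <- generate_metacommunity(synthetic_config(seed = s))
    out <- suppressMessages(collinearity_screen(sim$environment, 0.9))
    pair <- c(out$dropped$variable, out$dropped$partner)
    expect_true(all(c("EVI", "AMT") %in% pair))
    expect_lt(out$dropped$rho[1], -0.9)
  }
})

test_that("scenario truth labels and config match", {
  expect_identical(
    generate_metacommunity(scenario_config("sorting", 1))$truth$expected_dominant,
    "environment")
  expect_identical(
    generate_metacommunity(scenario_config("dispersal", 1))$truth$expected_dominant,
    "connectivity")
  expect_identical(
    generate_metacommunity(scenario_config("noise", 1))$truth$expected_dominant,
    "noise")
})

test_that("write_synthetic emits readable inputs plus config and truth", {
  sim <- fixture_small(2)
  d <- withr::local_tempdir()
  paths <- write_synthetic(sim, d)
  expect_true(all(file.exists(unlist(paths))))
  objs <- read_tables(file.path(d, "community.tsv"), file.path(d, "coords.tsv"),
                      file.path(d, "environment.tsv"))
  expect_equal(unclass(objs$community), unclass(sim$community),
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$kernel_scale, sim$truth$kernel_scale)
})
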