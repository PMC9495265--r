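#' Configuration for the synthetic metacommunity generator
#'
#' Defaults emulate the structure of a 78-transect survey across three
#' contrasting landscape blocks (22/19/37 sites) holding 139 species over an
#' extent of a few hundred km: spatially autocorrelated environmental fields
#' (range `env_gradient_scale` km), Gaussian environmental niches, and a
#' negative-exponential dispersal kernel of scale `kernel_scale` km. The
#' three assembly weights blend species sorting, dispersal limitation and
#' noise and must sum to 1.
#'
#' @param n_sites number of sites.
#' @param blocks named integer vector of landscape block sizes, summing to
#'   `n_sites`.
#' @param n_species number of species.
#' @param env_gradient_scale autocorrelation range of the environmental
#'   random fields, km.
#' @param niche_width Gaussian niche width on the standardised environmental
#'   axes.
#' @param optima_sd spread of species niche optima on the standardised axes;
#'   the default 1.5 places many optima beyond the observed gradient, giving
#'   truncated (monotone) responses within the study extent, as species
#'   ranges along real gradients typically show.
#' @param env_nugget fraction of environmental variance that is spatially
#'   unstructured (micro-habitat variation between transects).
#' @param kernel_scale dispersal kernel scale sigma, km.
#' @param sorting_weight,dispersal_weight,noise_weight assembly mixture
#'   weights in [0,1], summing to 1.
#' @param detection_rate thinning applied to expected counts (transect
#'   surveys miss individuals).
#' @param mean_abundance expected count at a fully suitable occupied site.
#' @param base_occupancy per-wave colonisation probability scaler.
#' @param n_seeds number of founding sites per species.
#' @param n_passes number of colonisation waves per species. One wave keeps
#'   the realised aggregation at the kernel scale; more waves grow clusters
#'   beyond it (each wave convolves the kernel again).
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 78,
                             blocks = c(M = 22, R = 19, D = 37),
                             n_species = 139,
                             env_gradient_scale = 100,
                             niche_width = 1.5,
                             optima_sd = 1.5,
                             env_nugget = 0.15,
                             kernel_scale = 100,
                             sorting_weight = 0.3,
                             dispersal_weight = 0.5,
                             noise_weight = 0.2,
                             detection_rate = 0.8,
                             mean_abundance = 4,
                             base_occupancy = 0.7,
                             n_seeds = 3,
                             n_passes = 1,
                             seed = 1) {
  w <- c(sorting_weight, dispersal_weight, noise_weight)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("sorting, dispersal and noise weights must be in [0,1] and sum to 1")
  if (sum(blocks) != n_sites) stop("block sizes must sum to n_sites")
  if (env_gradient_scale <= 0 || kernel_scale <= 0 || niche_width <= 0)
    stop("all scales must be positive")
  if (env_nugget < 0 || env_nugget >= 1) stop("env_nugget must be in [0, 1)")
  structure(list(n_sites = n_sites, blocks = blocks, n_species = n_species,
                 env_gradient_scale = env_gradient_scale,
                 niche_width = niche_width, optima_sd = optima_sd,
                 env_nugget = env_nugget, kernel_scale = kernel_scale,
                 sorting_weight = sorting_weight,
                 dispersal_weight = dispersal_weight,
                 noise_weight = noise_weight,
                 detection_rate = detection_rate,
                 mean_abundance = mean_abundance,
                 base_occupancy = base_occupancy, n_seeds = n_seeds,
                 n_passes = n_passes, seed = seed),
            class = "synthetic_config")
}

# Gaussian random field over sites: exponential covariance exp(-h/range)
# plus a nugget (spatially unstructured) variance fraction
grf <- function(dist_km, range_km, nugget = 0) {
  Sigma <- (1 - nugget) * exp(-dist_km / range_km) +
    diag(nugget + 1e-8, nrow(dist_km))
  as.numeric(t(chol(Sigma)) %*% stats::rnorm(nrow(dist_km)))
}

#' Generate a synthetic metacommunity with known assembly structure
#'
#' Sites are placed in contiguous latitude bands (one per landscape block)
#' across a temperate-steppe-sized extent. Environmental variables are
#' Gaussian random fields with range `env_gradient_scale`; an annual-mean
#' temperature column is built collinear with the vegetation index
#' (Spearman rho about -0.93) to exercise the collinearity screen. Each
#' species receives a Gaussian niche on the standardised elevation and
#' vegetation axes, then assembles by colonisation waves from a seed site:
#' per pass, an unoccupied site colonises with probability proportional to a
#' weighted blend of niche suitability, kernel connectivity to currently
#' occupied sites (`1 - exp(-sum exp(-d/sigma))`), and uniform noise.
#' Counts are Poisson around suitability-modulated abundance thinned by
#' `detection_rate`. Sites left empty are patched with one individual of the
#' locally most suitable species so that every locality holds a community.
#'
#' @param config a [synthetic_config()].
#' @return list with `community`, `geometry`, `environment`, `partition` and
#'   `truth` (class `synthetic_truth`: niche optima, kernel scale, weights,
#'   expected dominant process).
#' @export
generate_metacommunity <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_sites
  k_blocks <- length(config$blocks)
  block_names <- if (is.null(names(config$blocks)))
    LETTERS[seq_len(k_blocks)] else names(config$blocks)

  # contiguous latitude bands, north (block 1, elevated) to south
  lat_lo <- 45.2; lat_hi <- 49.0; lon_lo <- 85.5; lon_hi <- 90.5
  band_edges <- seq(lat_hi, lat_lo, length.out = k_blocks + 1)
  lat <- numeric(0); lon <- numeric(0); labels <- character(0)
  for (b in seq_len(k_blocks)) {
    nb <- config$blocks[b]
    lat <- c(lat, stats::runif(nb, band_edges[b + 1], band_edges[b]))
    lon <- c(lon, stats::runif(nb, lon_lo, lon_hi))
    labels <- c(labels, rep(block_names[b], nb))
  }
  site_ids <- sprintf("s%02d", seq_len(n))
  geom <- site_geometry(site_ids, lat, lon)
  part <- metacommunity_partition(stats::setNames(labels, site_ids))

  D <- geom$dist
  f <- replicate(6, grf(D, config$env_gradient_scale, config$env_nugget))
  elev_base <- ifelse(labels == block_names[1], 1500, 750)
  evi_z <- f[, 2]
  # AMT planted collinear with EVI at sample Pearson -0.94 (Spearman ~ -0.93):
  # orthogonalised noise keeps the realised correlation on target even though
  # the smooth fields leave few effective degrees of freedom
  ev <- as.numeric(scale(evi_z))
  eps <- stats::rnorm(n)
  eps <- eps - ev * sum(eps * ev) / sum(ev^2)
  eps <- as.numeric(scale(eps))
  amt_z <- -(0.94 * ev + sqrt(1 - 0.94^2) * eps)
  env <- environment_table(data.frame(
    elevation = pmax(420, elev_base + 300 * f[, 1]),
    EVI = 0.2 + 0.08 * evi_z,
    CTI = 8 + 1.5 * f[, 3],
    HFP = pmax(0, 20 + 8 * f[, 4]),
    AMT = 3 * amt_z,
    MDTR = 13 + 2 * f[, 5],
    AP = pmax(50, 250 + 100 * f[, 6]),
    row.names = site_ids))

  # niche space: standardised elevation and vegetation axes
  zE <- as.numeric(scale(env$elevation))
  zV <- as.numeric(scale(env$EVI))
  ws <- config$sorting_weight; wd <- config$dispersal_weight
  wn <- config$noise_weight
  Kd <- exp(-D / config$kernel_scale); diag(Kd) <- 0

  counts <- matrix(0, n, config$n_species,
                   dimnames = list(site_ids,
                                   sprintf("sp%03d", seq_len(config$n_species))))
  optima <- matrix(NA_real_, config$n_species, 2,
                   dimnames = list(colnames(counts), c("elev_z", "evi_z")))
  # species commonness: right-skewed range sizes so the community holds both
  # widespread and rare (single-site) species, as transect surveys do
  commonness <- stats::rbeta(config$n_species, 0.9, 2.2)
  for (k in seq_len(config$n_species)) {
    mu <- stats::rnorm(2, 0, config$optima_sd)
    optima[k, ] <- mu
    suit <- exp(-((zE - mu[1])^2 + (zV - mu[2])^2) /
                  (2 * config$niche_width^2))
    p_seed <- ws * suit + (1 - ws)
    occ <- logical(n)
    occ[sample.int(n, min(config$n_seeds, n), prob = p_seed)] <- TRUE
    for (pass in seq_len(config$n_passes)) {
      # stepping-stone colonisation: reachability decays with distance to
      # the nearest occupied site at the kernel scale, imprinting sigma on
      # the realised aggregation pattern
      dmin <- apply(D[, occ, drop = FALSE], 1, min)
      conn <- exp(-dmin / config$kernel_scale)
      conn[occ] <- 1
      p_col <- config$base_occupancy * (0.25 + 0.75 * commonness[k]) *
        (ws * suit + wd * conn + wn * stats::runif(n))
      newly <- !occ & stats::runif(n) < p_col
      occ <- occ | newly
    }
    lambda <- config$mean_abundance * (0.3 + 0.7 * commonness[k]) *
      (ws * suit + (1 - ws)) * config$detection_rate
    ck <- ifelse(occ, stats::rpois(n, lambda), 0)
    if (all(ck == 0)) ck[which(occ)[1]] <- 1
    counts[, k] <- ck
  }
  # no locality is ever birdless in a field survey: patch empty sites
  empty <- which(rowSums(counts) == 0)
  for (i in empty) {
    suit_i <- exp(-((zE[i] - optima[, 1])^2 + (zV[i] - optima[, 2])^2) /
                    (2 * config$niche_width^2))
    counts[i, which.max(suit_i)] <- 1
  }

  expected <- if (wn >= max(ws, wd)) "noise"
  else if (ws > wd) "environment"
  else if (wd > ws) "connectivity"
  else "mixed"
  truth <- structure(list(niche_optima = optima,
                          niche_width = config$niche_width,
                          kernel_scale = config$kernel_scale,
                          weights = c(sorting = ws, dispersal = wd,
                                      noise = wn),
                          expected_dominant = expected,
                          config = config),
                     class = "synthetic_truth")
  list(community = community_matrix(counts), geometry = geom,
       environment = env, partition = part, truth = truth)
}

#' Canonical assembly scenarios for recovery experiments
#'
#' Configurations for the three archetypal metacommunity generators used to
#' validate the variation-partitioning chain. "sorting" is pure species
#' sorting on a fine-grained environmental mosaic (range 30 km, i.e. weakly
#' structured at typical inter-site spacing) — with an environment smooth at
#' the dispersal scale, sorting and dispersal are formally confounded, so the
#' pure-sorting world keeps them apart by construction. "dispersal" is pure
#' dispersal limitation under a 100 km kernel with spatially smooth (but
#' assembly-irrelevant) environment. "noise" has neither signal.
#'
#' @param process one of "sorting", "dispersal", "noise".
#' @param seed RNG seed.
#' @param n_species number of species (default 100).
#' @param kernel_scale dispersal kernel scale for the dispersal scenario, km.
#' @return a [synthetic_config()].
#' @export
scenario_config <- function(process = c("sorting", "dispersal", "noise"),
                            seed = 1, n_species = 100, kernel_scale = 100) {
  process <- match.arg(process)
  w <- switch(process,
              sorting = c(1, 0, 0),
              dispersal = c(0, 1, 0),
              noise = c(0, 0, 1))
  synthetic_config(n_species = n_species,
                   sorting_weight = w[1], dispersal_weight = w[2],
                   noise_weight = w[3],
                   env_gradient_scale = if (process == "sorting") 30 else 100,
                   # selective niches and repeated establishment waves give
                   # the pure-sorting world its full deterministic signal;
                   # dispersal keeps one wave so the kernel scale stays
                   # imprinted on the realised aggregation
                   niche_width = if (process == "sorting") 1.0 else 1.5,
                   n_passes = if (process == "sorting") 3 else 1,
                   kernel_scale = kernel_scale,
                   seed = seed)
}

#' Tiny deterministic fixture: 8 sites, 10 species
#'
#' A miniature metacommunity (two landscape blocks of 4 sites) with all the
#' structures the pipeline consumes, including one planted single-site
#' species (`sp010`) so the rarity filter always has something to remove.
#' Fully determined by `seed`.
#'
#' @param seed RNG seed.
#' @return same structure as [generate_metacommunity()].
#' @export
fixture_small <- function(seed = 1) {
  cfg <- synthetic_config(n_sites = 8, blocks = c(X = 4, Y = 4),
                          n_species = 10, env_gradient_scale = 80,
                          kernel_scale = 80, base_occupancy = 0.6,
                          n_passes = 3, seed = seed)
  sim <- generate_metacommunity(cfg)
  counts <- unclass(sim$community)
  # plant a singleton at the best-occupied site of the last species
  host <- which.max(counts[, ncol(counts)])
  counts[, ncol(counts)] <- 0
  counts[host, ncol(counts)] <- 1
  empty <- which(rowSums(counts) == 0)
  counts[empty, 1] <- 1
  sim$community <- community_matrix(counts)
  sim
}

#' Write a synthetic dataset in the formats the readers consume
#'
#' Emits the community/coords/environment/labels TSVs (via [write_tables()]),
#' the generating configuration as a human-readable key: value file, and the
#' ground truth as JSON.
#'
#' @param sim a [generate_metacommunity()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(sim, dir) {
  paths <- write_tables(sim, dir)
  cfg <- sim$truth$config
  cfg_lines <- vapply(names(unclass(cfg)), function(nm) {
    v <- cfg[[nm]]
    paste0(nm, ": ", paste(if (!is.null(names(v)))
      paste0(names(v), "=", v) else v, collapse = ", "))
  }, character(1))
  cfg_path <- file.path(dir, "config.yml")
  writeLines(cfg_lines, cfg_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    kernel_scale = sim$truth$kernel_scale,
    niche_width = sim$truth$niche_width,
    weights = as.list(sim$truth$weights),
    expected_dominant = sim$truth$expected_dominant,
    niche_optima = as.data.frame(sim$truth$niche_optima)),
    truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, config = cfg_path, truth = truth_path))
}
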