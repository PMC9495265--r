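#' Incidence-function connectivity metric C
#'
#' Hanski-style connectivity of every site to every species:
#' `c_ik = sum over j != i of N_jk * exp(-d_ij / alpha)`, where `N_jk` is the
#' count (or incidence) of species `k` at the other site `j`, `d_ij` the
#' great-circle distance in km and `alpha` the dispersal-kernel scale in km.
#' Small `alpha` means strong dispersal limitation. The focal site itself is
#' excluded from the sum.
#'
#' @param cm a [community_matrix()]; counts are used as given (pass
#'   `incidence(cm)` for the 0/1 view).
#' @param geom a [site_geometry()] in the same site order.
#' @param alpha kernel scale, km; must be positive.
#' @return site x species matrix of connectivity values.
#' @export
metric_C <- function(cm, geom, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a single positive number (km)")
  N <- unclass(as.matrix(cm))
  K <- exp(-geom$dist / alpha)
  diag(K) <- 0
  out <- K %*% N
  dimnames(out) <- dimnames(N)
  out
}

#' Nearest-occupied-site distance metric N
#'
#' For every site i and species k, the distance to the nearest *other* site
#' where k is present. Species present at no other site (including species
#' recorded at a single site) get the maximum inter-site distance of the
#' study extent as an explicit sentinel; those columns are flagged in the
#' `sentinel_species` attribute.
#'
#' @param cm a [community_matrix()] (incidence view is taken internally).
#' @param geom a [site_geometry()] in the same site order.
#' @return site x species matrix of distances (km), with attributes
#'   `sentinel` (the sentinel value) and `sentinel_species`.
#' @export
metric_N <- function(cm, geom) {
  X <- unclass(incidence(cm))
  D <- geom$dist
  diag(D) <- Inf
  sentinel <- max(geom$dist)
  out <- matrix(sentinel, nrow(X), ncol(X), dimnames = dimnames(X))
  flagged <- logical(ncol(X))
  for (k in seq_len(ncol(X))) {
    occ <- which(X[, k] > 0)
    if (length(occ) == 0) { flagged[k] <- TRUE; next }
    m <- apply(D[, occ, drop = FALSE], 1, min)   # Inf where only self occupied
    sent <- !is.finite(m)
    m[sent] <- sentinel
    if (any(sent)) flagged[k] <- TRUE
    out[, k] <- m
  }
  attr(out, "sentinel") <- sentinel
  attr(out, "sentinel_species") <- colnames(X)[flagged]
  out
}

#' Bundle connectivity predictors at a given dispersal scale
#'
#' @param cm a [community_matrix()].
#' @param geom a [site_geometry()].
#' @param alpha kernel scale, km.
#' @return object of class `connectivity_bundle` with `alpha`, `metric_C`,
#'   `metric_N` and `site_total` (per-site sum of species connectivity).
#' @export
connectivity_bundle <- function(cm, geom, alpha) {
  C <- metric_C(cm, geom, alpha)
  structure(list(alpha = alpha, metric_C = C, metric_N = metric_N(cm, geom),
                 site_total = rowSums(C)),
            class = "connectivity_bundle")
}

#' Default log-spaced dispersal-scale grid, 1-500 km
#'
#' @param n number of grid points.
#' @return ascending numeric vector of alpha values in km.
#' @export
default_alpha_grid <- function(n = 20) exp(seq(log(1), log(500), length.out = n))

#' Estimate the dispersal-kernel scale alpha by grid search
#'
#' Scans a grid of alpha values with one of two objectives and returns the
#' maximiser (ties go to the smallest alpha):
#'
#' * `"decay"` (default): the Pearson correlation between pairwise Sorensen
#'   similarity and the kernel `exp(-d / (1.5 * alpha))`. Community
#'   similarity between two sites colonised from common sources decays as
#'   the self-convolution of the dispersal kernel; its scale is about 1.5x
#'   the kernel's for two-dimensional site layouts censored by the study
#'   extent (the one-dimensional convolution bound would be 2x), hence the
#'   deconvolution factor. Unlike likelihood- or r2-based scores, the
#'   correlation is not invariant to monotone rescaling of distance, so it
#'   is genuinely scale-sensitive.
#' * `"rda"`: explained variation of the species incidence matrix by an RDA
#'   on the reduced metric-C/N axes at each alpha. Simple, but inherits the
#'   construction circularity of metric C, which inflates the objective at
#'   large alpha (documented in the methods vignette).
#'
#' @param cm a [community_matrix()].
#' @param geom a [site_geometry()].
#' @param alpha_grid candidate scales, km (all positive; at least 2 values).
#' @param objective "decay" or "rda".
#' @param variance_kept PCA variance retained when reducing metric C
#'   (see [reduce_connectivity()]); "rda" objective only.
#' @param include_N also include metric N columns in the reduced predictor
#'   block; "rda" objective only.
#' @return object of class `alpha_scan`: `alpha_grid`, `objective` (score
#'   per alpha), `objective_name` and `alpha_star`.
#' @export
estimate_alpha <- function(cm, geom, alpha_grid = default_alpha_grid(),
                           objective = c("decay", "rda"),
                           variance_kept = 0.9, include_N = TRUE) {
  objective <- match.arg(objective)
  if (length(alpha_grid) < 2) stop("alpha_grid needs at least 2 values")
  if (any(alpha_grid <= 0)) stop("alpha grid values must be positive")
  alpha_grid <- sort(alpha_grid)
  Y <- unclass(incidence(cm))
  if (objective == "decay") {
    A <- Y %*% t(Y)
    r <- rowSums(Y)
    if (any(r == 0))
      stop("sites with no species present: ",
           paste(rownames(Y)[r == 0], collapse = ", "))
    ut <- upper.tri(A)
    sim <- (2 * A / outer(r, r, "+"))[ut]     # Sorensen similarity
    if (stats::sd(sim) == 0)
      stop("pairwise similarity is constant; the decay objective is undefined")
    d <- geom$dist[ut]
    obj <- vapply(alpha_grid, function(a) stats::cor(sim, exp(-d / (1.5 * a))),
                  numeric(1))
  } else {
    obj <- vapply(alpha_grid, function(a) {
      bundle <- connectivity_bundle(cm, geom, a)
      axes <- reduce_connectivity(bundle, variance_kept = variance_kept,
                                  include_N = include_N)
      rda_fit(Y, axes, n_perm = 0)$r2
    }, numeric(1))
  }
  if (diff(range(obj)) < .Machine$double.eps^0.5)
    warning("objective is flat across the alpha grid; returning smallest alpha")
  structure(list(alpha_grid = alpha_grid, objective = obj,
                 objective_name = objective,
                 alpha_star = alpha_grid[which.max(obj)]),
            class = "alpha_scan")
}

#' Per-site total connectivity and stepping-stone candidates
#'
#' Sums each site's connectivity over species and ranks sites; sites in the
#' top quantile are flagged as stepping-stone candidates — high-connectivity
#' localities that ease dispersal between distant suitable habitats.
#'
#' @param bundle a [connectivity_bundle()].
#' @param top_frac quantile flagged as stepping stones (default top 20%).
#' @return data.frame (site, total, rank, stepping_stone), sorted by total
#'   descending.
#' @export
site_connectivity <- function(bundle, top_frac = 0.2) {
  tot <- bundle$site_total
  thr <- stats::quantile(tot, 1 - top_frac, names = FALSE)
  out <- data.frame(site = names(tot), total = unname(tot),
                    rank = rank(-tot, ties.method = "min"),
                    stepping_stone = tot >= thr)
  out[order(-out$total), ]
}
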