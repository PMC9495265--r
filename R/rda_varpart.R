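#' Spearman collinearity screen over environmental variables
#'
#' Computes the pairwise Spearman rank correlation matrix and iteratively
#' drops one member of every pair with `|rho| >= threshold`: the member with
#' the larger mean absolute correlation to all other variables (ties go to
#' the later column). This mirrors the usual pre-ordination screen, e.g.
#' dropping one of a vegetation-index / temperature pair correlated at
#' rho close to -0.93.
#'
#' @param env an [environment_table()] (or numeric data.frame).
#' @param threshold absolute Spearman rho at or above which a pair is deemed
#'   collinear; default 0.9.
#' @return list with `rho` (full Spearman matrix), `dropped` (data.frame:
#'   variable, partner, rho) and `env_reduced`.
#' @export
collinearity_screen <- function(env, threshold = 0.9) {
  df <- as.data.frame(env)
  if (ncol(df) < 2) stop("need at least 2 environmental variables")
  rho_full <- stats::cor(df, method = "spearman")
  keep <- names(df)
  dropped <- data.frame(variable = character(0), partner = character(0),
                        rho = numeric(0))
  repeat {
    rho <- rho_full[keep, keep, drop = FALSE]
    diag(rho) <- 0
    if (max(abs(rho)) < threshold) break
    ij <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    meanabs <- vapply(pair, function(v)
      mean(abs(rho[v, setdiff(keep, v)])), numeric(1))
    # drop the variable more entangled with the rest; ties -> later column
    victim <- if (meanabs[2] >= meanabs[1]) pair[2] else pair[1]
    partner <- setdiff(pair, victim)
    dropped <- rbind(dropped, data.frame(
      variable = victim, partner = partner,
      rho = rho_full[victim, partner]))
    message("collinearity screen: dropping '", victim, "' (Spearman rho = ",
            round(rho_full[victim, partner], 3), " with '", partner, "')")
    keep <- setdiff(keep, victim)
  }
  env_reduced <- df[, keep, drop = FALSE]
  class(env_reduced) <- class(env)
  list(rho = rho_full, dropped = dropped, env_reduced = env_reduced)
}

# centre Y columns, standardise X columns (dropping constants), return pieces
prepare_rda <- function(Y, X) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  Yc <- sweep(Y, 2, colMeans(Y))
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) == 0) stop("no non-constant predictors")
  Xs <- scale(X)
  qrX <- qr(Xs)
  rank <- qrX$rank
  n <- nrow(Y)
  if (rank >= n - 1)
    stop("predictor rank (", rank, ") saturates the ", n,
         "-site response; reduce the predictors to fewer axes first")
  Q <- qr.Q(qrX)[, seq_len(rank), drop = FALSE]
  list(Yc = Yc, Q = Q, rank = rank, n = n, ss_tot = sum(Yc^2))
}

rda_r2_from_Q <- function(Yc, Q, ss_tot) sum(crossprod(Q, Yc)^2) / ss_tot

#' Redundancy analysis: explained variation with a Monte Carlo test
#'
#' Multivariate regression of a (column-centred) community matrix on
#' standardised predictors. `r2` is the fraction of the total sum of squares
#' captured by the least-squares projection of Y onto X; the pseudo-F is
#' `(r2/m) / ((1-r2)/(n-1-m))` with m the predictor rank; the p-value comes
#' from permuting the rows of Y, `p = (count(F_perm >= F) + 1)/(n_perm + 1)`.
#'
#' @param Y sites x species response matrix (centred internally).
#' @param X sites x predictors matrix (standardised internally; constant
#'   columns dropped; rank must stay below n_sites - 1).
#' @param n_perm Monte Carlo permutations (0 skips the test).
#' @param seed RNG seed.
#' @return object of class `rda_result`: `r2`, `adj_r2` (Ezekiel), `f_stat`,
#'   `p_perm`, `n_perm`, `rank`.
#' @export
rda_fit <- function(Y, X, n_perm = 999, seed = NULL) {
  pr <- prepare_rda(Y, X)
  if (pr$ss_tot == 0) stop("response matrix has no variance")
  r2 <- rda_r2_from_Q(pr$Yc, pr$Q, pr$ss_tot)
  m <- pr$rank; n <- pr$n
  f_stat <- (r2 / m) / ((1 - r2) / (n - 1 - m))
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 1 - m)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      r2p <- rda_r2_from_Q(pr$Yc[sample.int(n), , drop = FALSE], pr$Q,
                           pr$ss_tot)
      fp <- (r2p / m) / ((1 - r2p) / (n - 1 - m))
      exceed <- exceed + (fp >= f_stat)
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(r2 = r2, adj_r2 = adj_r2, f_stat = f_stat, p_perm = p_perm,
                 n_perm = n_perm, rank = m),
            class = "rda_result")
}

#' Marginal RDA screen of environmental variables
#'
#' One single-variable RDA per environmental variable against the species
#' matrix; variables with permutation p below `p_threshold` are retained.
#' Output is ordered by explained variation, descending.
#'
#' @param Y sites x species response (typically `incidence(cm)`).
#' @param env an [environment_table()].
#' @param n_perm,seed Monte Carlo settings.
#' @param p_threshold retention cut-off (default 0.05).
#' @return data.frame (variable, r2, p, retained), sorted by r2.
#' @export
marginal_env_screen <- function(Y, env, n_perm = 999, seed = NULL,
                                p_threshold = 0.05) {
  df <- as.data.frame(env)
  if (ncol(df) < 1) stop("need at least one environmental variable")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(df), function(v) {
    fit <- rda_fit(Y, df[[v]], n_perm = n_perm)
    data.frame(variable = v, r2 = fit$r2, p = fit$p_perm)
  })
  out <- do.call(rbind, rows)
  out$retained <- out$p < p_threshold
  out[order(-out$r2), ]
}

#' Reduce connectivity predictors to principal-component axes
#'
#' A site x species connectivity matrix has far more columns than an RDA on
#' n sites can absorb, so the standardised `[metric C | metric N]` block is
#' replaced by its leading principal components: the smallest set of axes
#' holding at least `variance_kept` of the variance, capped at `n_sites / 3`
#' axes.
#'
#' @param bundle a [connectivity_bundle()].
#' @param variance_kept fraction of variance to retain (default 0.9).
#' @param include_N include the metric N columns (default TRUE).
#' @param include_C include the metric C columns (default TRUE; disable to
#'   isolate the alpha-invariant metric N contribution).
#' @return sites x axes score matrix (orthogonal columns), with attribute
#'   `variance_explained`.
#' @export
reduce_connectivity <- function(bundle, variance_kept = 0.9,
                                include_N = TRUE, include_C = TRUE) {
  if (!include_N && !include_C) stop("at least one metric must be included")
  M <- if (include_C) bundle$metric_C else NULL
  if (include_N) M <- cbind(M, unclass(bundle$metric_N))
  sds <- apply(M, 2, stats::sd)
  M <- M[, sds > 0, drop = FALSE]
  if (ncol(M) == 0) stop("all connectivity columns are constant")
  pc <- stats::prcomp(M, scale. = TRUE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cumvar >= variance_kept)[1]
  k <- max(1L, min(k, floor(nrow(M) / 3)))
  axes <- pc$x[, seq_len(k), drop = FALSE]
  attr(axes, "variance_explained") <- cumvar[k]
  axes
}

# r2 of Y on the column space of cbind of blocks (unadjusted)
block_r2 <- function(Y, blocks) {
  X <- do.call(cbind, blocks)
  pr <- prepare_rda(Y, X)
  list(r2 = rda_r2_from_Q(pr$Yc, pr$Q, pr$ss_tot), rank = pr$rank)
}

# Freedman-Lane style permutation test of the unique contribution of X given
# covariates W: permute residuals of Y on W, keep the W-fitted part fixed.
partial_rda_perm <- function(Y, X, W, n_perm) {
  Y <- as.matrix(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  n <- nrow(Yc)
  prW <- prepare_rda(Y, W)
  fitW <- prW$Q %*% crossprod(prW$Q, Yc)
  resW <- Yc - fitW
  prF <- prepare_rda(Y, cbind(as.matrix(W), as.matrix(X)))
  ss_tot <- prF$ss_tot
  r2_full <- rda_r2_from_Q(Yc, prF$Q, ss_tot)
  r2_red <- rda_r2_from_Q(Yc, prW$Q, ss_tot)
  mx <- prF$rank - prW$rank
  if (mx < 1) return(list(r2_part = r2_full - r2_red, p = NA_real_))
  fobs <- ((r2_full - r2_red) / mx) / ((1 - r2_full) / (n - 1 - prF$rank))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    Yp <- fitW + resW[sample.int(n), , drop = FALSE]
    Ypc <- sweep(Yp, 2, colMeans(Yp))
    r2f <- rda_r2_from_Q(Ypc, prF$Q, ss_tot)
    r2r <- rda_r2_from_Q(Ypc, prW$Q, ss_tot)
    fp <- ((r2f - r2r) / mx) / ((1 - r2f) / (n - 1 - prF$rank))
    exceed <- exceed + (fp >= fobs)
  }
  list(r2_part = r2_full - r2_red, p = (exceed + 1) / (n_perm + 1))
}

#' Three-set variation partitioning of community composition
#'
#' Fits the seven RDA models on the environmental (E), spatial (S) and
#' connectivity (C) predictor blocks — E, S, C, ES, EC, SC, ESC — and
#' decomposes the full-model explained variation by inclusion-exclusion into
#' three unique, three pairwise-shared and one triple-shared fraction plus
#' the residual. Fractions are unadjusted r2 by default (Ezekiel-adjusted
#' values are also reported); shared fractions are not directly testable, so
#' permutation p-values are given for the full model and the three unique
#' fractions (residualised-model permutation).
#'
#' @param Y sites x species response matrix.
#' @param E,S,C predictor blocks (sites x variables), row-aligned with Y.
#' @param n_perm Monte Carlo permutations (0 skips all tests).
#' @param seed RNG seed.
#' @param alpha optional dispersal scale (km) at which C was built; recorded
#'   in the result.
#' @return object of class `varpart_result`: `single` (r2 of E, S, C),
#'   `fractions` (named vector: unique_E/S/C, shared_ES/EC/SC, shared_ESC,
#'   residual), `total` (ESC r2), `adj` (adjusted analogues), `p`
#'   (total + unique fractions), `alpha`.
#' @export
variation_partition <- function(Y, E, S, C, n_perm = 999, seed = NULL,
                                alpha = NA_real_) {
  blocks <- list(E = as.matrix(E), S = as.matrix(S), C = as.matrix(C))
  if (any(vapply(blocks, function(b) nrow(b) != nrow(as.matrix(Y)),
                 logical(1))))
    stop("predictor blocks must be row-aligned with Y")
  n <- nrow(as.matrix(Y))
  combos <- list(E = "E", S = "S", C = "C", ES = c("E", "S"),
                 EC = c("E", "C"), SC = c("S", "C"), ESC = c("E", "S", "C"))
  fits <- lapply(combos, function(co) block_r2(Y, blocks[co]))
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  rk <- vapply(fits, `[[`, numeric(1), "rank")

  uE <- r2[["ESC"]] - r2[["SC"]]
  uS <- r2[["ESC"]] - r2[["EC"]]
  uC <- r2[["ESC"]] - r2[["ES"]]
  sES <- r2[["ESC"]] - r2[["C"]] - uE - uS       # shared by E and S only
  sEC <- r2[["ESC"]] - r2[["S"]] - uE - uC
  sSC <- r2[["ESC"]] - r2[["E"]] - uS - uC
  sESC <- r2[["ESC"]] - uE - uS - uC - sES - sEC - sSC
  fractions <- c(unique_E = uE, unique_S = uS, unique_C = uC,
                 shared_ES = sES, shared_EC = sEC, shared_SC = sSC,
                 shared_ESC = sESC, residual = 1 - r2[["ESC"]])
  adj <- 1 - (1 - r2) * (n - 1) / (n - 1 - rk)

  p <- c(total = NA_real_, unique_E = NA_real_, unique_S = NA_real_,
         unique_C = NA_real_)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    p["total"] <- rda_fit(Y, do.call(cbind, blocks), n_perm = n_perm)$p_perm
    p["unique_E"] <- partial_rda_perm(Y, blocks$E,
                                      cbind(blocks$S, blocks$C), n_perm)$p
    p["unique_S"] <- partial_rda_perm(Y, blocks$S,
                                      cbind(blocks$E, blocks$C), n_perm)$p
    p["unique_C"] <- partial_rda_perm(Y, blocks$C,
                                      cbind(blocks$E, blocks$S), n_perm)$p
  }
  structure(list(single = r2[c("E", "S", "C")], r2_all = r2,
                 fractions = fractions, total = unname(r2[["ESC"]]),
                 adj = adj, p = p, n_perm = n_perm, alpha = alpha),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Three-set variation partitioning",
      if (!is.na(x$alpha)) sprintf(" (alpha = %.3g km)", x$alpha), "\n",
      sep = "")
  cat(sprintf("  single-set r2: E = %.3f, S = %.3f, C = %.3f\n",
              x$single[["E"]], x$single[["S"]], x$single[["C"]]))
  cat(sprintf("  total (ESC) r2 = %.3f", x$total))
  if (!is.na(x$p[["total"]])) cat(sprintf(" (p = %.4g)", x$p[["total"]]))
  cat("\n  fractions:\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Baseline explained variation of rebuilt connectivity predictors
#'
#' Metric C is derived from the community matrix itself, so its predictor
#' axes explain part of Y even when site positions carry no information (a
#' construction circularity). This estimates that floor: the rows/columns of
#' the distance matrix are permuted (site positions shuffled), metric C (and
#' N) are rebuilt from the unchanged community matrix on the shuffled
#' geometry, reduced to axes, and the adjusted RDA r2 against the original
#' response is recorded. Spatial association is destroyed; the
#' self-referential construction is retained.
#'
#' @param cm a [community_matrix()].
#' @param geom a [site_geometry()].
#' @param alpha kernel scale, km.
#' @param Y response matrix (default `incidence(cm)`).
#' @param n_sim number of rebuild permutations.
#' @param seed RNG seed.
#' @param variance_kept,include_N passed to [reduce_connectivity()].
#' @return mean adjusted r2 over rebuild permutations.
#' @export
connectivity_null_r2 <- function(cm, geom, alpha, Y = incidence(cm),
                                 n_sim = 20, seed = NULL,
                                 variance_kept = 0.9, include_N = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  D <- geom$dist
  vals <- vapply(seq_len(n_sim), function(b) {
    perm <- sample.int(nrow(D))
    gperm <- geom
    gperm$dist <- D[perm, perm]
    dimnames(gperm$dist) <- dimnames(D)
    axes <- reduce_connectivity(connectivity_bundle(cm, gperm, alpha),
                                variance_kept = variance_kept,
                                include_N = include_N)
    rda_fit(Y, axes, n_perm = 0)$adj_r2
  }, numeric(1))
  mean(vals)
}

#' Which assembly process dominates a variation partition?
#'
#' Classifies a [variation_partition()] result into the generator archetypes
#' "environment" (species sorting), "connectivity" (dispersal limitation),
#' "space", or "noise". Blocks of very different rank are compared on
#' Ezekiel-adjusted single-set r2; the connectivity block is additionally
#' corrected by its construction-circularity floor (`c_floor`, see
#' [connectivity_null_r2()]) since metric C is built from the response
#' matrix. If no corrected signal clears `min_signal`, the verdict is
#' "noise".
#'
#' @param vp a `varpart_result`.
#' @param c_floor adjusted-r2 circularity floor subtracted from the
#'   connectivity block (default 0).
#' @param min_signal smallest corrected adjusted r2 counted as structure.
#' @return one of "noise", "environment", "space", "connectivity".
#' @export
dominant_process <- function(vp, c_floor = 0, min_signal = 0.04) {
  excess <- c(environment = unname(vp$adj[["E"]]),
              space = unname(vp$adj[["S"]]),
              connectivity = unname(vp$adj[["C"]]) - c_floor)
  if (max(excess) < min_signal) return("noise")
  names(excess)[which.max(excess)]
}

#' Run the standard assembly-identification chain on a metacommunity
#'
#' The canonical analysis sequence used to ask which process structured a
#' (typically synthetic) metacommunity: rarity-filter the community, drop
#' sites left empty, screen environmental collinearity, build db-MEM axes
#' (capped at n/3, matching the connectivity cap so the spatial and
#' connectivity blocks are compared at equal rank), estimate the dispersal
#' scale, build and reduce connectivity at that scale, partition variation,
#' estimate the connectivity circularity floor, and classify with
#' [dominant_process()]. Spatial structure without an environmental signal
#' is read as dispersal dynamics, so both "space" and "connectivity"
#' verdicts identify a dispersal-limited generator.
#'
#' @param objects list with `community`, `geometry`, `environment` (e.g.
#'   from [generate_metacommunity()]).
#' @param min_sites rarity filter threshold.
#' @param alpha_grid dispersal-scale grid for [estimate_alpha()].
#' @param n_floor_sim permutations for [connectivity_null_r2()].
#' @param seed RNG seed for the floor estimate.
#' @return list: `generator` ("sorting", "dispersal" or "noise"),
#'   `dominant` (raw verdict), `alpha_star`, `varpart`, `c_floor`.
#' @export
identify_generator <- function(objects, min_sites = 2,
                               alpha_grid = default_alpha_grid(),
                               n_floor_sim = 10, seed = 1) {
  cm <- filter_rare_species(objects$community, min_sites = min_sites)
  keep <- rowSums(unclass(cm)) > 0
  if (!all(keep)) {
    message(sum(!keep), " sites empty after rarity filtering; dropped")
    cm <- community_matrix(unclass(cm)[keep, , drop = FALSE])
  }
  g <- objects$geometry
  gi <- match(rownames(cm), g$site_ids)
  geom <- site_geometry(rownames(cm), g$lat[gi], g$lon[gi])
  Y <- incidence(cm)
  env <- collinearity_screen(objects$environment)$env_reduced
  E <- scale(as.matrix(as.data.frame(env)[rownames(cm), , drop = FALSE]))
  S <- build_mem(geom)$vectors
  S <- S[, seq_len(min(ncol(S), floor(nrow(Y) / 3))), drop = FALSE]
  alpha_star <- estimate_alpha(cm, geom, alpha_grid = alpha_grid)$alpha_star
  C <- reduce_connectivity(connectivity_bundle(cm, geom, alpha_star))
  vp <- variation_partition(Y, E, S, C, n_perm = 0, alpha = alpha_star)
  c_floor <- connectivity_null_r2(cm, geom, alpha_star, Y,
                                  n_sim = n_floor_sim, seed = seed)
  dominant <- dominant_process(vp, c_floor = c_floor)
  generator <- switch(dominant,
                      environment = "sorting",
                      space = "dispersal",
                      connectivity = "dispersal",
                      noise = "noise")
  list(generator = generator, dominant = dominant, alpha_star = alpha_star,
       varpart = vp, c_floor = c_floor)
}

#' Variation partitioning swept across dispersal scales
#'
#' Rebuilds the connectivity block (metric C at each alpha plus the
#' alpha-invariant metric N), reduces it to principal-component axes, and
#' partitions variation at every alpha of the grid — the table behind the
#' usual "explained variation vs dispersal scale" figure.
#'
#' @param cm a [community_matrix()] (the incidence view is the response).
#' @param geom a [site_geometry()].
#' @param E environmental predictor block (retained variables).
#' @param S spatial predictor block (e.g. `build_mem(geom)$vectors`).
#' @param alpha_grid dispersal scales in km.
#' @param n_perm,seed Monte Carlo settings (applied per alpha).
#' @param variance_kept PCA variance kept by [reduce_connectivity()].
#' @param include_N include metric N in the connectivity block.
#' @return list with `results` (one `varpart_result` per alpha) and `table`
#'   (long data.frame: alpha_km, fraction, value, p where testable).
#' @export
alpha_sweep_varpart <- function(cm, geom, E, S,
                                alpha_grid = default_alpha_grid(),
                                n_perm = 999, seed = NULL,
                                variance_kept = 0.9, include_N = TRUE) {
  Y <- unclass(incidence(cm))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(alpha_grid))
  results <- lapply(seq_along(alpha_grid), function(i) {
    a <- alpha_grid[i]
    bundle <- connectivity_bundle(cm, geom, a)
    Cax <- reduce_connectivity(bundle, variance_kept = variance_kept,
                               include_N = include_N)
    variation_partition(Y, E, S, Cax, n_perm = n_perm, seed = seeds[i],
                        alpha = a)
  })
  tab <- do.call(rbind, lapply(results, function(vp) {
    data.frame(alpha_km = vp$alpha,
               fraction = c("single_E", "single_S", "single_C", "total",
                            names(vp$fractions)),
               value = unname(c(vp$single, vp$total, vp$fractions)),
               p = unname(c(NA, NA, NA, vp$p[["total"]], vp$p[["unique_E"]],
                            vp$p[["unique_S"]], vp$p[["unique_C"]],
                            rep(NA, 5))))
  }))
  list(results = results, table = tab)
}
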