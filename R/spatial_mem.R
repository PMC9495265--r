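#' Distance-based Moran's eigenvector maps (db-MEM)
#'
#' Classical PCNM-style construction: distances above the truncation
#' threshold are replaced by 4x the threshold, the matrix is transformed as
#' `A = -0.5 * d*^2` and double-centred, and the eigenvectors with positive
#' eigenvalue are retained (descending eigenvalue order) as orthonormal,
#' centred spatial predictors. The default truncation is the longest edge of
#' the minimum spanning tree of the site distance graph, which keeps the
#' truncated graph connected.
#'
#' @param geom a [site_geometry()] with at least 4 sites.
#' @param truncation threshold in km; default the longest MST edge.
#' @return object of class `mem_basis`: `vectors` (site x axis, orthonormal),
#'   `values` (eigenvalues), `truncation_km`, `retained` (axis indices).
#' @export
build_mem <- function(geom, truncation = NULL) {
  d <- geom$dist
  n <- nrow(d)
  if (n < 4) stop("db-MEM needs at least 4 sites")
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    ij <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    stop("duplicate coordinates collapse the spanning tree: ",
         paste(apply(ij, 1, function(r)
           paste(geom$site_ids[r], collapse = "/")), collapse = ", "))
  }
  mst_max <- max(vegan::spantree(stats::as.dist(d))$dist)
  if (is.null(truncation)) truncation <- mst_max
  if (truncation < mst_max - 1e-9)
    warning("truncation below the longest MST edge disconnects the graph")
  dstar <- d
  dstar[dstar > truncation] <- 4 * truncation
  A <- -0.5 * dstar^2
  # double centring
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  keep <- which(e$values > tol)
  V <- e$vectors[, keep, drop = FALSE]
  rownames(V) <- geom$site_ids
  colnames(V) <- paste0("MEM", seq_along(keep))
  structure(list(vectors = V, values = e$values[keep],
                 truncation_km = truncation, retained = seq_along(keep)),
            class = "mem_basis")
}

#' Moran's I spatial autocorrelation
#'
#' Standard Moran's I with row-sum normalised weights:
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with z the centred
#' values.
#'
#' @param values per-site numeric vector (must vary).
#' @param weights non-negative site x site weight matrix, zero diagonal.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  if (n < 4) stop("need at least 4 sites")
  w <- as.matrix(weights)
  if (any(w < 0)) stop("weights must be non-negative")
  diag(w) <- 0
  if (sum(w) == 0) stop("zero total weight")
  rs <- rowSums(w)
  w[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) stop("constant values: Moran's I undefined")
  (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / s2
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over corresponding upper-triangle entries, with a
#' one-tailed (positive association) permutation p-value obtained by
#' permuting the site order of the second matrix:
#' `p = (count(r_perm >= r_obs) + 1) / (n_perm + 1)`.
#'
#' @param dx,dy symmetric zero-diagonal matrices over the same sites.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for reproducibility.
#' @param alternative "greater" (default, positive association) or
#'   "two.sided".
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!all(dim(dx) == dim(dy))) stop("matrices must match in size")
  ut <- upper.tri(dx)
  x <- dx[ut]
  if (stats::sd(x) == 0 || stats::sd(dy[ut]) == 0)
    stop("constant upper triangle: Mantel r undefined")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(x, dy[ut])
  n <- nrow(dx)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(x, dy[p, p][ut])
    hit <- if (alternative == "greater") rp >= r_obs else abs(rp) >= abs(r_obs)
    exceed <- exceed + hit
  }
  list(r = r_obs, p = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Mantel correlogram of environmental structure over geographic distance
#'
#' Environmental distance is Euclidean on the z-scored retained variables.
#' Geographic distances are cut into equal-width classes (Sturges' rule on
#' the number of site pairs); classes with fewer than `min_pairs` pairs are
#' merged into their neighbour. For each class, the Mantel statistic is the
#' correlation between the environmental distance matrix and a membership
#' matrix coding pairs outside the class as 1 (so positive r means sites in
#' the class are environmentally more similar than average). Two-sided
#' permutation p-values are reported raw and with a progressive Holm
#' correction (class k corrected within classes 1..k).
#'
#' @param env an [environment_table()].
#' @param geom a [site_geometry()].
#' @param retained_vars environmental columns to use (from the marginal RDA
#'   screen); must be non-empty.
#' @param n_perm permutations per class.
#' @param seed RNG seed.
#' @param min_pairs smallest class size before merging.
#' @return data.frame of class `mantel_correlogram`: class midpoint (km),
#'   `r`, `p_raw`, `p_holm`, `n_pairs`.
#' @export
mantel_correlogram <- function(env, geom, retained_vars = names(env),
                               n_perm = 999, seed = NULL, min_pairs = 10) {
  if (length(retained_vars) == 0) stop("retained_vars must be non-empty")
  Z <- scale(as.matrix(as.data.frame(env)[, retained_vars, drop = FALSE]))
  denv <- as.matrix(stats::dist(Z))
  dgeo <- geom$dist
  ut <- upper.tri(dgeo)
  gvals <- dgeo[ut]
  n_pairs <- length(gvals)
  k <- ceiling(log2(n_pairs) + 1)                     # Sturges
  breaks <- seq(min(gvals), max(gvals), length.out = k + 1)
  breaks[1] <- breaks[1] - 1e-9
  cls <- cut(gvals, breaks = breaks, labels = FALSE)
  # merge undersized classes into the nearest lower neighbour
  repeat {
    tab <- table(factor(cls, levels = sort(unique(cls))))
    small <- as.integer(names(tab))[tab < min_pairs]
    if (length(small) == 0) break
    s <- small[1]
    lev <- sort(unique(cls))
    target <- if (s == min(lev)) lev[match(s, lev) + 1] else lev[match(s, lev) - 1]
    message("merging distance class ", s, " (", tab[as.character(s)],
            " pairs) into class ", target)
    cls[cls == s] <- target
  }
  lev <- sort(unique(cls))
  if (length(lev) < 2) {
    warning("all site pairs fall in one distance class; correlogram empty")
    out <- data.frame(midpoint_km = numeric(0), r = numeric(0),
                      p_raw = numeric(0), p_holm = numeric(0),
                      n_pairs = numeric(0))
    class(out) <- c("mantel_correlogram", "data.frame")
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(lev, function(l) {
    member <- matrix(0, nrow(dgeo), ncol(dgeo))
    member[ut][cls != l] <- 1                         # outside-class coding
    member <- member + t(member)
    mt <- mantel_test(denv, member, n_perm = n_perm,
                      alternative = "two.sided")
    mid <- mean(gvals[cls == l])
    c(midpoint_km = mid, r = mt$r, p_raw = mt$p, n_pairs = sum(cls == l))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$p_holm <- vapply(seq_len(nrow(out)), function(i)
    stats::p.adjust(out$p_raw[seq_len(i)], method = "holm")[i], numeric(1))
  out <- out[, c("midpoint_km", "r", "p_raw", "p_holm", "n_pairs")]
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
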