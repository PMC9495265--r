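#' Pairwise Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' For every pair of sites with `a` shared species and `b`, `c` species unique
#' to each site, computes Sorensen dissimilarity
#' `beta.sor = (b + c) / (2a + b + c)`, its turnover (Simpson) component
#' `beta.sim = min(b, c) / (a + min(b, c))`, and the nestedness-resultant
#' component `beta.nes = beta.sor - beta.sim` (Baselga partition). Works on
#' the incidence view; abundance input is binarised.
#'
#' @param cm a [community_matrix()]; every site must hold at least one species.
#' @return an object of class `pairwise_dissimilarity`: list with `site_ids`,
#'   integer pair indices `pair_i` < `pair_j`, and vectors `beta_sor`,
#'   `beta_sim`, `beta_nes` over all n(n-1)/2 pairs.
#' @export
pairwise_partition <- function(cm) {
  X <- unclass(incidence(cm))
  r <- rowSums(X)
  if (any(r == 0))
    stop("sites with no species present: ",
         paste(rownames(X)[r == 0], collapse = ", "))
  A <- X %*% t(X)                       # shared species per pair
  n <- nrow(X)
  ij <- which(upper.tri(A), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  a <- unname(A[ij])
  b <- unname(r[ij[, 1]]) - a
  c_ <- unname(r[ij[, 2]]) - a
  minbc <- pmin(b, c_)
  beta_sor <- (b + c_) / (2 * a + b + c_)
  beta_sim <- ifelse(a + minbc == 0, 0, minbc / (a + minbc))
  structure(list(site_ids = rownames(X),
                 pair_i = ij[, 1], pair_j = ij[, 2],
                 beta_sor = beta_sor, beta_sim = beta_sim,
                 beta_nes = beta_sor - beta_sim),
            class = "pairwise_dissimilarity")
}

#' Summarise pairwise dissimilarities
#'
#' Mean and standard error of each index over all site pairs, plus
#' `beta_ratio` = mean(beta.nes) / mean(beta.sor) as a percentage — the share
#' of total dissimilarity attributable to nestedness. The SE is the sample
#' standard deviation over pair values divided by sqrt(number of pairs); pair
#' values are not independent, so treat it as a descriptive spread, not an
#' inferential one.
#'
#' @param pd a [pairwise_partition()] result.
#' @return a data.frame of class `beta_summary` with one row per index and a
#'   `beta_ratio` attribute (percent).
#' @export
beta_summary <- function(pd) {
  stopifnot(inherits(pd, "pairwise_dissimilarity"))
  n <- length(pd$beta_sor)
  if (n < 3) stop("need at least 3 site pairs to summarise")
  one <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(n))
  tab <- rbind(beta.sor = one(pd$beta_sor),
               beta.sim = one(pd$beta_sim),
               beta.nes = one(pd$beta_nes))
  out <- as.data.frame(tab)
  out$index <- rownames(tab)
  out <- out[, c("index", "mean", "se")]
  rownames(out) <- NULL
  attr(out, "beta_ratio") <- 100 * mean(pd$beta_nes) / mean(pd$beta_sor)
  attr(out, "n_pairs") <- n
  class(out) <- c("beta_summary", "data.frame")
  out
}

#' @export
print.beta_summary <- function(x, ...) {
  cat(sprintf("Pairwise beta diversity over %d site pairs\n",
              attr(x, "n_pairs")))
  print.data.frame(cbind(x[1], round(x[-1], 4)))
  cat(sprintf("beta.ratio (nestedness share): %.1f%%\n",
              attr(x, "beta_ratio")))
  invisible(x)
}

pd_values <- function(x, index) {
  if (inherits(x, "pairwise_dissimilarity"))
    x[[paste0("beta_", index)]]
  else as.numeric(x)
}

#' Compare a dissimilarity index between metacommunities
#'
#' Kruskal-Wallis test across all groups and two-sided Mann-Whitney tests for
#' every pair of groups, applied to the pooled pairwise dissimilarity values
#' of each group. Ties are handled by mid-ranks with tie correction; the
#' Mann-Whitney test is exact when the combined sample size is at most 20 and
#' tie-free, and otherwise uses the normal approximation with continuity
#' correction.
#'
#' @param pds named list of [pairwise_partition()] results (or plain numeric
#'   vectors of dissimilarity values), one per group.
#' @param index which index to compare: "sor", "sim" or "nes".
#' @return list with `kruskal` (statistic, df, p) and `pairwise` (data.frame
#'   of group pairs with U statistic and p).
#' @export
compare_groups <- function(pds, index = c("sor", "sim", "nes")) {
  index <- match.arg(index)
  vals <- lapply(pds, pd_values, index = index)
  if (length(vals) < 2) stop("need at least 2 groups")
  if (is.null(names(vals)) || any(names(vals) == ""))
    names(vals) <- paste0("group", seq_along(vals))
  ns <- lengths(vals)
  if (any(ns < 2))
    stop("groups with fewer than 2 values: ",
         paste(names(vals)[ns < 2], collapse = ", "))
  kw <- stats::kruskal.test(vals)
  pairs <- utils::combn(names(vals), 2)
  pw <- apply(pairs, 2, function(p) {
    x <- vals[[p[1]]]; y <- vals[[p[2]]]
    exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    c(U = unname(wt$statistic), p = wt$p.value)
  })
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             U = pw["U", ], p = pw["p", ]))
}
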