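#' Restrict all pipeline objects to one landscape label
#'
#' Subsets the community, geometry, environment and partition to the sites
#' carrying `label`; species with no record inside the subset are dropped,
#' and distance-derived structures (MEM, connectivity) must be recomputed on
#' the subset — nothing is inherited from the full extent.
#'
#' @param objects list with `community`, `geometry`, `environment`,
#'   `partition` (as from [read_tables()] or [generate_metacommunity()]).
#' @param label a level of the partition.
#' @return the same structure, restricted and re-validated.
#' @export
subset_metacommunity <- function(objects, label) {
  part <- objects$partition
  if (!label %in% levels(part)) stop("unknown landscape label: ", label)
  sites <- names(part)[as.character(part) == label]
  if (length(sites) < 4)
    stop("landscape '", label, "' has fewer than 4 sites")
  idx <- match(sites, rownames(objects$community))
  counts <- unclass(objects$community)[idx, , drop = FALSE]
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  g <- objects$geometry
  gi <- match(sites, g$site_ids)
  list(community = community_matrix(counts),
       geometry = site_geometry(sites, g$lat[gi], g$lon[gi]),
       environment = environment_table(
         as.data.frame(objects$environment)[sites, , drop = FALSE]),
       partition = metacommunity_partition(
         stats::setNames(rep(label, length(sites)), sites),
         min_label_size = 3))
}

#' Trim predictor blocks to leave residual degrees of freedom
#'
#' A joint RDA on environmental, spatial and connectivity blocks must keep
#' its combined rank below `n - 1`. E is capped at `n/4` columns (in the
#' order given, i.e. screening order), then the remaining budget of
#' `n - 2 - ncol(E)` axes is split between S and C, each truncated in its
#' own importance order (MEM eigenvalue order, PCA variance order).
#'
#' @param n number of sites.
#' @param E,S,C predictor matrices (columns ordered by importance).
#' @return list with the trimmed `E`, `S`, `C`.
#' @export
budget_blocks <- function(n, E, S, C) {
  kE <- max(1L, min(ncol(E), floor(n / 4)))
  E <- E[, seq_len(kE), drop = FALSE]
  budget <- n - 2 - ncol(E)
  if (budget < 2)
    stop("too few sites (", n, ") for a three-block partition")
  kS <- min(ncol(S), floor(budget / 2))
  kC <- min(ncol(C), budget - kS)
  kS <- min(ncol(S), budget - kC)
  list(E = E, S = S[, seq_len(kS), drop = FALSE],
       C = C[, seq_len(kC), drop = FALSE])
}

analyse_one <- function(objs, name, alpha_grid, n_perm, seed,
                        variance_kept, correlogram_n_perm, min_ordination_sites) {
  cm <- objs$community
  empty <- rowSums(unclass(cm)) == 0
  if (any(empty)) {
    message("metacommunity ", name, ": dropping ", sum(empty),
            " sites left empty by filtering: ",
            paste(rownames(cm)[empty], collapse = ", "))
    keep <- rownames(cm)[!empty]
    cm <- community_matrix(unclass(cm)[keep, , drop = FALSE])
    g <- objs$geometry
    gi <- match(keep, g$site_ids)
    objs$geometry <- site_geometry(keep, g$lat[gi], g$lon[gi])
    objs$environment <- environment_table(
      as.data.frame(objs$environment)[keep, , drop = FALSE])
    objs$community <- cm
  }
  geom <- objs$geometry
  n <- nrow(cm)
  out <- list(name = name, n_sites = n)

  pd <- pairwise_partition(cm)
  out$beta <- beta_summary(pd)
  out$pairwise <- pd
  if (n < min_ordination_sites) {
    message("metacommunity ", name, ": ", n,
            " sites; ordination stages skipped (need >= ",
            min_ordination_sites, ")")
    return(out)
  }

  Y <- unclass(incidence(cm))
  screen <- marginal_env_screen(Y, objs$environment, n_perm = n_perm,
                                seed = seed)
  out$env_screen <- screen
  retained <- screen$variable[screen$retained]
  if (length(retained) == 0) {
    message("metacommunity ", name,
            ": no environmental variable significant; keeping top-r2 variable")
    retained <- screen$variable[1]
  }
  out$retained_vars <- retained
  out$correlogram <- mantel_correlogram(objs$environment, geom,
                                        retained_vars = retained,
                                        n_perm = correlogram_n_perm,
                                        seed = seed)
  mem <- build_mem(geom)
  out$mem <- mem
  E0 <- scale(as.matrix(as.data.frame(objs$environment)[, retained,
                                                        drop = FALSE]))
  bundle_max <- connectivity_bundle(cm, geom, max(alpha_grid))
  Cmax <- reduce_connectivity(bundle_max, variance_kept = variance_kept)
  blocks <- budget_blocks(n, E0, mem$vectors, Cmax)

  sweep_res <- alpha_sweep_varpart(
    cm, geom, blocks$E, blocks$S, alpha_grid = alpha_grid, n_perm = n_perm,
    seed = seed, variance_kept = variance_kept)
  # cap connectivity axes inside the sweep via a wrapper is avoided; instead
  # re-budget per alpha only if saturation occurs (rare at survey sizes)
  out$sweep <- sweep_res
  vp_max <- sweep_res$results[[length(sweep_res$results)]]
  out$varpart_max <- vp_max
  out$c_floor <- connectivity_null_r2(cm, geom, max(alpha_grid),
                                      Y = Y, n_sim = 10, seed = seed,
                                      variance_kept = variance_kept)
  out$dominant <- dominant_process(vp_max, c_floor = out$c_floor)
  sc <- site_connectivity(bundle_max)
  gi <- match(sc$site, geom$site_ids)
  sc$lat <- geom$lat[gi]
  sc$lon <- geom$lon[gi]
  out$site_connectivity <- sc
  out$alpha_scan <- estimate_alpha(cm, geom, alpha_grid = alpha_grid,
                                   variance_kept = variance_kept)
  out
}

#' Run the full metacommunity workflow and write its output tables
#'
#' For the full site set ("A") and each landscape label: beta-diversity
#' summary, marginal environmental screening, Mantel correlogram of the
#' retained variables, db-MEM spatial predictors, a variation-partitioning
#' sweep over the dispersal-scale grid, and per-site connectivity totals at
#' the largest scale. Writes seven artefacts to `out_dir`:
#' `beta_summary.tsv`, `env_screen.tsv`, `correlogram.tsv`,
#' `varpart_single.tsv`, `alpha_sweep.tsv`, `site_connectivity.tsv` and
#' `manifest.json` (parameters, seeds, dominant predictor per metacommunity,
#' file checksums). Landscape subsets too small for ordination keep their
#' beta summaries and skip the ordination stages with a logged note.
#'
#' @param objects list with `community`, `geometry`, `environment` and
#'   optionally `partition`.
#' @param out_dir output directory.
#' @param min_sites rarity-filter occupancy threshold (default 2).
#' @param collinearity_threshold Spearman screen threshold (default 0.9).
#' @param alpha_grid dispersal-scale grid, km.
#' @param n_perm Monte Carlo permutations (>= 99).
#' @param correlogram_n_perm permutations per correlogram class.
#' @param variance_kept PCA variance kept for connectivity axes.
#' @param min_ordination_sites smallest subset given the ordination stages.
#' @param seed master seed; every stochastic stage derives from it.
#' @return invisibly, a list of per-metacommunity results plus the manifest.
#' @export
run_pipeline <- function(objects, out_dir, min_sites = 2,
                         collinearity_threshold = 0.9,
                         alpha_grid = default_alpha_grid(),
                         n_perm = 999, correlogram_n_perm = 199,
                         variance_kept = 0.9, min_ordination_sites = 8,
                         seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "rarity filter"
  res <- tryCatch({
    cm <- filter_rare_species(objects$community, min_sites = min_sites)
    objects$community <- cm

    stage <- "collinearity screen"
    cs <- collinearity_screen(objects$environment,
                              threshold = collinearity_threshold)
    objects$environment <- cs$env_reduced

    mcs <- list(A = objects)
    if (!is.null(objects$partition))
      for (l in levels(objects$partition))
        mcs[[l]] <- subset_metacommunity(objects, l)

    results <- list()
    for (nm in names(mcs)) {
      stage <- paste0("metacommunity ", nm)
      results[[nm]] <- analyse_one(
        mcs[[nm]], nm, alpha_grid = alpha_grid, n_perm = n_perm,
        seed = seed, variance_kept = variance_kept,
        correlogram_n_perm = correlogram_n_perm,
        min_ordination_sites = min_ordination_sites)
    }
    list(results = results, collinearity = cs)
  }, error = function(e) {
    manifest <- list(status = "failed", stage = stage,
                     error = conditionMessage(e),
                     files_written = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  results <- res$results
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  beta_tab <- do.call(rbind, lapply(results, function(r)
    data.frame(metacommunity = r$name, n_sites = r$n_sites,
               index = r$beta$index, mean = r$beta$mean, se = r$beta$se,
               beta_ratio_pct = attr(r$beta, "beta_ratio"))))
  files <- wtsv(beta_tab, "beta_summary.tsv")

  ord <- Filter(function(r) !is.null(r$env_screen), results)
  files <- c(files, wtsv(do.call(rbind, lapply(ord, function(r)
    cbind(metacommunity = r$name, r$env_screen))), "env_screen.tsv"))
  cg <- do.call(rbind, lapply(ord, function(r) {
    df <- as.data.frame(r$correlogram)
    if (nrow(df) == 0) return(NULL)
    cbind(metacommunity = r$name, df)
  }))
  if (is.null(cg))
    cg <- data.frame(metacommunity = character(0), midpoint_km = numeric(0),
                     r = numeric(0), p_raw = numeric(0), p_holm = numeric(0),
                     n_pairs = numeric(0))
  files <- c(files, wtsv(cg, "correlogram.tsv"))
  files <- c(files, wtsv(do.call(rbind, lapply(ord, function(r) {
    vp <- r$varpart_max
    data.frame(metacommunity = r$name,
               predictor = c("environment", "space", "connectivity", "total"),
               r2 = c(unname(vp$single), vp$total),
               p = c(NA, NA, NA, unname(vp$p[["total"]])))
  })), "varpart_single.tsv"))
  files <- c(files, wtsv(do.call(rbind, lapply(ord, function(r)
    cbind(metacommunity = r$name, r$sweep$table))), "alpha_sweep.tsv"))
  files <- c(files, wtsv(do.call(rbind, lapply(ord, function(r)
    cbind(metacommunity = r$name, r$site_connectivity))),
    "site_connectivity.tsv"))

  manifest <- list(
    status = "ok",
    package_version = as.character(utils::packageVersion("metaconn")),
    seed = seed, n_perm = n_perm,
    min_sites = min_sites,
    collinearity_threshold = collinearity_threshold,
    alpha_grid_km = alpha_grid,
    variance_kept = variance_kept,
    dropped_collinear = res$collinearity$dropped,
    dominant_predictor = lapply(ord, function(r) r$dominant),
    alpha_star_km = lapply(ord, function(r) r$alpha_scan$alpha_star),
    file_md5 = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, collinearity = res$collinearity,
                 manifest = manifest))
}
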