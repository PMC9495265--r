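# shared test scaffolding: tiny deterministic builders used across files

# a 2-site incidence pair with no empty site, from given per-site species sets
pair_matrix <- function(sp1, sp2) {
  species <- sort(union(sp1, sp2))
  m <- rbind(as.integer(species %in% sp1), as.integer(species %in% sp2))
  dimnames(m) <- list(c("a", "b"), species)
  community_matrix(m)
}

# random incidence matrix with no empty sites (and, optionally, no species
# absent everywhere — leave off for 2-site pairs, where it is near-impossible
# at low prevalence and irrelevant to pairwise indices)
random_incidence <- function(n_sites, n_species, p = 0.4,
                             require_species = n_sites > 2) {
  repeat {
    m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species,
                dimnames = list(paste0("s", seq_len(n_sites)),
                                paste0("sp", seq_len(n_species))))
    if (all(rowSums(m) > 0) && (!require_species || all(colSums(m) > 0)))
      return(community_matrix(m))
  }
}

# random scattered geometry inside the study window
random_geometry <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  site_geometry(paste0("s", seq_len(n)),
                lat = runif(n, 45, 49), lon = runif(n, 85, 91))
}

# spherical law of cosines, independent of the haversine implementation
slc_distance <- function(lat1, lon1, lat2, lon2, R = 6371) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  arg <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  R * acos(pmin(1, pmax(-1, arg)))
}

# collinear sites along one meridian at given km offsets (exact arc distances)
meridian_geometry <- function(km) {
  site_geometry(paste0("s", seq_along(km)),
                lat = 45 + km / (6371 * pi / 180), lon = rep(87, length(km)))
}

# write a community/coords/env/labels TSV quartet, returning the paths
write_input_quartet <- function(dir, cm, lat, lon, env, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  write.table(data.frame(site = rownames(cm), unclass(cm),
                         check.names = FALSE),
              p$community <- file.path(dir, "comm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(site = rownames(cm), lat = lat, lon = lon),
              p$coords <- file.path(dir, "coords.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(site = rownames(cm), env, check.names = FALSE),
              p$env <- file.path(dir, "env.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels))
    write.table(data.frame(site = rownames(cm), landscape = labels),
                p$labels <- file.path(dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
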