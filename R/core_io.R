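#' Construct and validate a community matrix
#'
#' A community matrix holds counts or incidences of species (columns) at
#' sites (rows). Values must be finite and non-negative; site and species
#' labels must be unique. An incidence (presence/absence) view is always
#' derivable with [incidence()].
#'
#' @param values numeric matrix, sites x species (counts or 0/1 incidences).
#' @param site_ids site labels; defaults to `rownames(values)`.
#' @param species_ids species labels; defaults to `colnames(values)`.
#' @return a numeric matrix of class `community_matrix`.
#' @export
community_matrix <- function(values, site_ids = rownames(values),
                             species_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(site_ids) || is.null(species_ids))
    stop("community_matrix needs site and species labels")
  site_ids <- as.character(site_ids)
  species_ids <- as.character(species_ids)
  if (nrow(values) != length(site_ids) || ncol(values) != length(species_ids))
    stop("label lengths do not match matrix dimensions")
  if (anyDuplicated(site_ids))
    stop("duplicate site labels: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  if (anyDuplicated(species_ids))
    stop("duplicate species labels: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  if (nrow(values) < 2) stop("a community matrix needs at least 2 sites")
  if (ncol(values) < 1) stop("a community matrix needs at least 1 species")
  if (any(!is.finite(values)) || any(values < 0))
    stop("community values must be finite and non-negative")
  dimnames(values) <- list(site_ids, species_ids)
  class(values) <- c("community_matrix", class(values))
  values
}

#' Incidence (presence/absence) view of a community matrix
#'
#' @param cm a [community_matrix()] (or plain numeric matrix).
#' @return a 0/1 matrix with the same dimnames and class.
#' @export
incidence <- function(cm) {
  out <- (unclass(as.matrix(cm)) > 0) * 1
  dimnames(out) <- dimnames(cm)
  class(out) <- c("community_matrix", "matrix", "array")
  out
}

#' Great-circle (haversine) distance matrix
#'
#' Distances between sites given in decimal-degree latitude/longitude, on a
#' sphere of radius 6371 km.
#'
#' @param lat,lon numeric vectors, decimal degrees.
#' @param radius_km sphere radius; default 6371.
#' @return symmetric matrix of distances in km with zero diagonal.
#' @export
great_circle_distances <- function(lat, lon, radius_km = 6371) {
  if (length(lat) != length(lon)) stop("lat and lon lengths differ")
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90))
    stop("latitude outside [-90, 90]")
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180))
    stop("longitude outside [-180, 180]")
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  h <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  h[h > 1] <- 1
  d <- 2 * radius_km * asin(sqrt(h))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Site geometry: coordinates and the derived distance matrix
#'
#' @param site_ids site labels, in community-matrix order.
#' @param lat,lon decimal-degree coordinates.
#' @return an object of class `site_geometry` with fields `site_ids`, `lat`,
#'   `lon`, and `dist` (great-circle km).
#' @export
site_geometry <- function(site_ids, lat, lon) {
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) stop("duplicate site labels in geometry")
  if (length(lat) != length(site_ids) || length(lon) != length(site_ids))
    stop("coordinate lengths do not match site labels")
  d <- great_circle_distances(lat, lon)
  dimnames(d) <- list(site_ids, site_ids)
  structure(list(site_ids = site_ids, lat = as.numeric(lat),
                 lon = as.numeric(lon), dist = d),
            class = "site_geometry")
}

#' Site-by-environment table
#'
#' Validates a numeric table of per-site environmental variables (e.g.
#' elevation, EVI, CTI, HFP, AMT, MDTR, AP). No missing values are allowed
#' and every column must vary.
#'
#' @param df data.frame of numeric columns, rownames (or `site_ids`) = sites.
#' @param site_ids site labels; defaults to `rownames(df)`.
#' @return a data.frame of class `environment_table`.
#' @export
environment_table <- function(df, site_ids = rownames(df)) {
  df <- as.data.frame(df)
  if (is.null(site_ids)) stop("environment table needs site labels")
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) stop("duplicate site labels in environment table")
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric environment columns: ",
                        paste(bad, collapse = ", "))
  if (anyNA(df)) {
    idx <- which(is.na(as.matrix(df)), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at site '%s', variable '%s'",
                 site_ids[idx[1]], names(df)[idx[2]]))
  }
  novar <- names(df)[vapply(df, function(x) stats::var(x) == 0, logical(1))]
  if (length(novar)) stop("zero-variance environment columns: ",
                          paste(novar, collapse = ", "))
  rownames(df) <- site_ids
  class(df) <- c("environment_table", "data.frame")
  df
}

#' Metacommunity (landscape) partition of sites
#'
#' @param labels per-site landscape labels (e.g. "M", "R", "D"); the full
#'   metacommunity is the union of all sites.
#' @param site_ids site labels; defaults to `names(labels)`.
#' @param min_label_size smallest admissible group; default 3 so downstream
#'   statistics are defined.
#' @return a named factor of class `metacommunity_partition`.
#' @export
metacommunity_partition <- function(labels, site_ids = names(labels),
                                    min_label_size = 3) {
  if (is.null(site_ids)) stop("partition needs site labels")
  site_ids <- as.character(site_ids)
  f <- factor(as.character(labels))
  if (anyNA(f)) stop("every site must carry exactly one landscape label")
  tab <- table(f)
  small <- names(tab)[tab < min_label_size]
  if (length(small))
    stop("landscape labels with fewer than ", min_label_size, " sites: ",
         paste(small, collapse = ", "))
  names(f) <- site_ids
  class(f) <- c("metacommunity_partition", "factor")
  f
}

# crude delimiter sniffing between tab and comma on the header line
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_site_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  sites <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      if (anyNA(num) && !anyNA(vals[[j]])) {
        i <- which(is.na(num))[1]
        stop(sprintf("non-numeric cell in %s at row %d ('%s'), column '%s'",
                     basename(path), i, sites[i], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  rownames(vals) <- sites
  vals
}

#' Read and cross-validate the pipeline input tables
#'
#' Reads the site-by-species table, the site coordinates (`site`, `lat`,
#' `lon`), the site-by-environment table and (optionally) the site landscape
#' labels. All tables are re-aligned to the community-matrix site order; any
#' mismatch in site sets is a hard error naming the offending sites.
#'
#' @param community_path,coords_path,env_path,labels_path delimited text files
#'   (TSV or CSV, auto-detected) whose first column is the site label.
#' @return a list with elements `community`, `geometry`, `environment` and
#'   (if labels were given) `partition`.
#' @export
read_tables <- function(community_path, coords_path, env_path,
                        labels_path = NULL) {
  comm <- read_site_table(community_path)
  coords <- read_site_table(coords_path)
  env <- read_site_table(env_path)
  sites <- rownames(comm)

  check_sites <- function(tab, what) {
    missing <- setdiff(sites, rownames(tab))
    extra <- setdiff(rownames(tab), sites)
    if (length(missing) || length(extra))
      stop(sprintf("site sets disagree between community and %s table%s%s",
                   what,
                   if (length(missing))
                     paste0("; missing: ", paste(missing, collapse = ", "))
                   else "",
                   if (length(extra))
                     paste0("; extra: ", paste(extra, collapse = ", "))
                   else ""))
    tab[sites, , drop = FALSE]
  }
  coords <- check_sites(coords, "coordinate")
  env <- check_sites(env, "environment")
  lc <- tolower(names(coords))
  lat_col <- match(TRUE, lc %in% c("lat", "latitude"))
  lon_col <- match(TRUE, lc %in% c("lon", "long", "longitude"))
  if (is.na(lat_col) || is.na(lon_col))
    stop("coordinate table must have lat/latitude and lon/longitude columns")

  out <- list(
    community = community_matrix(as.matrix(comm)),
    geometry = site_geometry(sites, coords[[lat_col]], coords[[lon_col]]),
    environment = environment_table(env)
  )
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, header = TRUE,
                             sep = detect_delim(labels_path),
                             stringsAsFactors = FALSE, comment.char = "")
    labs <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
    missing <- setdiff(sites, names(labs))
    if (length(missing))
      stop("site sets disagree between community and label table; missing: ",
           paste(missing, collapse = ", "))
    out$partition <- metacommunity_partition(labs[sites], site_ids = sites)
  }
  out
}

#' Write the canonical pipeline tables plus a JSON validation report
#'
#' @param objects list as returned by [read_tables()] or
#'   [generate_metacommunity()] (fields `community`, `geometry`,
#'   `environment`, optional `partition`).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_tables <- function(objects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(data.frame(site = rownames(df), df,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  cm <- objects$community
  paths["community"] <- wtsv(as.data.frame(unclass(cm)), "community.tsv")
  g <- objects$geometry
  paths["coords"] <- wtsv(data.frame(lat = g$lat, lon = g$lon,
                                     row.names = g$site_ids), "coords.tsv")
  paths["environment"] <- wtsv(as.data.frame(objects$environment),
                               "environment.tsv")
  if (!is.null(objects$partition))
    paths["labels"] <- wtsv(data.frame(
      landscape = as.character(objects$partition),
      row.names = names(objects$partition)), "labels.tsv")
  report <- list(
    n_sites = nrow(cm), n_species = ncol(cm),
    total_count = sum(cm),
    labels = if (!is.null(objects$partition))
      as.list(table(objects$partition)) else NULL
  )
  p <- file.path(dir, "validation.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, pretty = TRUE)
  paths["validation"] <- p
  invisible(paths)
}

#' Drop species recorded at fewer than `min_sites` sites
#'
#' The default `min_sites = 2` keeps species recorded in more than one
#' site, the usual screen before beta-diversity and ordination analyses.
#'
#' @param cm a [community_matrix()].
#' @param min_sites minimum occupancy (number of sites with a record).
#' @return the filtered community matrix; attribute `n_removed` records how
#'   many species were dropped.
#' @export
filter_rare_species <- function(cm, min_sites = 2) {
  if (min_sites < 1) stop("min_sites must be >= 1")
  occ <- colSums(unclass(cm) > 0)
  keep <- occ >= min_sites
  if (!any(keep)) stop("rarity filter would remove every species")
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message(n_removed, " species below occupancy ", min_sites, " removed (",
            sum(keep), " retained)")
  out <- community_matrix(unclass(cm)[, keep, drop = FALSE])
  attr(out, "n_removed") <- n_removed
  out
}

#' Per-landscape richness and shared-species counts
#'
#' @param cm a [community_matrix()].
#' @param part a [metacommunity_partition()] over the same sites.
#' @return list with `richness` (per label), `pairwise_shared` (label x label
#'   matrix of shared species counts), and `shared_all` (species present in
#'   every landscape) — the Venn cells of a landscape overlap diagram.
#' @export
richness_overlap <- function(cm, part) {
  if (nlevels(part) < 2) stop("need at least 2 landscape labels")
  if (nrow(cm) != length(part)) stop("partition length does not match sites")
  X <- incidence(cm)
  specs <- lapply(levels(part), function(l) {
    colnames(X)[colSums(X[part == l, , drop = FALSE]) > 0]
  })
  names(specs) <- levels(part)
  k <- length(specs)
  shared <- matrix(0L, k, k, dimnames = list(names(specs), names(specs)))
  for (i in seq_len(k)) for (j in seq_len(k))
    shared[i, j] <- length(intersect(specs[[i]], specs[[j]]))
  list(richness = vapply(specs, length, integer(1)),
       pairwise_shared = shared,
       shared_all = length(Reduce(intersect, specs)))
}
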