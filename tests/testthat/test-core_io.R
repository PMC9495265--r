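test_that("read_tables round-trips a fixture and re-aligns row order", {
  cm <- random_incidence(3, 2)
  lat <- c(45.1, 46.2, 47.3); lon <- c(86, 87, 88)
  env <- data.frame(elevation = c(500, 900, 1400), EVI = c(0.1, 0.2, 0.3))
  d <- withr::local_tempdir()
  p <- write_input_quartet(d, cm, lat, lon, env,
                           labels = c("X", "X", "Y"))
  # labels with <3 sites per level: relax by reading without labels
  objs <- read_tables(p$community, p$coords, p$env)
  expect_s3_class(objs$community, "community_matrix")
  expect_identical(dim(objs$community), c(3L, 2L))
  expect_equal(unclass(objs$community), unclass(cm), ignore_attr = TRUE)
  expect_equal(objs$geometry$lat, lat)
  expect_equal(as.data.frame(objs$environment)$elevation, env$elevation)

  # shuffle coordinate rows on disk; reader must re-align to community order
  co <- read.delim(p$coords)
  write.table(co[c(3, 1, 2), ], p$coords, sep = "\t", quote = FALSE,
              row.names = FALSE)
  objs2 <- read_tables(p$community, p$coords, p$env)
  expect_equal(objs2$geometry$lat, lat)
})

test_that("site-set mismatches and bad cells are hard errors naming culprits", {
  cm <- random_incidence(3, 2)
  env <- data.frame(elevation = c(500, 900, 1400), EVI = c(0.1, 0.2, 0.3))
  d <- withr::local_tempdir()
  p <- write_input_quartet(d, cm, c(45, 46, 47), c(86, 87, 88), env)
  co <- read.delim(p$coords)
  co$site[2] <- "x9"
  write.table(co, p$coords, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tables(p$community, p$coords, p$env), "x9")

  p2 <- write_input_quartet(d, cm, c(45, 46, 47), c(86, 87, 88), env)
  ev <- read.delim(p2$env)
  ev$elevation[2] <- "oops"
  write.table(ev, p2$env, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tables(p2$community, p2$coords, p2$env), "non-numeric")
})

test_that("write_tables -> read_tables is lossless to 12 significant digits", {
  sim <- fixture_small(4)
  d <- withr::local_tempdir()
  write_tables(sim, d)
  objs <- read_tables(file.path(d, "community.tsv"), file.path(d, "coords.tsv"),
                      file.path(d, "environment.tsv"), file.path(d, "labels.tsv"))
  expect_equal(unclass(objs$community), unclass(sim$community),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.matrix(as.data.frame(objs$environment)),
               as.matrix(as.data.frame(sim$environment)), tolerance = 1e-12)
  expect_identical(as.character(objs$partition), as.character(sim$partition))
})

test_that("filter_rare_species keeps occupancy >= min_sites and is idempotent", {
  m <- matrix(0, 6, 3, dimnames = list(paste0("s", 1:6), c("one", "two", "five")))
  m[1, "one"] <- 1; m[1:2, "two"] <- 1; m[1:5, "five"] <- 1
  cm <- community_matrix(m)
  out <- suppressMessages(filter_rare_species(cm, min_sites = 2))
  expect_identical(colnames(out), c("two", "five"))
  expect_identical(attr(out, "n_removed"), 1L)
  expect_identical(nrow(out), nrow(cm))
  # min_sites = 1 is the identity
  expect_identical(colnames(filter_rare_species(cm, min_sites = 1)),
                   colnames(cm))
  # idempotence
  again <- filter_rare_species(out, min_sites = 2)
  expect_equal(unclass(again), unclass(out), ignore_attr = TRUE)
  expect_error(suppressMessages(filter_rare_species(cm, min_sites = 7)),
               "every species")
})

test_that("a 139-species fixture with 32 singletons retains 107", {
  set.seed(11)
  n_sites <- 20
  m <- matrix(0, n_sites, 139,
              dimnames = list(paste0("s", 1:n_sites), paste0("sp", 1:139)))
  for (k in 1:107) m[sample.int(n_sites, sample(2:8, 1)), k] <- 1
  for (k in 108:139) m[sample.int(n_sites, 1), k] <- 1
  out <- suppressMessages(filter_rare_species(community_matrix(m)))
  expect_identical(ncol(out), 107L)
  expect_identical(attr(out, "n_removed"), 32L)
})

test_that("richness_overlap matches brute-force set algebra", {
  m <- matrix(0, 9, 6, dimnames = list(paste0("s", 1:9), paste0("sp", 1:6)))
  memb <- list(sp1 = 1:9, sp2 = 1:3, sp3 = 4:6, sp4 = c(1, 5, 9),
               sp5 = 7:9, sp6 = c(2, 4))
  for (k in seq_along(memb)) m[memb[[k]], k] <- 1
  cm <- community_matrix(m)
  part <- metacommunity_partition(
    setNames(rep(c("M", "R", "D"), each = 3), rownames(m)))
  ro <- richness_overlap(cm, part)
  sets <- lapply(split(rownames(m), part), function(s)
    colnames(m)[colSums(m[s, , drop = FALSE]) > 0])
  expect_equal(ro$richness, vapply(sets, length, integer(1)))
  for (a in names(sets)) for (b in names(sets))
    expect_identical(ro$pairwise_shared[a, b],
                     length(intersect(sets[[a]], sets[[b]])))
  expect_identical(ro$shared_all, length(Reduce(intersect, sets)))

  # disjoint landscapes share nothing; identical ones share everything
  m2 <- rbind(diag(6)[rep(1:3, 2), ], diag(6)[rep(4:6, 2), ])
  rownames(m2) <- paste0("s", 1:12); colnames(m2) <- paste0("sp", 1:6)
  part2 <- metacommunity_partition(
    setNames(rep(c("A", "B"), each = 6), rownames(m2)))
  ro2 <- richness_overlap(community_matrix(m2), part2)
  expect_identical(ro2$pairwise_shared["A", "B"], 0L)
  m3 <- m2[c(1:6, 1:6), ]; rownames(m3) <- paste0("s", 1:12)
  ro3 <- richness_overlap(community_matrix(m3), part2)
  expect_identical(ro3$pairwise_shared["A", "B"], ro3$richness[["A"]])
})

test_that("haversine distances: fixed value, symmetry, oracle agreement", {
  d <- great_circle_distances(c(45, 46), c(87, 87))
  expect_equal(d[1, 2], 111.19, tolerance = 0.01 / 111.19)
  expect_identical(d[1, 1], 0)

  set.seed(21)
  lat <- runif(100, -89, 89); lon <- runif(100, -179, 179)
  D <- great_circle_distances(lat, lon)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # spherical law of cosines as an independent oracle (1000 pairs)
  i <- sample.int(100, 1000, replace = TRUE)
  j <- sample.int(100, 1000, replace = TRUE)
  expect_equal(D[cbind(i, j)], slc_distance(lat[i], lon[i], lat[j], lon[j]),
               tolerance = 1e-6)
  expect_error(great_circle_distances(91, 0), "latitude")
})

test_that("domain type invariants are enforced", {
  expect_error(community_matrix(matrix(1, 1, 2,
    dimnames = list("a", c("x", "y")))), "2 sites")
  expect_error(community_matrix(matrix(-1, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y")))), "non-negative")
  expect_error(community_matrix(matrix(1, 2, 2,
    dimnames = list(c("a", "a"), c("x", "y")))), "duplicate site")
  expect_error(environment_table(data.frame(a = c(1, 1, 1)),
                                 site_ids = c("s1", "s2", "s3")),
               "zero-variance")
  expect_error(metacommunity_partition(setNames(c("A", "A", "A", "B"),
                                                paste0("s", 1:4))),
               "fewer than 3")
  inc <- incidence(community_matrix(matrix(c(0, 3, 2, 0), 2, 2,
    dimnames = list(c("a", "b"), c("x", "y")))))
  expect_identical(sort(unique(as.vector(inc))), c(0, 1))
})
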