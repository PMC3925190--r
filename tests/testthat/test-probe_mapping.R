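# build a minimal pose at a location with a given energy
pose_at <- function(xyz, e_total, probe_id = "p", e_vdw = e_total, heavy = 3) {
  list(probe_id = probe_id, coords = matrix(xyz, 1, 3), centroid = xyz,
       energy = structure(list(e_vdw = e_vdw, e_elec = 0, e_solv = 0,
                               e_total = e_total, min_dist = 5),
                          class = "EnergyComponents"),
       heavy_atom_count = heavy)
}

# independent greedy leader-clustering oracle
leader_oracle <- function(centroids, energies, radius) {
  ord <- order(energies)
  seeds <- list(); assign <- integer(length(ord))
  for (i in ord) {
    hit <- 0
    for (k in seq_along(seeds)) {
      if (sqrt(sum((centroids[i, ] - seeds[[k]])^2)) <= radius) { hit <- k; break }
    }
    if (hit == 0) { seeds[[length(seeds) + 1]] <- centroids[i, ]; hit <- length(seeds) }
    assign[i] <- hit
  }
  assign
}

test_that("pose clustering follows greedy leader clustering exactly", {
  # separation much larger than the radius -> two hot spots
  poses <- list(pose_at(c(0, 0, 0), -5), pose_at(c(0.1, 0, 0), -4),
                pose_at(c(50, 0, 0), -3))
  hs <- cluster_poses(poses, cluster_radius = 3.5)
  expect_length(hs, 2)
  expect_equal(hs[[1]]$n_members + hs[[2]]$n_members, 3)
  # all identical -> one hot spot holding every pose
  same <- lapply(1:6, function(i) pose_at(c(1, 2, 3), -i))
  expect_length(cluster_poses(same, 3.5), 1)
  expect_equal(cluster_poses(same, 3.5)[[1]]$n_members, 6)
  # empty input
  expect_length(cluster_poses(list(), 3.5), 0)
  # random pose sets: partition identical to the oracle
  set.seed(91)
  for (rep in 1:10) {
    n <- 40
    cen <- matrix(runif(3 * n, 0, 25), ncol = 3)
    e <- runif(n, -8, -1)
    poses <- lapply(seq_len(n), function(i) pose_at(cen[i, ], e[i]))
    hs <- cluster_poses(poses, cluster_radius = 4)
    assign <- leader_oracle(cen, e, 4)
    expect_length(hs, max(assign))
    sizes_pkg <- sort(vapply(hs, function(h) h$n_members, 1L))
    expect_identical(sizes_pkg, sort(as.integer(table(assign))))
  }
  # every member pose lies within cluster_radius of its seed centroid
  set.seed(92)
  cen <- matrix(runif(90, 0, 15), ncol = 3)
  poses <- lapply(1:30, function(i) pose_at(cen[i, ], runif(1, -9, -1)))
  for (h in cluster_poses(poses, 3.5)) {
    for (p in h$member_poses)
      expect_lte(sqrt(sum((p$centroid - h$seed_centroid)^2)), 3.5 + 1e-9)
  }
})

test_that("L_e equals its one-expression definition", {
  # single probe: -6 kcal/mol over 6 heavy atoms -> -1.0
  h1 <- fake_hotspot("a", -6, 6)
  expect_equal(compute_le(h1), -1)
  # two probes (-6,6) and (-8,8) -> mean(-1, -1) = -1
  h2 <- fake_hotspot(c("a", "b"), c(-6, -8), c(6, 8))
  expect_equal(compute_le(h2), -1)
  # best (lowest) pose per probe enters the sum
  h3 <- fake_hotspot(c("a", "a", "b"), c(-2, -6, -8), c(6, 6, 8))
  expect_equal(compute_le(h3), mean(c(-1, -1)))
  # zero heavy atoms is an error
  expect_error(compute_le(fake_hotspot("a", -6, 0)), "zero heavy")
  # 100 randomized hot spots: exact agreement with the oracle
  set.seed(93)
  for (rep in 1:100) {
    k <- sample(1:6, 1)
    ids <- sample(letters[1:4], k, replace = TRUE)
    h <- fake_hotspot(ids, runif(k, -9, -0.5), sample(3:9, k, replace = TRUE))
    expect_identical(compute_le(h), le_oracle(h))
  }
})

test_that("L_e never improves when a probe's best pose weakens", {
  h <- fake_hotspot(c("a", "b", "c"), c(-6, -4, -9), c(6, 5, 9))
  base <- compute_le(h)
  worse <- fake_hotspot(c("a", "b", "c"), c(-3, -4, -9), c(6, 5, 9))
  expect_gte(compute_le(worse), base)
})

test_that("hot-spot ranking sorts by L_e with deterministic tie-breaks", {
  hs <- list(fake_hotspot("a", -1.2 * 5, 5),
             fake_hotspot("b", -0.5 * 4, 4),
             fake_hotspot(c("a", "b"), c(-2.0 * 3, -2.0 * 6), c(3, 6)))
  ranked <- rank_hotspots(hs)
  expect_equal(vapply(ranked, function(h) h$le_score, 1.0),
               sort(vapply(ranked, function(h) h$le_score, 1.0)))
  expect_equal(vapply(ranked, function(h) h$rank, 1L), 1:3)
  # permutation of input: nothing lost
  expect_setequal(vapply(ranked, function(h) h$best_e_total, 1.0),
                  vapply(hs, function(h) h$best_e_total, 1.0))
  # equal L_e: more distinct probes first
  t1 <- fake_hotspot(c("a", "b", "c"), rep(-4, 3), rep(4, 3))
  t2 <- fake_hotspot(c("a", "b", "c", "d", "e"), rep(-4, 5), rep(4, 5))
  ranked2 <- rank_hotspots(list(t1, t2))
  expect_length(ranked2[[1]]$distinct_probe_ids, 5)
})

test_that("pocket assembly matches a connected-components oracle", {
  mk_hs <- function(center) {
    h <- fake_hotspot(c("a", "b"), c(-6, -5), c(5, 5))
    h$centroid <- center
    for (i in seq_along(h$member_poses))
      h$member_poses[[i]]$coords <- matrix(center + rnorm(3, 0, 0.3), 1, 3)
    h
  }
  set.seed(94)
  conf <- random_conformer(20, spread = 12)
  # two nearby top hot spots -> one pocket
  hs <- rank_hotspots(list(mk_hs(c(0, 0, 0)), mk_hs(c(3, 0, 0))))
  pk <- identify_pockets(conf, hs, rank_fraction = 1, proximity_cutoff = 8)
  expect_length(pk, 1)
  expect_length(pk[[1]]$hotspot_ranks, 2)
  # all pairwise beyond the cutoff -> no pockets (a valid empty result)
  hs2 <- rank_hotspots(list(mk_hs(c(0, 0, 0)), mk_hs(c(20, 0, 0)),
                            mk_hs(c(0, 25, 0))))
  expect_length(identify_pockets(conf, hs2, rank_fraction = 1,
                                 proximity_cutoff = 8), 0)
  # planted three-cluster geometry vs brute-force components
  centers <- rbind(c(0, 0, 0), c(4, 0, 0), c(30, 0, 0), c(33, 0, 0),
                   c(60, 0, 0))
  hs3 <- rank_hotspots(lapply(seq_len(nrow(centers)),
                              function(i) mk_hs(centers[i, ])))
  pk3 <- identify_pockets(conf, hs3, rank_fraction = 1, proximity_cutoff = 8)
  adj <- as.matrix(dist(centers)) <= 8
  # brute-force components of size >= 2: {1,2} and {3,4}
  expect_length(pk3, 2)
  expect_true(all(vapply(pk3, function(p) length(p$hotspot_ranks), 1L) == 2))
  # ranking required first
  hs_unranked <- list(mk_hs(c(0, 0, 0)), mk_hs(c(3, 0, 0)))
  expect_error(identify_pockets(conf, hs_unranked), "ranked")
})

test_that("pocket count is non-increasing as rank_fraction decreases", {
  mk_hs <- function(center, le) {
    h <- fake_hotspot(c("a", "b"), c(le * 5, le * 5), c(5, 5))
    h$centroid <- center
    for (i in seq_along(h$member_poses))
      h$member_poses[[i]]$coords <- matrix(center, 1, 3)
    h
  }
  set.seed(95)
  conf <- random_conformer(15, spread = 10)
  centers <- rbind(c(0, 0, 0), c(3, 0, 0), c(20, 0, 0), c(23, 0, 0),
                   c(40, 0, 0), c(43, 0, 0), c(60, 0, 0), c(63, 0, 0))
  hs <- rank_hotspots(lapply(1:8, function(i) mk_hs(centers[i, ], -i)))
  counts <- vapply(c(1, 0.75, 0.5, 0.25), function(f)
    length(identify_pockets(conf, hs, rank_fraction = f,
                            proximity_cutoff = 8)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("lining residues and the long-range flag follow the geometry", {
  # chain along x; a pocket whose poses sit near residues 1-2 and 14-15
  xyz <- cbind(seq(0, by = 3.8, length.out = 15), 0, 0)
  conf <- assign_parameters(toy_conformer(xyz, residue_index = 1:15))
  h1 <- fake_hotspot(c("a", "b"), c(-6, -6), c(5, 5))
  h1$centroid <- c(1.9, 2, 0)
  h1$member_poses[[1]]$coords <- matrix(c(0, 2, 0), 1, 3)
  h1$member_poses[[2]]$coords <- matrix(c(53.2, 2, 0), 1, 3)
  h2 <- fake_hotspot(c("a", "c"), c(-5, -5), c(5, 5))
  h2$centroid <- c(5, 2, 0)
  h2$member_poses[[1]]$coords <- matrix(c(3.8, 2, 0), 1, 3)
  h2$member_poses[[2]]$coords <- matrix(c(7.6, 2, 0), 1, 3)
  hs <- rank_hotspots(list(h1, h2))
  pk <- identify_pockets(conf, hs, rank_fraction = 1, proximity_cutoff = 8,
                         lining_dist = 4.5, long_range_min = 12)
  expect_length(pk, 1)
  expect_true(all(c(1, 14, 15) %in% pk[[1]]$lining_residues))
  expect_gte(pk[[1]]$max_seq_separation, 12)
  expect_true(pk[[1]]$long_range_flag)
})

test_that("docking finds the global best under exhaustive enumeration", {
  # coarse settings so the candidate set is small enough to re-score in R
  set.seed(96)
  conf <- random_conformer(12, spread = 5)
  probes <- cached_probes()
  benz <- probes[[which(vapply(probes, `[[`, "", "ligand_id") == "benzene")]]
  centers <- idpscreen:::surface_grid(conf, spacing = 3.5, shell = c(1, 4))
  rots <- idpscreen:::with_local_seed(17, idpscreen:::random_rotations(4))
  ref <- sweep(benz$conformers[[1]], 2, colMeans(benz$conformers[[1]]))
  # independent R-side re-scoring of every candidate
  best <- Inf
  for (ci in seq_len(nrow(centers))) {
    for (R in rots) {
      xyz <- sweep(ref %*% t(R), 2, centers[ci, ], `+`)
      en <- score_pose(conf, xyz, benz$params)
      if (en$min_dist >= 2.0 && en$e_total < best) best <- en$e_total
    }
  }
  poses <- dock_probe(conf, benz, grid_spacing = 3.5, n_orientations = 4,
                      top_k = 1, seed = 17, minimize = FALSE)
  expect_equal(poses[[1]]$energy$e_total, best, tolerance = 1e-9)
})

test_that("a planted concave cavity binds probes better than a featureless convex surface", {
  probes <- cached_probes()
  benz <- probes[[which(vapply(probes, `[[`, "", "ligand_id") == "benzene")]]
  ens <- generate_disordered_ensemble(60, 1, seed = 5, plant_pocket = TRUE,
                                      cavity_radius = 4)
  planted <- assign_parameters(ens$conformers[[1]])
  # convex control: all-carbon atoms on a solid sphere surface
  set.seed(97)
  u <- matrix(rnorm(180), ncol = 3); u <- u / sqrt(rowSums(u^2))
  convex <- assign_parameters(toy_conformer(u * 8))
  p_planted <- dock_probe(planted, benz, grid_spacing = 2.5,
                          n_orientations = 8, top_k = 1, seed = 3)
  p_convex <- dock_probe(convex, benz, grid_spacing = 2.5,
                         n_orientations = 8, top_k = 1, seed = 3)
  expect_lt(p_planted[[1]]$energy$e_total, p_convex[[1]]$energy$e_total)
})

test_that("pocket export writes protein ATOM and probe HETATM records", {
  set.seed(98)
  conf <- random_conformer(10, spread = 6)
  h1 <- fake_hotspot(c("a", "b"), c(-6, -5), c(5, 5))
  h1$centroid <- c(0, 0, 0)
  h2 <- fake_hotspot(c("a", "c"), c(-5, -4), c(5, 5))
  h2$centroid <- c(3, 0, 0)
  hs <- rank_hotspots(list(h1, h2))
  pk <- identify_pockets(conf, hs, rank_fraction = 1, proximity_cutoff = 8)[[1]]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pocket_pdb(conf, hs, pk, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "ATOM")), 10)
  expect_equal(sum(startsWith(lines, "HETATM")),
               sum(vapply(hs[pk$hotspot_ranks], function(h) h$n_members, 1L)))
  # the file is parseable by the package's own reader
  back <- read_ensemble_pdb(path)
  expect_equal(nrow(back$conformers[[1]]$atoms), length(lines) - 1)
})
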