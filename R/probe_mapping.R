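#' The built-in fragment probe set
#'
#' Fifteen small solvent-mapping probes with diverse functional groups and
#' shapes (alcohols, carbonyls, amide, acid, amine, urea, nitrile, ether,
#' aromatic, apolar ring), shipped as an editable SMILES file.  Probes are
#' kept in their neutral forms (no pH protonation) so that the per-atom van
#' der Waals term that drives hot-spot scoring is not dominated by formal
#' charges.
#'
#' @param path SMILES file; defaults to the bundled 15-probe set.
#' @param seed seed for 3D embedding.
#' @param param_table nonbonded parameter table.
#' @return list of `Ligand` objects (see [read_library()]).
#' @export
load_probe_set <- function(path = system.file("extdata", "probes.smi",
                                              package = "idpscreen"),
                           seed = 1, param_table = default_parameter_table()) {
  read_library(path, seed = seed, n_confs = 1, protonate = FALSE,
               param_table = param_table)
}

# Grid of candidate placement centres in a shell just outside the protein
# surface.  offset = distance to the nearest atom centre minus that atom's
# vdW radius; points with offset in [shell[1], shell[2]] are kept.
surface_grid <- function(conf, spacing, shell = c(1, 4), box = NULL) {
  xyz <- coords_of(conf)
  rmin <- conf$atoms$rmin
  if (is.null(box)) {
    lo <- apply(xyz, 2, min) - shell[2] - 2
    hi <- apply(xyz, 2, max) + shell[2] + 2
  } else {
    lo <- box$lo; hi <- box$hi
  }
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  if (nrow(pts) == 0) return(pts)
  offset <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(xyz))) {
    d <- sqrt((pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
              (pts[, 3] - xyz[j, 3])^2) - rmin[j]
    offset <- pmin(offset, d)
  }
  pts[offset >= shell[1] & offset <= shell[2], , drop = FALSE]
}

#' Dock a fragment probe over a conformer surface
#'
#' Exhaustive rigid search over a surface-shell grid of placement centres
#' times uniformly sampled orientations times the probe's conformers, each
#' candidate scored with the shifted LJ + screened-Coulomb + burial force
#' field; the best candidates are then locally minimized (rigid body +
#' rotatable torsions) and the `top_k` lowest-energy non-clashing poses are
#' returned, sorted by ascending `e_total`.  Deterministic for a given
#' `seed`.
#'
#' @param conf a parameterized [Conformer].
#' @param probe a `Ligand` (see [load_probe_set()]).
#' @param grid_spacing grid step in Angstrom.
#' @param n_orientations rigid orientations sampled per grid point.
#' @param top_k poses to keep.
#' @param shell surface-offset band (Angstrom) for placement centres.
#' @param seed orientation-sampling seed.
#' @param minimize logical; locally minimize the short-listed candidates.
#' @param pre_k candidates short-listed for minimization.
#' @param box optional `list(lo=, hi=)` search box restriction.
#' @param cutoff,sigma_solv,probe_radius force-field settings.
#' @param clash_dist closest allowed protein-ligand approach.
#' @param min_steps iteration budget per pose minimization.
#' @return list of `ProbePose` lists (`probe_id`, `coords`, `centroid`,
#'   `energy`, `heavy_atom_count`); empty (with a warning) if no
#'   non-clashing pose exists.
#' @export
dock_probe <- function(conf, probe, grid_spacing = 2.0, n_orientations = 24,
                       top_k = 30, shell = c(1, 4), seed = 1,
                       minimize = TRUE, pre_k = top_k + 15, box = NULL,
                       cutoff = 9, sigma_solv = 0.025, probe_radius = 1.4,
                       clash_dist = 2.0, min_steps = 60) {
  check_parameterized(conf)
  stopifnot(inherits(probe, "Ligand"), grid_spacing > 0)
  centers <- surface_grid(conf, grid_spacing, shell, box)
  if (nrow(centers) == 0) {
    warning("no placement centres for probe ", probe$ligand_id)
    return(list())
  }
  rots <- with_local_seed(seed, random_rotations(n_orientations))
  rmat <- vapply(rots, function(R) as.numeric(t(R)), numeric(9))
  pxyz <- coords_of(conf)
  cand <- list()
  for (ci in seq_along(probe$conformers)) {
    ref <- probe$conformers[[ci]]
    ref <- sweep(ref, 2, colMeans(ref))
    sc <- rigid_scan_cpp(pxyz, conf$atoms$charge, conf$atoms$rmin,
                         conf$atoms$eps, ref, probe$params$charge,
                         probe$params$rmin, probe$params$eps, centers, rmat,
                         cutoff, sigma_solv, probe_radius, clash_dist)
    ok <- which(!is.na(sc[, 6]) & sc[, 7] >= clash_dist)
    if (length(ok) == 0) next
    cand[[length(cand) + 1]] <- data.frame(conf_idx = ci,
                                           center = sc[ok, 1],
                                           rot = sc[ok, 2],
                                           e_total = sc[ok, 6])
  }
  if (length(cand) == 0) {
    warning("no non-clashing pose for probe ", probe$ligand_id)
    return(list())
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$e_total), , drop = FALSE]
  cand <- utils::head(cand, if (minimize) pre_k else top_k)
  poses <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ref <- probe$conformers[[cand$conf_idx[i]]]
    ref <- sweep(ref, 2, colMeans(ref))
    R <- rots[[cand$rot[i]]]
    xyz <- sweep(ref %*% t(R), 2, centers[cand$center[i], ], `+`)
    if (minimize) {
      mres <- minimize_pose(conf, xyz, probe$params, probe$torsions,
                            max_steps = min_steps, tol = 1e-5,
                            cutoff = cutoff, sigma_solv = sigma_solv,
                            probe_radius = probe_radius,
                            clash_dist = clash_dist)
      if (mres$flagged) { poses[i] <- list(NULL); next }
      xyz <- mres$coords
      en <- mres$energy
    } else {
      en <- score_pose(conf, xyz, probe$params, cutoff, sigma_solv,
                       probe_radius)
    }
    poses[[i]] <- list(probe_id = probe$ligand_id, coords = xyz,
                       centroid = colMeans(xyz), energy = en,
                       heavy_atom_count = probe$heavy_atom_count)
  }
  poses <- Filter(Negate(is.null), poses)
  if (length(poses) == 0) {
    warning("all poses clashed for probe ", probe$ligand_id)
    return(list())
  }
  poses <- poses[order(vapply(poses, function(p) p$energy$e_total, 1.0))]
  utils::head(poses, top_k)
}

#' Cluster probe poses into hot spots
#'
#' Greedy leader clustering on pose centroids: poses are visited in order
#' of ascending `e_total`, the strongest pose seeds the first cluster, and
#' each pose joins the first existing cluster (in creation order) whose
#' seed centroid lies within `cluster_radius`, otherwise it seeds a new
#' one.  The hot-spot centroid is the energy-weighted mean of member
#' centroids (weight `max(-e_total, 1e-6)`).
#'
#' @param poses list of `ProbePose` objects from one conformer.
#' @param cluster_radius leader radius in Angstrom.
#' @return list of `HotSpot` lists (`centroid`, `member_poses`,
#'   `distinct_probe_ids`, `n_members`, `best_e_total`; `le_score` and
#'   `rank` are filled by [compute_le()] / [rank_hotspots()]).
#' @export
cluster_poses <- function(poses, cluster_radius = 3.5) {
  if (length(poses) == 0) return(list())
  et <- vapply(poses, function(p) p$energy$e_total, 1.0)
  poses <- poses[order(et)]
  seeds <- list()
  members <- list()
  for (p in poses) {
    placed <- FALSE
    for (k in seq_along(seeds)) {
      if (sqrt(sum((p$centroid - seeds[[k]])^2)) <= cluster_radius) {
        members[[k]] <- c(members[[k]], list(p))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds[[length(seeds) + 1]] <- p$centroid
      members[[length(members) + 1]] <- list(p)
    }
  }
  lapply(seq_along(seeds), function(k) {
    mem <- members[[k]]
    w <- vapply(mem, function(p) max(-p$energy$e_total, 1e-6), 1.0)
    cent <- colSums(do.call(rbind, lapply(mem, `[[`, "centroid")) * w) / sum(w)
    structure(list(
      centroid = cent,
      seed_centroid = seeds[[k]],
      member_poses = mem,
      distinct_probe_ids = sort(unique(vapply(mem, `[[`, "", "probe_id"))),
      n_members = length(mem),
      best_e_total = min(vapply(mem, function(p) p$energy$e_total, 1.0)),
      le_score = NA_real_, rank = NA_integer_
    ), class = "HotSpot")
  })
}

#' Potential ligand efficiency of a hot spot
#'
#' \deqn{L_e = \frac{\sum_p E^{(p)}_{vdW} / n^{(p)}_{heavy}}{N_{probes}}}
#' where the sum runs over the distinct probes binding the hot spot, each
#' contributing its best (lowest) member-pose van der Waals energy divided
#' by its heavy-atom count, and \eqn{N_{probes}} is the number of distinct
#' probes.  Only the van der Waals component enters; more negative is more
#' druggable.
#'
#' @param h a `HotSpot` from [cluster_poses()].
#' @return L_e in kcal/mol per heavy atom; also stored back when used via
#'   [rank_hotspots()].
#' @export
compute_le <- function(h) {
  stopifnot(inherits(h, "HotSpot"), length(h$member_poses) >= 1)
  by_probe <- split(h$member_poses,
                    vapply(h$member_poses, `[[`, "", "probe_id"))
  terms <- vapply(by_probe, function(mem) {
    ha <- mem[[1]]$heavy_atom_count
    if (ha == 0) stop("probe ", mem[[1]]$probe_id, " has zero heavy atoms")
    min(vapply(mem, function(p) p$energy$e_vdw, 1.0)) / ha
  }, 1.0)
  sum(terms) / length(terms)
}

#' Rank hot spots by ligand efficiency
#'
#' Ascending `le_score` (most negative first); ties broken by distinct
#' probe count (more first), then lexicographically by centroid so the
#' ordering is fully deterministic.
#'
#' @param hotspots list of `HotSpot` objects.
#' @return the same hot spots with `le_score` and `rank` filled, in rank
#'   order.
#' @export
rank_hotspots <- function(hotspots) {
  if (length(hotspots) == 0) return(hotspots)
  le <- vapply(hotspots, compute_le, 1.0)
  np <- vapply(hotspots, function(h) length(h$distinct_probe_ids), 1L)
  cen <- do.call(rbind, lapply(hotspots, `[[`, "centroid"))
  ord <- order(le, -np, cen[, 1], cen[, 2], cen[, 3])
  out <- hotspots[ord]
  for (i in seq_along(out)) {
    out[[i]]$le_score <- le[ord[i]]
    out[[i]]$rank <- i
  }
  out
}

#' Assemble high-ranking hot spots into binding pockets
#'
#' Restricts to the top `rank_fraction` of ranked hot spots, connects pairs
#' whose centroids are at most `proximity_cutoff` apart, and reports every
#' connected component with at least two hot spots as a pocket.  Lining
#' residues are those with a heavy atom within `lining_dist` of any member
#' pose atom; a pocket is flagged `long_range` when two lining residues are
#' at least `long_range_min` apart in sequence (a long-range tertiary
#' contact, i.e. a conformation-specific site).
#'
#' @param conf the parameterized [Conformer] the hot spots belong to.
#' @param hotspots ranked hot spots from [rank_hotspots()].
#' @param rank_fraction fraction (0-1] of top-ranked hot spots considered.
#' @param proximity_cutoff hot-spot adjacency distance in Angstrom.
#' @param lining_dist residue-lining distance in Angstrom.
#' @param long_range_min sequence separation defining a long-range contact.
#' @return list of `Pocket` lists (`pocket_id`, `model_id`,
#'   `hotspot_ranks`, `centroid`, `lining_residues`, `max_seq_separation`,
#'   `long_range_flag`, `bbox`).  Zero pockets is a valid result.
#' @export
identify_pockets <- function(conf, hotspots, rank_fraction = 0.25,
                             proximity_cutoff = 8, lining_dist = 4.5,
                             long_range_min = 12) {
  stopifnot(rank_fraction > 0, rank_fraction <= 1)
  if (length(hotspots) == 0) return(list())
  if (any(is.na(vapply(hotspots, function(h) h$rank, 1L))))
    stop("hot spots must be ranked first (rank_hotspots)")
  # floor of 2: a pocket is by definition two or more high-ranking hot
  # spots, so the "high-ranking" cut must never leave fewer than two
  # candidates when they exist
  m <- min(length(hotspots), max(2L, ceiling(rank_fraction * length(hotspots))))
  top <- hotspots[seq_len(m)]
  cen <- do.call(rbind, lapply(top, `[[`, "centroid"))
  adj <- as.matrix(stats::dist(cen)) <= proximity_cutoff
  comp <- connected_components(adj)
  pockets <- list()
  for (cc in comp) {
    if (length(cc) < 2) next
    mem <- top[cc]
    pose_xyz <- do.call(rbind, unlist(lapply(mem, function(h)
      lapply(h$member_poses, `[[`, "coords")), recursive = FALSE))
    lining <- lining_residues(conf, pose_xyz, lining_dist)
    maxsep <- if (length(lining) > 1) max(lining) - min(lining) else 0L
    # max over all pairs |i-j| equals range for a sorted index set
    pockets[[length(pockets) + 1]] <- structure(list(
      pocket_id = sprintf("m%d_p%d", conf$model_id, length(pockets) + 1L),
      model_id = conf$model_id,
      hotspot_ranks = vapply(mem, function(h) h$rank, 1L),
      centroid = colMeans(do.call(rbind, lapply(mem, `[[`, "centroid"))),
      lining_residues = lining,
      max_seq_separation = as.integer(maxsep),
      long_range_flag = maxsep >= long_range_min,
      bbox = list(lo = apply(pose_xyz, 2, min), hi = apply(pose_xyz, 2, max))
    ), class = "Pocket")
  }
  pockets
}

connected_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

lining_residues <- function(conf, pose_xyz, lining_dist) {
  a <- conf$atoms[conf$atoms$is_heavy, , drop = FALSE]
  axyz <- as.matrix(a[, c("x", "y", "z")])
  near <- rep(FALSE, nrow(axyz))
  for (i in seq_len(nrow(pose_xyz))) {
    d2 <- (axyz[, 1] - pose_xyz[i, 1])^2 + (axyz[, 2] - pose_xyz[i, 2])^2 +
          (axyz[, 3] - pose_xyz[i, 3])^2
    near <- near | d2 <= lining_dist^2
  }
  sort(unique(a$residue_index[near]))
}

#' Map fragment probes over one conformer
#'
#' Runs [dock_probe()] for every probe, pools the poses, clusters them into
#' hot spots and ranks those by L_e.  Clusters visited by fewer than
#' `min_probes` distinct probes are not promoted to hot spots: a hot spot
#' is by definition a locus where *different* probes bind, and
#' single-probe clusters carry un-averaged, systematically optimistic L_e
#' values.
#'
#' @param conf a parameterized [Conformer].
#' @param probes list of `Ligand` probes (default: bundled set).
#' @param cluster_radius hot-spot leader radius.
#' @param seed base seed; each probe gets a derived seed.
#' @param min_probes minimum distinct probes per hot spot.
#' @param ... passed to [dock_probe()].
#' @return list with `poses` (all kept poses) and `hotspots` (ranked).
#' @export
map_conformer <- function(conf, probes = load_probe_set(),
                          cluster_radius = 3.5, seed = 1, min_probes = 2,
                          ...) {
  poses <- list()
  for (i in seq_along(probes)) {
    poses <- c(poses, dock_probe(conf, probes[[i]],
                                 seed = derive_seed(seed, probes[[i]]$ligand_id),
                                 ...))
  }
  cl <- cluster_poses(poses, cluster_radius)
  cl <- Filter(function(h) length(h$distinct_probe_ids) >= min_probes, cl)
  list(poses = poses, hotspots = rank_hotspots(cl))
}

#' Export a pocket and its probe poses as a PDB file
#'
#' Protein atoms are written as ATOM records, member probe-pose atoms as
#' HETATM records (residue name PRB), for visual inspection.
#'
#' @param conf the pocket's [Conformer].
#' @param hotspots ranked hot spots (as used for [identify_pockets()]).
#' @param pocket a `Pocket`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(conf, hotspots, pocket, path) {
  lines <- character(0)
  a <- conf$atoms
  nm <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name)
  lines <- c(lines, sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), substr(nm, 1, 4), substr(a$residue_name, 1, 3),
    a$chain_id, a$residue_index, a$x, a$y, a$z, 1, 0, substr(a$element, 1, 2)))
  serial <- nrow(a)
  for (r in pocket$hotspot_ranks) {
    h <- hotspots[[r]]
    for (p in h$member_poses) {
      for (i in seq_len(nrow(p$coords))) {
        serial <- serial + 1
        lines <- c(lines, sprintf(
          "HETATM%5d %-4s PRB X%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, " C", r, p$coords[i, 1], p$coords[i, 2],
          p$coords[i, 3], 1, 0, " C"))
      }
    }
  }
  atomic_write_lines(c(lines, "END"), path)
  invisible(path)
}
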