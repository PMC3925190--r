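#' Radius of gyration of a conformer
#'
#' \deqn{R_g = \sqrt{\sum_i w_i |r_i - \bar r|^2 / \sum_i w_i}} with
#' \eqn{\bar r} the (weighted) centroid.  Defaults to heavy atoms with
#' uniform weights, since NMR ensembles vary in protonation; set
#' `mass_weighted = TRUE` for atomic-mass weights.
#'
#' @param conf a [Conformer].
#' @param mass_weighted logical; weight atoms by atomic mass.
#' @param heavy_only logical; restrict to heavy atoms.
#' @return Rg in Angstrom.
#' @export
compute_rg <- function(conf, mass_weighted = FALSE, heavy_only = TRUE) {
  stopifnot(inherits(conf, "Conformer"))
  a <- conf$atoms
  if (heavy_only && any(a$is_heavy)) a <- a[a$is_heavy, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms for Rg computation")
  w <- if (mass_weighted) atomic_mass(a$element) else rep(1, nrow(a))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

# monoisotopic-ish average masses for weighting and MW checks
atomic_mass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974, F = 18.998, CL = 35.45, BR = 79.904)
  out <- m[toupper(element)]
  if (anyNA(out)) stop("no atomic mass for element(s): ",
                       paste(unique(element[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` deterministic golden-spiral points on each atom's
#' probe-inflated sphere and counts the fraction not occluded by any
#' neighbour.  Atom radii are the `rmin` parameters, so the conformer must
#' be parameterized first.
#'
#' @param conf a parameterized [Conformer].
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom (>= 92; accuracy ~2\% at
#'   960).
#' @return list with `per_atom` (Angstrom^2 per atom) and `total`.
#' @export
compute_sasa <- function(conf, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(conf, "Conformer"), probe_radius >= 0, n_points >= 92)
  if (is.null(conf$atoms$rmin) || anyNA(conf$atoms$rmin))
    stop("conformer has no radii; run assign_parameters() first")
  xyz <- coords_of(conf)
  per <- sasa_cpp(xyz, conf$atoms$rmin, probe_radius, as.integer(n_points),
                  seq_len(nrow(xyz)))
  list(per_atom = per, total = sum(per))
}

#' Count non-bonded heavy-atom contacts
#'
#' A contact is a heavy-atom pair at most `cutoff` apart whose residues are
#' at least `min_seq_sep` positions apart in sequence (so bonded and
#' near-neighbour pairs never count).  Implemented with a spatial hash;
#' exactly equivalent to the brute-force double loop.
#'
#' @param conf a [Conformer].
#' @param cutoff distance cutoff in Angstrom.
#' @param min_seq_sep minimum residue separation.
#' @return integer contact count.
#' @export
count_nonbonded_contacts <- function(conf, cutoff = 5.4, min_seq_sep = 3) {
  stopifnot(inherits(conf, "Conformer"), cutoff > 0, min_seq_sep >= 0)
  contact_count_cpp(coords_of(conf), as.integer(conf$atoms$residue_index),
                    conf$atoms$is_heavy, cutoff, as.integer(min_seq_sep))
}

#' Summarize every conformer of an ensemble
#'
#' @param ens a parameterized [EnsembleSet].
#' @param probe_radius,n_points passed to [compute_sasa()].
#' @param cutoff,min_seq_sep passed to [count_nonbonded_contacts()].
#' @return data frame with columns `model_id`, `rg`, `sasa`, `n_contacts`.
#' @export
summarize_ensemble <- function(ens, probe_radius = 1.4, n_points = 960,
                               cutoff = 5.4, min_seq_sep = 3) {
  stopifnot(inherits(ens, "EnsembleSet"))
  rows <- lapply(ens$conformers, function(cf) {
    data.frame(model_id = cf$model_id,
               rg = compute_rg(cf),
               sasa = compute_sasa(cf, probe_radius, n_points)$total,
               n_contacts = count_nonbonded_contacts(cf, cutoff, min_seq_sep))
  })
  do.call(rbind, rows)
}

#' Superposition-free distance between two conformers
#'
#' Distance-matrix RMSD over C-alpha atoms: the root-mean-square difference
#' of all intramolecular CA-CA distances.  Chosen over superposed RMSD
#' because optimal superposition is ill-conditioned for disordered chains.
#'
#' @param a,b [Conformer]s with identical atom ordering.
#' @return distance in Angstrom; zero iff the internal distance matrices
#'   agree.
#' @export
conformer_distance <- function(a, b) {
  stopifnot(inherits(a, "Conformer"), inherits(b, "Conformer"))
  if (nrow(a$atoms) != nrow(b$atoms) ||
      !identical(a$atoms$atom_name, b$atoms$atom_name))
    stop("conformers have mismatched atom ordering")
  ca_a <- ca_coords(a); ca_b <- ca_coords(b)
  da <- as.matrix(stats::dist(ca_a)); db <- as.matrix(stats::dist(ca_b))
  lt <- lower.tri(da)
  sqrt(mean((da[lt] - db[lt])^2))
}

ca_coords <- function(conf) {
  sel <- conf$atoms$atom_name == "CA"
  if (!any(sel)) sel <- conf$atoms$is_heavy  # no CA (small molecules): all heavy
  as.matrix(conf$atoms[sel, c("x", "y", "z")])
}

#' Pairwise conformer distance matrix
#' @param ens an [EnsembleSet].
#' @return symmetric matrix with dimnames = model ids.
#' @export
conformer_distance_matrix <- function(ens) {
  n <- length(ens$conformers)
  ids <- vapply(ens$conformers, function(cf) cf$model_id, 1L)
  cas <- lapply(ens$conformers, ca_coords)
  dms <- lapply(cas, function(m) {
    dd <- as.matrix(stats::dist(m)); dd[lower.tri(dd)]
  })
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- sqrt(mean((dms[[i]] - dms[[j]])^2))
  }
  out
}

#' Select a diverse, compactness-biased conformer subset
#'
#' Greedy weighted max-min diversity selection.  Each conformer carries a
#' compactness weight \eqn{w_i = \exp(-\beta (Rg_i - Rg_{min}) /
#' (Rg_{max} - Rg_{min}))} with \eqn{\beta} = `bias_strength`; the first
#' pick is sampled with probability proportional to \eqn{w} (seeded), and
#' each subsequent pick maximizes `w_i * min(dist to already selected)`.
#' With `bias_strength = 0` this is plain greedy max-min diversity; larger
#' values trade diversity for compactness.
#'
#' @param summaries data frame from [summarize_ensemble()] (needs
#'   `model_id`, `rg`).
#' @param dist symmetric pairwise distance matrix in `summaries` row order.
#' @param k number of conformers to select.
#' @param bias_strength non-negative compactness bias (dimensionless).
#' @param seed integer seed for the initial pick.
#' @return list of class `SelectionResult`: `selected_ids`, `pool_mean_rg`,
#'   `selected_mean_rg`, `diversity_score` (mean pairwise distance among
#'   selected).
#' @export
select_diverse_compact <- function(summaries, dist, k, bias_strength = 1,
                                   seed = 1) {
  n <- nrow(summaries)
  if (k > n) stop("k (", k, ") exceeds pool size (", n, ")")
  stopifnot(k >= 1, bias_strength >= 0, nrow(dist) == n, ncol(dist) == n)
  rg <- summaries$rg
  span <- max(rg) - min(rg)
  w <- if (span > 0) exp(-bias_strength * (rg - min(rg)) / span) else rep(1, n)
  sel <- integer(0)
  if (k == n) {
    sel <- seq_len(n)
  } else {
    first <- with_local_seed(seed, sample.int(n, 1, prob = w))
    sel <- first
    while (length(sel) < k) {
      cand <- setdiff(seq_len(n), sel)
      gain <- w[cand] * apply(dist[cand, sel, drop = FALSE], 1, min)
      best <- cand[order(-gain, summaries$model_id[cand])[1]]
      sel <- c(sel, best)
    }
  }
  dsel <- dist[sel, sel, drop = FALSE]
  structure(list(
    selected_ids = summaries$model_id[sel],
    pool_mean_rg = mean(rg),
    selected_mean_rg = mean(rg[sel]),
    diversity_score = if (length(sel) > 1) mean(dsel[lower.tri(dsel)]) else 0
  ), class = "SelectionResult")
}

#' Seeded uniform subsample of an ensemble
#'
#' The precursor step to characterization: draw `n` members uniformly at
#' random (without replacement) from a larger ensemble.
#'
#' @param ens an [EnsembleSet].
#' @param n subsample size.
#' @param seed integer seed.
#' @return an [EnsembleSet] of size `n`.
#' @export
subsample_ensemble <- function(ens, n, seed = 1) {
  stopifnot(inherits(ens, "EnsembleSet"), n >= 1)
  if (n > length(ens$conformers))
    stop("subsample size exceeds ensemble size")
  idx <- with_local_seed(seed, sort(sample.int(length(ens$conformers), n)))
  new_ensemble_set(ens$conformers[idx])
}

# run expr under a local RNG state so callers' RNG stream is untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
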