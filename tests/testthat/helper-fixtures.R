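# In-code fixtures shared across the test files.  No binary data: every
# structure and molecule is built programmatically under a fixed seed.

# average atomic masses for the independent molecular-weight oracle
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, F = 18.998, CL = 35.45, BR = 79.904)

# independent MW summation over a Ligand's atom list (heavy + hydrogens)
mw_oracle <- function(lig) {
  sum(ATOMIC_MASS[toupper(lig$params$element)]) +
    lig$n_hydrogens * ATOMIC_MASS[["H"]]
}

# a bare conformer from a coordinate matrix; all-carbon unless elements given
toy_conformer <- function(xyz, elements = NULL, model_id = 1,
                          residue_index = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(elements)) elements <- rep("C", n)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  new_conformer(model_id, data.frame(
    atom_name = sprintf("C%d", seq_len(n)),
    element = elements,
    residue_index = as.integer(residue_index),
    residue_name = "LIG",
    chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# parameterized random all-carbon conformer (one atom per residue)
random_conformer <- function(n, spread = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- toy_conformer(matrix(runif(3 * n, -spread, spread), ncol = 3))
  assign_parameters(cf)
}

# a minimal ligand-like parameter table for hand-built poses
lig_params <- function(n, element = "C", charge = 0) {
  tab <- default_parameter_table()$elements[[element]]
  data.frame(element = rep(element, n), charge = rep(charge, length.out = n),
             rmin = tab$rmin, eps = tab$eps)
}

# hand-built multi-model PDB text (3 models x 2 residues x 2 atoms)
toy_pdb_lines <- function(n_models = 3) {
  set.seed(42)
  out <- character(0)
  for (m in seq_len(n_models)) {
    out <- c(out, sprintf("MODEL     %4d", m))
    xyz <- matrix(round(runif(12, -20, 20), 3), ncol = 3)
    for (i in 1:4) {
      out <- c(out, sprintf(
        "ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, c("CA", "CB")[(i %% 2) + 1], " ", "ALA", "A", (i + 1) %/% 2,
        xyz[i, 1], xyz[i, 2], xyz[i, 3], c("C", "O")[(i %% 2) + 1]))
    }
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

# brute-force contact count oracle: O(n^2) double loop
contacts_brute <- function(conf, cutoff = 5.4, min_seq_sep = 3) {
  a <- conf$atoms[conf$atoms$is_heavy, ]
  n <- nrow(a)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(a$residue_index[i] - a$residue_index[j]) < min_seq_sep) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# synthetic HotSpot builder for the L_e oracle tests (poses need only
# probe_id, e_vdw and heavy_atom_count)
fake_hotspot <- function(probe_ids, e_vdw, heavy) {
  poses <- lapply(seq_along(probe_ids), function(i) {
    list(probe_id = probe_ids[i],
         coords = matrix(0, 1, 3), centroid = c(0, 0, 0),
         energy = structure(list(e_vdw = e_vdw[i], e_elec = 0, e_solv = 0,
                                 e_total = e_vdw[i], min_dist = 5),
                            class = "EnergyComponents"),
         heavy_atom_count = heavy[i])
  })
  structure(list(centroid = c(0, 0, 0), seed_centroid = c(0, 0, 0),
                 member_poses = poses,
                 distinct_probe_ids = sort(unique(probe_ids)),
                 n_members = length(poses),
                 best_e_total = min(e_vdw),
                 le_score = NA_real_, rank = NA_integer_),
            class = "HotSpot")
}

# one-expression L_e oracle, straight from the definition: sum over
# distinct probes of best-E_vdW/heavy-atoms, divided by the probe count
# (probes taken in sorted order so floating-point summation order is fixed)
le_oracle <- function(h) {
  ids <- vapply(h$member_poses, `[[`, "", "probe_id")
  v <- vapply(h$member_poses, function(p) p$energy$e_vdw, 1.0)
  ha <- vapply(h$member_poses, `[[`, 1L, "heavy_atom_count")
  uid <- sort(unique(ids))
  sum(vapply(uid, function(id) {
    k <- which(ids == id)
    min(v[k]) / ha[k][1]
  }, 1.0)) / length(uid)
}

# probe set and shared planted fixture are expensive (python + docking);
# cache them for the whole test run
probe_cache <- new.env()
cached_probes <- function() {
  if (is.null(probe_cache$probes))
    probe_cache$probes <- load_probe_set(seed = 1)
  probe_cache$probes
}
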