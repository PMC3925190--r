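#' Nonbonded interaction energy of a ligand pose against a rigid protein
#'
#' Three additive components, all in kcal/mol:
#' \itemize{
#'   \item `e_vdw`: 12-6 Lennard-Jones,
#'     \eqn{\epsilon_{ij}[(r^{min}_{ij}/r)^{12} - 2 (r^{min}_{ij}/r)^6]}
#'     with \eqn{r^{min}_{ij} = rmin_i + rmin_j} and
#'     \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}, shifted to zero
#'     at the cutoff;
#'   \item `e_elec`: Coulomb with distance-dependent dielectric
#'     \eqn{\epsilon(r) = 4r}, i.e. \eqn{332.06\, q_i q_j / (4 r^2)},
#'     likewise shifted;
#'   \item `e_solv`: the surface-area solvation change on binding,
#'     `sigma_solv * (ligand SASA bound - ligand SASA free)`, i.e. minus
#'     `sigma_solv` times the ligand surface buried by the protein (burial
#'     is stabilizing, as in gamma-SASA implicit-solvent models).  The
#'     buried area is computed analytically from pairwise sphere overlaps,
#'     which -- unlike sampled SASA -- is exactly rotation invariant.
#' }
#' `e_total` is their exact sum.  Interactions beyond `cutoff` contribute
#' nothing.
#'
#' @param protein a parameterized [Conformer].
#' @param lig_xyz n x 3 matrix of ligand atom coordinates (Angstrom).
#' @param lig_params data frame with per-atom `charge`, `rmin`, `eps`.
#' @param cutoff pair cutoff in Angstrom.
#' @param sigma_solv desolvation coefficient, kcal/mol/Angstrom^2.
#' @param probe_radius solvent probe used for the burial term.
#' @return list of class `EnergyComponents` with `e_vdw`, `e_elec`,
#'   `e_solv`, `e_total`, `min_dist` (closest protein-ligand approach).
#' @export
score_pose <- function(protein, lig_xyz, lig_params, cutoff = 9,
                       sigma_solv = 0.025, probe_radius = 1.4) {
  check_parameterized(protein)
  lig_xyz <- as.matrix(lig_xyz)
  stopifnot(ncol(lig_xyz) == 3, nrow(lig_xyz) == nrow(lig_params))
  if (anyNA(lig_params$rmin) || anyNA(lig_params$eps) || anyNA(lig_params$charge))
    stop("ligand atoms are not fully parameterized")
  v <- energy_components_cpp(
    coords_of(protein), protein$atoms$charge, protein$atoms$rmin,
    protein$atoms$eps, lig_xyz, lig_params$charge, lig_params$rmin,
    lig_params$eps, cutoff, sigma_solv, probe_radius)
  if (v[["min_dist"]] == 0) stop("protein-ligand pair at zero distance")
  structure(as.list(v), class = "EnergyComponents")
}

check_parameterized <- function(conf) {
  stopifnot(inherits(conf, "Conformer"))
  a <- conf$atoms
  if (is.null(a$rmin) || anyNA(a$rmin) || anyNA(a$eps) || anyNA(a$charge))
    stop("protein conformer is not parameterized; run assign_parameters()")
  invisible(conf)
}

#' @export
print.EnergyComponents <- function(x, ...) {
  cat(sprintf("E_vdw %.4f  E_elec %.4f  E_solv %.4f  E_total %.4f kcal/mol\n",
              x$e_vdw, x$e_elec, x$e_solv, x$e_total))
  invisible(x)
}

# rotation matrix from a rotation vector (axis * angle, Rodrigues)
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# uniform random rotation matrices (Shoemake quaternions), n of them
random_rotations <- function(n) {
  u <- matrix(runif(3 * n), ncol = 3)
  q <- cbind(sqrt(1 - u[, 1]) * sin(2 * pi * u[, 2]),
             sqrt(1 - u[, 1]) * cos(2 * pi * u[, 2]),
             sqrt(u[, 1]) * sin(2 * pi * u[, 3]),
             sqrt(u[, 1]) * cos(2 * pi * u[, 3]))
  lapply(seq_len(n), function(i) quat_to_matrix(q[i, ]))
}

quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotate `moving` atom subset of xyz around the bond axis from atom i to j
apply_torsion <- function(xyz, axis, moving, angle) {
  if (abs(angle) < 1e-12) return(xyz)
  a <- xyz[axis[1], ]; b <- xyz[axis[2], ]
  u <- b - a
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) return(xyz)
  R <- rotvec_to_matrix(u / nu * angle)
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, b) %*% t(R),
                         2, b, `+`)
  xyz
}

# build pose coordinates from a parameter vector:
# par = (tx,ty,tz, rx,ry,rz, torsion angles...)
pose_coords <- function(par, ref_xyz, ref_centroid, torsions) {
  nt <- length(torsions)
  xyz <- ref_xyz
  if (nt > 0) {
    for (t in seq_len(nt))
      xyz <- apply_torsion(xyz, torsions[[t]]$axis, torsions[[t]]$moving,
                           par[6 + t])
  }
  R <- rotvec_to_matrix(par[4:6])
  sweep(sweep(xyz, 2, ref_centroid) %*% t(R), 2,
        ref_centroid + par[1:3], `+`)
}

#' Locally minimize a ligand pose against a rigid protein
#'
#' Optimizes rigid-body translation and rotation of the ligand plus its
#' rotatable-bond torsions (bond lengths and angles stay fixed), using
#' quasi-Newton (BFGS) descent on `e_total`.  The protein never moves.  The
#' returned energy is never above the starting energy: if the optimizer
#' fails to improve, the input pose is returned unchanged.
#'
#' @param protein a parameterized [Conformer].
#' @param lig_xyz starting ligand coordinates (n x 3).
#' @param lig_params per-atom `charge`, `rmin`, `eps` data frame.
#' @param torsions list of rotatable torsions, each
#'   `list(axis = c(i, j), moving = <atom indices>)`; `NULL` for rigid.
#' @param max_steps iteration budget.
#' @param tol relative convergence tolerance on the energy.
#' @param cutoff,sigma_solv,probe_radius passed to [score_pose()].
#' @param clash_dist poses whose closest approach stays below this after
#'   minimization are flagged (`flagged = TRUE`), not errored.
#' @return list with `coords`, `energy` ([score_pose()] result), `start_energy`,
#'   `converged`, `flagged`.
#' @export
minimize_pose <- function(protein, lig_xyz, lig_params, torsions = NULL,
                          max_steps = 200, tol = 1e-6, cutoff = 9,
                          sigma_solv = 0.025, probe_radius = 1.4,
                          clash_dist = 2.0) {
  check_parameterized(protein)
  lig_xyz <- as.matrix(lig_xyz)
  if (is.null(torsions)) torsions <- list()
  ctr <- colMeans(lig_xyz)
  pxyz <- coords_of(protein)
  pq <- protein$atoms$charge; prmin <- protein$atoms$rmin
  peps <- protein$atoms$eps
  lq <- lig_params$charge; lrmin <- lig_params$rmin; leps <- lig_params$eps
  efun <- function(par) {
    xyz <- pose_coords(par, lig_xyz, ctr, torsions)
    v <- energy_components_cpp(pxyz, pq, prmin, peps, xyz, lq, lrmin, leps,
                               cutoff, sigma_solv, probe_radius)
    e <- v[["e_total"]]
    if (!is.finite(e)) 1e9 else min(e, 1e9)
  }
  par0 <- rep(0, 6 + length(torsions))
  e0 <- efun(par0)
  fit <- tryCatch(
    stats::optim(par0, efun, method = "BFGS",
                 control = list(maxit = max_steps, reltol = tol)),
    error = function(e) list(par = par0, value = e0, convergence = 1L))
  use_fit <- is.finite(fit$value) && fit$value <= e0
  par <- if (use_fit) fit$par else par0
  xyz <- pose_coords(par, lig_xyz, ctr, torsions)
  en <- score_pose(protein, xyz, lig_params, cutoff, sigma_solv, probe_radius)
  start_en <- score_pose(protein, lig_xyz, lig_params, cutoff, sigma_solv,
                         probe_radius)
  list(coords = xyz, energy = en, start_energy = start_en,
       converged = use_fit && fit$convergence == 0L,
       flagged = en$min_dist < clash_dist || en$e_total >= 1e9)
}
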