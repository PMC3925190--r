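#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

static const double COULOMB = 332.06;   // kcal*Angstrom/(mol*e^2)
static const double PI = 3.14159265358979323846;

// Deterministic golden-spiral points on the unit sphere.
static std::vector<double> sphere_points(int n) {
  std::vector<double> pts(3 * n);
  const double ga = PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    pts[3 * k] = r * std::cos(phi);
    pts[3 * k + 1] = r * std::sin(phi);
    pts[3 * k + 2] = z;
  }
  return pts;
}

// Shrake-Rupley SASA for a subset of atoms (1-based indices into xyz).
// radii are per-atom van der Waals radii; probe is the solvent radius.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points, IntegerVector subset) {
  int n = xyz.nrow();
  std::vector<double> pts = sphere_points(n_points);
  NumericVector out(subset.size());
  for (int s = 0; s < subset.size(); ++s) {
    int i = subset[s] - 1;
    double ri = radii[i] + probe;
    // neighbours that can occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rj = radii[j] + probe;
      if (d2 < (ri + rj) * (ri + rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xyz(i, 0) + ri * pts[3 * k];
      double py = xyz(i, 1) + ri * pts[3 * k + 1];
      double pz = xyz(i, 2) + ri * pts[3 * k + 2];
      bool exposed = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { exposed = false; break; }
      }
      if (exposed) ++acc;
    }
    out[s] = 4.0 * PI * ri * ri * acc / double(n_points);
  }
  return out;
}

// Analytic pairwise-overlap burial of ligand SASA spheres by protein atoms.
// Rotation invariant by construction (used for the desolvation term).
static double buried_area(const NumericMatrix &pxyz, const NumericVector &prmin,
                          const double *lx, const NumericVector &lrmin,
                          int nl, double probe) {
  int np = pxyz.nrow();
  double total = 0.0;
  for (int i = 0; i < nl; ++i) {
    double Ri = lrmin[i] + probe;
    double full = 4.0 * PI * Ri * Ri;
    double sum = 0.0;
    for (int j = 0; j < np; ++j) {
      double Rj = prmin[j] + probe;
      double dx = lx[3 * i] - pxyz(j, 0), dy = lx[3 * i + 1] - pxyz(j, 1),
             dz = lx[3 * i + 2] - pxyz(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d >= Ri + Rj) continue;
      if (d + Ri <= Rj) { sum = full; break; }
      double h = Ri - (d * d + Ri * Ri - Rj * Rj) / (2.0 * d);
      if (h < 0.0) h = 0.0;
      if (h > 2.0 * Ri) h = 2.0 * Ri;
      sum += 2.0 * PI * Ri * h;
      if (sum >= full) { sum = full; break; }
    }
    total += std::min(sum, full);
  }
  return total;
}

// Protein-ligand interaction energy: shifted 12-6 Lennard-Jones +
// distance-dependent-dielectric Coulomb (eps(r) = 4r) + pairwise-overlap
// desolvation.  Returns c(e_vdw, e_elec, e_solv, e_total, min_dist).
static void pair_terms(const NumericMatrix &pxyz, const NumericVector &pq,
                       const NumericVector &prmin, const NumericVector &peps,
                       const double *lx, const NumericVector &lq,
                       const NumericVector &lrmin, const NumericVector &leps,
                       int nl, double cutoff, double *evdw, double *eelec,
                       double *mind) {
  int np = pxyz.nrow();
  double rc2 = cutoff * cutoff;
  double v = 0.0, e = 0.0, md2 = 1e30;
  for (int i = 0; i < nl; ++i) {
    for (int j = 0; j < np; ++j) {
      double dx = lx[3 * i] - pxyz(j, 0), dy = lx[3 * i + 1] - pxyz(j, 1),
             dz = lx[3 * i + 2] - pxyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < md2) md2 = d2;
      if (d2 >= rc2 || d2 <= 0.0) continue;
      double rm = lrmin[i] + prmin[j];
      double epsij = std::sqrt(leps[i] * peps[j]);
      double s6 = std::pow(rm * rm / d2, 3.0);
      double s6c = std::pow(rm / cutoff, 6.0);
      v += epsij * (s6 * s6 - 2.0 * s6) - epsij * (s6c * s6c - 2.0 * s6c);
      double qq = lq[i] * pq[j];
      if (qq != 0.0) {
        e += COULOMB * qq / (4.0 * d2) - COULOMB * qq / (4.0 * rc2);
      }
    }
  }
  *evdw = v;
  *eelec = e;
  *mind = std::sqrt(md2);
}

// [[Rcpp::export]]
NumericVector energy_components_cpp(NumericMatrix pxyz, NumericVector pq,
                                    NumericVector prmin, NumericVector peps,
                                    NumericMatrix lxyz, NumericVector lq,
                                    NumericVector lrmin, NumericVector leps,
                                    double cutoff, double sigma_solv,
                                    double probe) {
  int nl = lxyz.nrow();
  std::vector<double> lx(3 * nl);
  for (int i = 0; i < nl; ++i) {
    lx[3 * i] = lxyz(i, 0); lx[3 * i + 1] = lxyz(i, 1); lx[3 * i + 2] = lxyz(i, 2);
  }
  double evdw, eelec, mind;
  pair_terms(pxyz, pq, prmin, peps, lx.data(), lq, lrmin, leps, nl, cutoff,
             &evdw, &eelec, &mind);
  double esolv = 0.0;
  if (sigma_solv != 0.0)
    esolv = -sigma_solv * buried_area(pxyz, prmin, lx.data(), lrmin, nl, probe);
  NumericVector out = NumericVector::create(evdw, eelec, esolv,
                                            evdw + eelec + esolv, mind);
  out.names() = CharacterVector::create("e_vdw", "e_elec", "e_solv",
                                        "e_total", "min_dist");
  return out;
}

// Exhaustive rigid scan: for every placement centre x every rotation,
// place the (pre-centred) ligand and score it.  rots is 9 x m, each column
// a row-major 3x3 rotation matrix.  Returns (n*m) x 7:
// centre index, rotation index, e_vdw, e_elec, e_solv, e_total, min_dist.
// Rows with min_dist < clash_skip are returned with NA energies (cheap skip).
// [[Rcpp::export]]
NumericMatrix rigid_scan_cpp(NumericMatrix pxyz, NumericVector pq,
                             NumericVector prmin, NumericVector peps,
                             NumericMatrix ligref, NumericVector lq,
                             NumericVector lrmin, NumericVector leps,
                             NumericMatrix centers, NumericMatrix rots,
                             double cutoff, double sigma_solv, double probe,
                             double clash_skip) {
  int nl = ligref.nrow(), nc = centers.nrow(), nr = rots.ncol();
  NumericMatrix out(nc * nr, 7);
  std::vector<double> lx(3 * nl);
  int row = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r, ++row) {
      for (int i = 0; i < nl; ++i) {
        double x = ligref(i, 0), y = ligref(i, 1), z = ligref(i, 2);
        lx[3 * i]     = rots(0, r) * x + rots(1, r) * y + rots(2, r) * z + centers(c, 0);
        lx[3 * i + 1] = rots(3, r) * x + rots(4, r) * y + rots(5, r) * z + centers(c, 1);
        lx[3 * i + 2] = rots(6, r) * x + rots(7, r) * y + rots(8, r) * z + centers(c, 2);
      }
      double evdw, eelec, mind;
      pair_terms(pxyz, pq, prmin, peps, lx.data(), lq, lrmin, leps, nl,
                 cutoff, &evdw, &eelec, &mind);
      out(row, 0) = c + 1;
      out(row, 1) = r + 1;
      out(row, 6) = mind;
      if (mind < clash_skip) {
        out(row, 2) = NA_REAL; out(row, 3) = NA_REAL;
        out(row, 4) = NA_REAL; out(row, 5) = NA_REAL;
        continue;
      }
      double esolv = sigma_solv == 0.0 ? 0.0 :
        -sigma_solv * buried_area(pxyz, prmin, lx.data(), lrmin, nl, probe);
      out(row, 2) = evdw;
      out(row, 3) = eelec;
      out(row, 4) = esolv;
      out(row, 5) = evdw + eelec + esolv;
    }
  }
  return out;
}

// Heavy-atom non-bonded contact count with a cell list (spatial hash).
// [[Rcpp::export]]
int contact_count_cpp(NumericMatrix xyz, IntegerVector resid,
                      LogicalVector heavy, double cutoff, int min_seq_sep) {
  int n = xyz.nrow();
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) if (heavy[i]) idx.push_back(i);
  int nh = idx.size();
  if (nh == 0) return 0;
  double cell = cutoff;
  std::map<std::tuple<int, int, int>, std::vector<int> > grid;
  for (int a = 0; a < nh; ++a) {
    int i = idx[a];
    grid[std::make_tuple((int)std::floor(xyz(i, 0) / cell),
                         (int)std::floor(xyz(i, 1) / cell),
                         (int)std::floor(xyz(i, 2) / cell))].push_back(i);
  }
  double c2 = cutoff * cutoff;
  long count = 0;
  for (int a = 0; a < nh; ++a) {
    int i = idx[a];
    int cx = (int)std::floor(xyz(i, 0) / cell);
    int cy = (int)std::floor(xyz(i, 1) / cell);
    int cz = (int)std::floor(xyz(i, 2) / cell);
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          auto it = grid.find(std::make_tuple(cx + ox, cy + oy, cz + oz));
          if (it == grid.end()) continue;
          for (size_t m = 0; m < it->second.size(); ++m) {
            int j = it->second[m];
            if (j <= i) continue;
            if (std::abs(resid[i] - resid[j]) < min_seq_sep) continue;
            double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
                   dz = xyz(i, 2) - xyz(j, 2);
            if (dx * dx + dy * dy + dz * dz <= c2) ++count;
          }
        }
  }
  return (int)count;
}
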