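// Energy kernels for the rigid-water MM potential, the QM/MM coupling term,
// and the Metropolis sweep engine. Units: kcal/mol, Angstrom, elementary
// charge. Water sites are stored as a (3n x 3) matrix with rows
// (O, H1, H2) per molecule; truncation is group-based on the O site.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coulomb constant in kcal * Angstrom / (mol e^2), fixed for reproducibility
static const double COULK = 332.0637;
static const double OVERLAP_R2 = 0.01; // (0.1 A)^2 hard-overlap guard
static const double BIG_E = 1e10;

static inline double d2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// energy of one water-water molecule pair given site coordinates
// a[0..2], b[0..2] are pointers to (x,y,z) triples for O,H1,H2
static double pair_ww(const double a[3][3], const double b[3][3],
                      double qO, double qH, double sigma, double eps,
                      bool* overlap) {
  const double q[3] = {qO, qH, qH};
  double e = 0.0;
  for (int s = 0; s < 3; ++s) {
    for (int t = 0; t < 3; ++t) {
      double r2 = d2(a[s], b[t]);
      if (r2 < OVERLAP_R2) { *overlap = true; return BIG_E; }
      e += COULK * q[s] * q[t] / std::sqrt(r2);
    }
  }
  double r2 = d2(a[0], b[0]);
  double sr2 = sigma * sigma / r2;
  double sr6 = sr2 * sr2 * sr2;
  e += 4.0 * eps * (sr6 * sr6 - sr6);
  return e;
}

static inline void get_mol(const NumericMatrix& sites, int i, double m[3][3]) {
  for (int s = 0; s < 3; ++s)
    for (int k = 0; k < 3; ++k) m[s][k] = sites(3 * i + s, k);
}

// [[Rcpp::export]]
double ww_energy_cpp(NumericMatrix sites, double qO, double qH,
                     double sigma, double eps, double rc,
                     bool periodic, double L) {
  int n = sites.nrow() / 3;
  double rc2 = R_FINITE(rc) ? rc * rc : R_PosInf;
  double e = 0.0;
  double a[3][3], b[3][3];
  bool overlap = false;
  for (int i = 0; i < n - 1; ++i) {
    get_mol(sites, i, a);
    for (int j = i + 1; j < n; ++j) {
      get_mol(sites, j, b);
      if (periodic) {
        // minimum-image shift determined by the O-O vector, applied to the
        // whole molecule so rigid pairs are never split across images
        for (int k = 0; k < 3; ++k) {
          double d = b[0][k] - a[0][k];
          double shift = -L * std::round(d / L);
          if (shift != 0.0)
            for (int s = 0; s < 3; ++s) b[s][k] += shift;
        }
      }
      if (d2(a[0], b[0]) >= rc2) continue;
      e += pair_ww(a, b, qO, qH, sigma, eps, &overlap);
      if (overlap)
        stop("overlapping water sites (r < 0.1 A) between molecules %d and %d",
             i + 1, j + 1);
    }
  }
  return e;
}

// water-water energy of a single molecule (candidate coordinates `mol`,
// occupying slot imol) with all other molecules; BIG_E on overlap
static double mol_ww(const double mol[3][3], int imol,
                     const NumericMatrix& sites, double qO, double qH,
                     double sigma, double eps, double rc2) {
  int n = sites.nrow() / 3;
  double b[3][3];
  double e = 0.0;
  bool overlap = false;
  for (int j = 0; j < n; ++j) {
    if (j == imol) continue;
    get_mol(sites, j, b);
    if (d2(mol[0], b[0]) >= rc2) continue;
    e += pair_ww(mol, b, qO, qH, sigma, eps, &overlap);
    if (overlap) return BIG_E;
  }
  return e;
}

// coupling of a single water molecule with the solute.
// qin: solute charges already scaled to the sampling level (used inside the
// cutoff); qout: bare ESP charges (outside, Coulomb only).
static double mol_coupling(const double mol[3][3], const NumericMatrix& sol,
                           const NumericVector& qin, const NumericVector& qout,
                           const NumericVector& sigmix, const NumericVector& epsmix,
                           double qO, double qH, double rc2) {
  int m = sol.nrow();
  double rmin2 = R_PosInf;
  for (int a = 0; a < m; ++a) {
    double p[3] = {sol(a, 0), sol(a, 1), sol(a, 2)};
    double r2 = d2(mol[0], p);
    if (r2 < rmin2) rmin2 = r2;
  }
  bool inside = rmin2 < rc2;
  const double qw[3] = {qO, qH, qH};
  double e = 0.0;
  for (int a = 0; a < m; ++a) {
    double p[3] = {sol(a, 0), sol(a, 1), sol(a, 2)};
    double qa = inside ? qin[a] : qout[a];
    for (int s = 0; s < 3; ++s) {
      double r2 = d2(mol[s], p);
      if (r2 < OVERLAP_R2) return BIG_E;
      e += COULK * qa * qw[s] / std::sqrt(r2);
    }
    if (inside && epsmix[a] > 0.0) {
      double r2 = d2(mol[0], p);
      double sr2 = sigmix[a] * sigmix[a] / r2;
      double sr6 = sr2 * sr2 * sr2;
      e += 4.0 * epsmix[a] * (sr6 * sr6 - sr6);
    }
  }
  return e;
}

// Split coupling terms at bare (unit-scale) charges so callers can apply a
// level charge scale to the inside-cutoff Coulomb part:
//   E(level) = scale * coul_in + lj_in + coul_out
// [[Rcpp::export]]
NumericVector coupling_parts_cpp(NumericMatrix sol, NumericVector q,
                                 NumericVector sigmix, NumericVector epsmix,
                                 NumericMatrix sites, double qO, double qH,
                                 double rc) {
  int n = sites.nrow() / 3, m = sol.nrow();
  double rc2 = R_FINITE(rc) ? rc * rc : R_PosInf;
  const double qw[3] = {qO, qH, qH};
  double coul_in = 0.0, lj_in = 0.0, coul_out = 0.0;
  int n_in = 0;
  double mol[3][3];
  for (int i = 0; i < n; ++i) {
    get_mol(sites, i, mol);
    double rmin2 = R_PosInf;
    for (int a = 0; a < m; ++a) {
      double p[3] = {sol(a, 0), sol(a, 1), sol(a, 2)};
      double r2 = d2(mol[0], p);
      if (r2 < rmin2) rmin2 = r2;
    }
    bool inside = rmin2 < rc2;
    if (inside) ++n_in;
    for (int a = 0; a < m; ++a) {
      double p[3] = {sol(a, 0), sol(a, 1), sol(a, 2)};
      double c = 0.0;
      for (int s = 0; s < 3; ++s) {
        double r2 = d2(mol[s], p);
        if (r2 < OVERLAP_R2)
          stop("overlapping solute/water sites (r < 0.1 A) at molecule %d", i + 1);
        c += COULK * q[a] * qw[s] / std::sqrt(r2);
      }
      if (inside) {
        coul_in += c;
        if (epsmix[a] > 0.0) {
          double r2 = d2(mol[0], p);
          double sr2 = sigmix[a] * sigmix[a] / r2;
          double sr6 = sr2 * sr2 * sr2;
          lj_in += 4.0 * epsmix[a] * (sr6 * sr6 - sr6);
        }
      } else {
        coul_out += c;
      }
    }
  }
  return NumericVector::create(_["coul_in"] = coul_in, _["lj_in"] = lj_in,
                               _["coul_out"] = coul_out, _["n_in"] = n_in);
}

// Metropolis sweeps over rigid waters (translation + rotation about O).
// Solute frozen. Uses R's RNG so trajectories are reproducible from set.seed.
// Returns the updated sites plus acceptance counters.
// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix sites_in, double L, bool wall,
                NumericMatrix sol, NumericVector qin, NumericVector qout,
                NumericVector sigmix, NumericVector epsmix,
                double rc_couple, double rc_ww,
                double qO, double qH, double sigma, double eps,
                double kT, double dtrans, double drot, int nsweeps) {
  NumericMatrix sites = clone(sites_in);
  int n = sites.nrow() / 3;
  bool has_sol = sol.nrow() > 0;
  double rcw2 = R_FINITE(rc_ww) ? rc_ww * rc_ww : R_PosInf;
  double rcc2 = R_FINITE(rc_couple) ? rc_couple * rc_couple : R_PosInf;
  long accepted = 0, attempted = 0;
  double oldm[3][3], newm[3][3];

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      ++attempted;
      get_mol(sites, i, oldm);
      // uniform translation
      double tr[3];
      for (int k = 0; k < 3; ++k) tr[k] = dtrans * (2.0 * unif_rand() - 1.0);
      // random rotation axis and angle about the (translated) oxygen
      double ax[3];
      double nrm = 0.0;
      for (int k = 0; k < 3; ++k) { ax[k] = norm_rand(); nrm += ax[k] * ax[k]; }
      nrm = std::sqrt(nrm);
      for (int k = 0; k < 3; ++k) ax[k] /= nrm;
      double th = drot * (2.0 * unif_rand() - 1.0);
      double ct = std::cos(th), st = std::sin(th);
      double O[3];
      for (int k = 0; k < 3; ++k) {
        O[k] = oldm[0][k] + tr[k];
        newm[0][k] = O[k];
      }
      for (int s = 1; s < 3; ++s) {
        double v[3];
        for (int k = 0; k < 3; ++k) v[k] = oldm[s][k] + tr[k] - O[k];
        double ad = ax[0] * v[0] + ax[1] * v[1] + ax[2] * v[2];
        double cx[3] = {ax[1] * v[2] - ax[2] * v[1],
                        ax[2] * v[0] - ax[0] * v[2],
                        ax[0] * v[1] - ax[1] * v[0]};
        for (int k = 0; k < 3; ++k)
          newm[s][k] = O[k] + v[k] * ct + cx[k] * st + ax[k] * ad * (1.0 - ct);
      }
      // hard-wall container for the non-periodic droplet
      if (wall) {
        bool out = false;
        for (int k = 0; k < 3; ++k)
          if (newm[0][k] < 0.0 || newm[0][k] >= L) out = true;
        if (out) continue;
      }
      double e_old = mol_ww(oldm, i, sites, qO, qH, sigma, eps, rcw2);
      double e_new = mol_ww(newm, i, sites, qO, qH, sigma, eps, rcw2);
      if (has_sol) {
        e_old += mol_coupling(oldm, sol, qin, qout, sigmix, epsmix, qO, qH, rcc2);
        e_new += mol_coupling(newm, sol, qin, qout, sigmix, epsmix, qO, qH, rcc2);
      }
      double dE = e_new - e_old;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) {
        for (int s = 0; s < 3; ++s)
          for (int k = 0; k < 3; ++k) sites(3 * i + s, k) = newm[s][k];
        ++accepted;
      }
    }
  }
  return List::create(_["sites"] = sites,
                      _["accepted"] = (double)accepted,
                      _["attempted"] = (double)attempted);
}
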