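#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Go-model energy terms, all in kBT units, lengths in nm.
//
// bonds:    0.5 * k * (r - r0)^2
// contacts: eps * (5 (r0/r)^12 - 6 (r0/r)^10)   (minimum -eps at r = r0)
// repulsion (non-bonded, non-contact pairs): eps_rep * ((sigma/r)^12 - 1)
//           for r < sigma, else 0; r clamped away from 0 so the energy
//           is large but finite for overlapping beads.

static const double R_CLAMP = 0.02;

static inline double dist3(const NumericMatrix& x, int i, int j) {
  double dx = x(i, 0) - x(j, 0);
  double dy = x(i, 1) - x(j, 1);
  double dz = x(i, 2) - x(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double contact_energy(double r, double r0, double eps) {
  if (r < R_CLAMP) r = R_CLAMP;
  double q = r0 / r;
  double q2 = q * q;
  double q10 = q2 * q2 * q2 * q2 * q2;
  return eps * (5.0 * q10 * q2 - 6.0 * q10);
}

static inline double rep_energy(double r, double sigma, double eps_rep) {
  if (r >= sigma) return 0.0;
  if (r < R_CLAMP) r = R_CLAMP;
  double q = sigma / r;
  double q2 = q * q;
  double q12 = q2 * q2 * q2;
  q12 = q12 * q12;
  return eps_rep * (q12 - 1.0);
}

struct Model {
  NumericMatrix coords;
  IntegerVector bi, bj;
  NumericVector br0, bk;
  IntegerVector ci, cj;
  NumericVector cr0, cdepth;
  LogicalVector cinter;
  double sigma, eps_rep;
  int n;
  std::vector<signed char> excl;  // n*n: 1 = bonded or contact pair

  Model(NumericMatrix coords_, DataFrame bonds, DataFrame contacts,
        double sigma_, double eps_rep_)
    : coords(clone(coords_)),
      bi(bonds["i"]), bj(bonds["j"]), br0(bonds["r0"]), bk(bonds["k"]),
      ci(contacts["i"]), cj(contacts["j"]), cr0(contacts["r0"]),
      cdepth(contacts["depth"]), cinter(contacts["inter"]),
      sigma(sigma_), eps_rep(eps_rep_), n(coords_.nrow()),
      excl(coords_.nrow() * coords_.nrow(), 0) {
    for (int b = 0; b < bi.size(); b++) {
      excl[(bi[b] - 1) * n + (bj[b] - 1)] = 1;
      excl[(bj[b] - 1) * n + (bi[b] - 1)] = 1;
    }
    for (int c = 0; c < ci.size(); c++) {
      excl[(ci[c] - 1) * n + (cj[c] - 1)] = 1;
      excl[(cj[c] - 1) * n + (ci[c] - 1)] = 1;
    }
  }

  double total_energy() const {
    double e = 0.0;
    for (int b = 0; b < bi.size(); b++) {
      double r = dist3(coords, bi[b] - 1, bj[b] - 1);
      double d = r - br0[b];
      e += 0.5 * bk[b] * d * d;
    }
    for (int c = 0; c < ci.size(); c++) {
      e += contact_energy(dist3(coords, ci[c] - 1, cj[c] - 1),
                          cr0[c], cdepth[c]);
    }
    for (int i = 0; i < n - 1; i++) {
      for (int j = i + 1; j < n; j++) {
        if (excl[i * n + j]) continue;
        e += rep_energy(dist3(coords, i, j), sigma, eps_rep);
      }
    }
    return e;
  }

  // energy terms involving bead i only
  double local_energy(int i) const {
    double e = 0.0;
    for (int b = 0; b < bi.size(); b++) {
      if (bi[b] - 1 != i && bj[b] - 1 != i) continue;
      double r = dist3(coords, bi[b] - 1, bj[b] - 1);
      double d = r - br0[b];
      e += 0.5 * bk[b] * d * d;
    }
    for (int c = 0; c < ci.size(); c++) {
      if (ci[c] - 1 != i && cj[c] - 1 != i) continue;
      e += contact_energy(dist3(coords, ci[c] - 1, cj[c] - 1),
                          cr0[c], cdepth[c]);
    }
    for (int j = 0; j < n; j++) {
      if (j == i || excl[i * n + j]) continue;
      e += rep_energy(dist3(coords, i, j), sigma, eps_rep);
    }
    return e;
  }

  double inter_fraction() const {
    int total = 0, formed = 0;
    for (int c = 0; c < ci.size(); c++) {
      if (!cinter[c]) continue;
      total++;
      double r = dist3(coords, ci[c] - 1, cj[c] - 1);
      if (r < 1.5 * cr0[c]) formed++;
    }
    if (total == 0) return 0.0;  // nothing holds the chains together
    return (double)formed / total;
  }
};

// [[Rcpp::export]]
double cg_energy_cpp(NumericMatrix coords, DataFrame bonds,
                     DataFrame contacts, double sigma, double eps_rep) {
  Model m(coords, bonds, contacts, sigma, eps_rep);
  return m.total_energy();
}

// Metropolis Monte Carlo pulling with two virtual springs.
//
// Anchors start on the pulling-group beads and recede along the fixed
// initial inter-group direction at `velocity` nm per sweep (total
// separation rate). Spring energy (kBT) = 0.5 * k_spring/kT * d^2 with
// d the 3-D anchor-bead distance; the recorded force (pN) is the mean
// spring tension k_spring * d over the two springs.
// One sweep = n single-bead Gaussian trial moves of SD `step`.
//
// [[Rcpp::export]]
List mc_pull_cpp(NumericMatrix coords, DataFrame bonds, DataFrame contacts,
                 double sigma, double eps_rep,
                 int group_a, int group_b,
                 double k_spring, double kT_pNnm,
                 double velocity, int sweeps, double step,
                 double contact_break_fraction, int equil_sweeps,
                 bool record_group_coords, NumericVector axis,
                 bool stop_at_rupture) {
  Model m(coords, bonds, contacts, sigma, eps_rep);
  int n = m.n;
  int ga = group_a - 1, gb = group_b - 1;
  double ks_kT = k_spring / kT_pNnm;  // spring constant in kBT / nm^2

  // pulling direction: the supplied axis, or the initial vector from
  // group a to group b; fixed for the whole run
  double ux, uy, uz;
  if (axis.size() == 3) {
    ux = axis[0]; uy = axis[1]; uz = axis[2];
  } else {
    ux = m.coords(gb, 0) - m.coords(ga, 0);
    uy = m.coords(gb, 1) - m.coords(ga, 1);
    uz = m.coords(gb, 2) - m.coords(ga, 2);
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;

  std::vector<double> ax = {m.coords(ga, 0), m.coords(ga, 1), m.coords(ga, 2)};
  std::vector<double> bx = {m.coords(gb, 0), m.coords(gb, 1), m.coords(gb, 2)};

  auto spring_energy = [&](int bead, const std::vector<double>& anchor) {
    double dx = m.coords(bead, 0) - anchor[0];
    double dy = m.coords(bead, 1) - anchor[1];
    double dz = m.coords(bead, 2) - anchor[2];
    return 0.5 * ks_kT * (dx * dx + dy * dy + dz * dz);
  };
  auto spring_force_pN = [&](int bead, const std::vector<double>& anchor) {
    double dx = m.coords(bead, 0) - anchor[0];
    double dy = m.coords(bead, 1) - anchor[1];
    double dz = m.coords(bead, 2) - anchor[2];
    return k_spring * std::sqrt(dx * dx + dy * dy + dz * dz);
  };

  long accepted = 0, attempted = 0;
  std::vector<double> rec_sep, rec_force, rec_frac, gx, gy, gz;
  rec_sep.reserve(sweeps); rec_force.reserve(sweeps);
  rec_frac.reserve(sweeps);

  int rupture_sweep = NA_INTEGER;
  double rupture_force = 0.0, max_force = 0.0;

  int total_sweeps = equil_sweeps + sweeps;
  for (int sw = 0; sw < total_sweeps; sw++) {
    bool production = sw >= equil_sweeps;
    if (production) {
      // anchors recede symmetrically along the pulling vector
      ax[0] -= 0.5 * velocity * ux; ax[1] -= 0.5 * velocity * uy;
      ax[2] -= 0.5 * velocity * uz;
      bx[0] += 0.5 * velocity * ux; bx[1] += 0.5 * velocity * uy;
      bx[2] += 0.5 * velocity * uz;
    }
    for (int mv = 0; mv < n; mv++) {
      int i = (int)(R::unif_rand() * n);
      if (i == n) i = n - 1;
      double e_old = m.local_energy(i);
      if (i == ga) e_old += spring_energy(ga, ax);
      if (i == gb) e_old += spring_energy(gb, bx);
      double ox = m.coords(i, 0), oy = m.coords(i, 1), oz = m.coords(i, 2);
      m.coords(i, 0) = ox + R::norm_rand() * step;
      m.coords(i, 1) = oy + R::norm_rand() * step;
      m.coords(i, 2) = oz + R::norm_rand() * step;
      double e_new = m.local_energy(i);
      if (i == ga) e_new += spring_energy(ga, ax);
      if (i == gb) e_new += spring_energy(gb, bx);
      attempted++;
      double dE = e_new - e_old;
      if (dE <= 0.0 || R::unif_rand() < std::exp(-dE)) {
        accepted++;
      } else {
        m.coords(i, 0) = ox; m.coords(i, 1) = oy; m.coords(i, 2) = oz;
      }
    }
    if (!production) continue;

    double sep = std::sqrt(
      (bx[0] - ax[0]) * (bx[0] - ax[0]) +
      (bx[1] - ax[1]) * (bx[1] - ax[1]) +
      (bx[2] - ax[2]) * (bx[2] - ax[2]));
    double force = 0.5 * (spring_force_pN(ga, ax) + spring_force_pN(gb, bx));
    double frac = m.inter_fraction();
    rec_sep.push_back(sep);
    rec_force.push_back(force);
    rec_frac.push_back(frac);
    if (record_group_coords) {
      gx.push_back(m.coords(ga, 0));
      gy.push_back(m.coords(ga, 1));
      gz.push_back(m.coords(ga, 2));
    }
    if (frac < contact_break_fraction && rupture_sweep == NA_INTEGER) {
      rupture_sweep = (int)rec_sep.size();
      rupture_force = max_force;
      if (stop_at_rupture) break;
    }
    if (rupture_sweep == NA_INTEGER && force > max_force) max_force = force;
  }
  if (rupture_sweep == NA_INTEGER) {
    // never ruptured within the sweep budget
    rupture_force = max_force;
  }

  List out = List::create(
    _["sweep"] = wrap(seq_len((int)rec_sep.size())),
    _["separation"] = wrap(rec_sep),
    _["force"] = wrap(rec_force),
    _["inter_fraction"] = wrap(rec_frac),
    _["rupture_sweep"] = rupture_sweep,
    _["rupture_force"] = rupture_force,
    _["acceptance"] = (double)accepted / (double)attempted,
    _["final_coords"] = m.coords);
  if (record_group_coords) {
    out["group_coords"] = DataFrame::create(
      _["x"] = wrap(gx), _["y"] = wrap(gy), _["z"] = wrap(gz));
  }
  return out;
}
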