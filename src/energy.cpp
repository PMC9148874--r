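#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Units: kcal/mol, Angstrom, radians, elementary charge.
// Coulomb constant in kcal*A/(mol*e^2), CHARMM value.
static const double COULOMB = 332.0637133;

struct Sys {
  int natoms;
  // nonbonded pair list (exclusions already removed)
  IntegerVector pi, pj, softcore, escale;
  NumericVector qq, eps, sig;
  // bonded terms
  IntegerMatrix bonds;   NumericVector kb, b0;
  IntegerMatrix angles;  NumericVector kt, t0;
  IntegerMatrix dih;     NumericVector dK, ddelta; IntegerVector dn;
  IntegerMatrix imp;     NumericVector kimp, psi0;
  // Cartesian tethers
  IntegerVector teth_atom; NumericVector teth_k; NumericMatrix teth_pos;
  // flat-bottom COM restraint
  bool restr_on;
  IntegerVector ga, gb; NumericVector masses;
  double rK, rr0;
  IntegerVector movable;
};

static Sys parse_sys(const List& s) {
  Sys y;
  y.natoms = as<int>(s["natoms"]);
  List p = s["pairs"];
  y.pi = p["i"]; y.pj = p["j"]; y.qq = p["qq"]; y.eps = p["eps"];
  y.sig = p["sig"]; y.softcore = p["softcore"]; y.escale = p["escale"];
  y.bonds = as<IntegerMatrix>(s["bonds"]);
  y.kb = s["kb"]; y.b0 = s["b0"];
  y.angles = as<IntegerMatrix>(s["angles"]);
  y.kt = s["kt"]; y.t0 = s["t0"];
  y.dih = as<IntegerMatrix>(s["dih"]);
  y.dK = s["dK"]; y.dn = s["dn"]; y.ddelta = s["ddelta"];
  y.imp = as<IntegerMatrix>(s["imp"]);
  y.kimp = s["kimp"]; y.psi0 = s["psi0"];
  y.teth_atom = s["teth_atom"]; y.teth_k = s["teth_k"];
  y.teth_pos = as<NumericMatrix>(s["teth_pos"]);
  List r = s["restr"];
  y.restr_on = as<bool>(r["on"]);
  y.ga = r["ga"]; y.gb = r["gb"]; y.masses = r["masses"];
  y.rK = as<double>(r["K"]); y.rr0 = as<double>(r["r0"]);
  y.movable = s["movable"];
  return y;
}

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

static inline void getr(const NumericMatrix& x, int i, double* out) {
  out[0] = x(i, 0); out[1] = x(i, 1); out[2] = x(i, 2);
}
static inline void addf(NumericMatrix* F, int i, const double* f, double s) {
  if (!F) return;
  (*F)(i, 0) += s * f[0]; (*F)(i, 1) += s * f[1]; (*F)(i, 2) += s * f[2];
}

// angle theta and its gradient wrt the three atoms; colinear geometry is
// handled by clamping sin(theta) away from zero (defined limit, never NaN)
static double angle_grad(const double* ri, const double* rj, const double* rk,
                         double* gi, double* gj, double* gk) {
  double u[3], v[3];
  vsub(ri, rj, u); vsub(rk, rj, v);
  double nu = vnorm(u), nv = vnorm(v);
  double c = vdot(u, v) / (nu * nv);
  c = std::max(-1.0, std::min(1.0, c));
  double s = std::sqrt(std::max(1.0 - c * c, 1e-16));
  double th = std::acos(c);
  for (int d = 0; d < 3; ++d) {
    gi[d] = (c * u[d] / nu - v[d] / nv) / (nu * s);
    gk[d] = (c * v[d] / nv - u[d] / nu) / (nv * s);
    gj[d] = -gi[d] - gk[d];
  }
  return th;
}

// dihedral phi in (-pi, pi] and gradient wrt the four atoms
static double dihedral_grad(const double* ri, const double* rj,
                            const double* rk, const double* rl,
                            double* gi, double* gj, double* gk, double* gl) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
  vsub(rj, ri, b1); vsub(rk, rj, b2); vsub(rl, rk, b3);
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double nb2 = vnorm(b2);
  vcross(n1, n2, m);
  double phi = std::atan2(vdot(m, b2) / std::max(nb2, 1e-12), vdot(n1, n2));
  double n1sq = std::max(vdot(n1, n1), 1e-16);
  double n2sq = std::max(vdot(n2, n2), 1e-16);
  double p = vdot(b1, b2) / std::max(nb2 * nb2, 1e-16);
  double q = vdot(b3, b2) / std::max(nb2 * nb2, 1e-16);
  for (int d = 0; d < 3; ++d) {
    gi[d] = -nb2 / n1sq * n1[d];
    gl[d] = nb2 / n2sq * n2[d];
    gj[d] = -(1.0 + p) * gi[d] + q * gl[d];
    gk[d] = p * gi[d] - (1.0 + q) * gl[d];
  }
  return phi;
}

// COM-distance between mass-weighted groups and, optionally, the chain-rule
// unit vectors needed for restraint forces
static double com_dist(const NumericMatrix& x, const IntegerVector& ga,
                       const IntegerVector& gb, const NumericVector& masses,
                       double* dvec, double* Ma_out, double* Mb_out) {
  double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0}, Ma = 0, Mb = 0;
  for (int a = 0; a < ga.size(); ++a) {
    int i = ga[a]; double m = masses[i]; Ma += m;
    for (int d = 0; d < 3; ++d) ca[d] += m * x(i, d);
  }
  for (int a = 0; a < gb.size(); ++a) {
    int i = gb[a]; double m = masses[i]; Mb += m;
    for (int d = 0; d < 3; ++d) cb[d] += m * x(i, d);
  }
  double dv[3];
  for (int d = 0; d < 3; ++d) dv[d] = ca[d] / Ma - cb[d] / Mb;
  double r = std::sqrt(vdot(dv, dv));
  if (dvec) { dvec[0] = dv[0]; dvec[1] = dv[1]; dvec[2] = dv[2]; }
  if (Ma_out) *Ma_out = Ma;
  if (Mb_out) *Mb_out = Mb;
  return r;
}

// Evaluate all energy components (and forces when F != NULL).
// comps: 0 bond, 1 angle, 2 dihedral, 3 improper, 4 elec, 5 vdw,
//        6 tether, 7 restraint
static double eval_all(const NumericMatrix& x, const Sys& s, double le,
                       double lv, NumericMatrix* F, double* comps) {
  for (int c = 0; c < 8; ++c) comps[c] = 0.0;
  double ri[3], rj[3], rk[3], rl[3], gi[3], gj[3], gk[3], gl[3];

  // bonds: U = k (b - b0)^2  (CHARMM convention, no 1/2)
  for (int t = 0; t < s.bonds.nrow(); ++t) {
    int i = s.bonds(t, 0), j = s.bonds(t, 1);
    getr(x, i, ri); getr(x, j, rj);
    double dv[3]; vsub(ri, rj, dv);
    double b = vnorm(dv), db = b - s.b0[t];
    comps[0] += s.kb[t] * db * db;
    if (F) {
      double coef = -2.0 * s.kb[t] * db / std::max(b, 1e-12);
      for (int d = 0; d < 3; ++d) { gi[d] = coef * dv[d]; }
      addf(F, i, gi, 1.0); addf(F, j, gi, -1.0);
    }
  }
  // angles: U = k (theta - theta0)^2
  for (int t = 0; t < s.angles.nrow(); ++t) {
    int i = s.angles(t, 0), j = s.angles(t, 1), k = s.angles(t, 2);
    getr(x, i, ri); getr(x, j, rj); getr(x, k, rk);
    double th = angle_grad(ri, rj, rk, gi, gj, gk);
    double dt = th - s.t0[t];
    comps[1] += s.kt[t] * dt * dt;
    if (F) {
      double coef = -2.0 * s.kt[t] * dt;
      addf(F, i, gi, coef); addf(F, j, gj, coef); addf(F, k, gk, coef);
    }
  }
  // proper dihedrals: U = K (1 + cos(n phi - delta)) per Fourier term
  for (int t = 0; t < s.dih.nrow(); ++t) {
    int i = s.dih(t, 0), j = s.dih(t, 1), k = s.dih(t, 2), l = s.dih(t, 3);
    getr(x, i, ri); getr(x, j, rj); getr(x, k, rk); getr(x, l, rl);
    double phi = dihedral_grad(ri, rj, rk, rl, gi, gj, gk, gl);
    double arg = s.dn[t] * phi - s.ddelta[t];
    comps[2] += s.dK[t] * (1.0 + std::cos(arg));
    if (F) {
      double coef = s.dK[t] * s.dn[t] * std::sin(arg); // -dU/dphi
      addf(F, i, gi, coef); addf(F, j, gj, coef);
      addf(F, k, gk, coef); addf(F, l, gl, coef);
    }
  }
  // impropers: harmonic in the dihedral angle, U = k (psi - psi0)^2
  for (int t = 0; t < s.imp.nrow(); ++t) {
    int i = s.imp(t, 0), j = s.imp(t, 1), k = s.imp(t, 2), l = s.imp(t, 3);
    getr(x, i, ri); getr(x, j, rj); getr(x, k, rk); getr(x, l, rl);
    double psi = dihedral_grad(ri, rj, rk, rl, gi, gj, gk, gl);
    double dp = psi - s.psi0[t];
    // wrap into (-pi, pi]
    while (dp > M_PI) dp -= 2.0 * M_PI;
    while (dp <= -M_PI) dp += 2.0 * M_PI;
    comps[3] += s.kimp[t] * dp * dp;
    if (F) {
      double coef = -2.0 * s.kimp[t] * dp;
      addf(F, i, gi, coef); addf(F, j, gj, coef);
      addf(F, k, gk, coef); addf(F, l, gl, coef);
    }
  }
  // nonbonded: no cutoffs (gas-phase convention)
  for (int t = 0; t < s.pi.size(); ++t) {
    int i = s.pi[t], j = s.pj[t];
    getr(x, i, ri); getr(x, j, rj);
    double dv[3]; vsub(ri, rj, dv);
    double r = vnorm(dv);
    double fr = 0.0; // radial force magnitude coefficient: F_i = fr * dv
    // electrostatics: region charges scaled by lambda_elec
    if (s.qq[t] != 0.0) {
      double scale = 1.0;
      if (s.escale[t] == 1) scale = le;
      else if (s.escale[t] == 2) scale = le * le;
      if (scale != 0.0) {
        if (r < 1e-10) stop("Coulomb singularity: interacting pair at r = 0");
        double e = scale * s.qq[t] / r;
        comps[4] += e;
        fr += e / (r * r);
      }
    }
    // Lennard-Jones: soft-core for region-environment pairs, plain otherwise
    if (s.eps[t] > 0.0) {
      if (s.softcore[t] && lv < 1.0) {
        if (lv > 0.0) {
          double dsh = r + s.sig[t] * (1.0 - lv);
          double s6 = std::pow(s.sig[t] / dsh, 6);
          comps[5] += 4.0 * lv * s.eps[t] * (s6 * s6 - s6);
          double dEdr = -24.0 * lv * s.eps[t] * (2.0 * s6 * s6 - s6) / dsh;
          fr += -dEdr / std::max(r, 1e-12);
        }
      } else {
        if (r < 1e-10) stop("LJ singularity: interacting pair at r = 0");
        double s6 = std::pow(s.sig[t] / r, 6);
        comps[5] += 4.0 * s.eps[t] * (s6 * s6 - s6);
        double dEdr = -24.0 * s.eps[t] * (2.0 * s6 * s6 - s6) / r;
        fr += -dEdr / r;
      }
    }
    if (F && fr != 0.0) {
      for (int d = 0; d < 3; ++d) gi[d] = fr * dv[d];
      addf(F, i, gi, 1.0); addf(F, j, gi, -1.0);
    }
  }
  // Cartesian tethers: U = k |r - r_ref|^2
  for (int t = 0; t < s.teth_atom.size(); ++t) {
    int i = s.teth_atom[t];
    for (int d = 0; d < 3; ++d) {
      double dx = x(i, d) - s.teth_pos(t, d);
      comps[6] += s.teth_k[t] * dx * dx;
      if (F) (*F)(i, d) += -2.0 * s.teth_k[t] * dx;
    }
  }
  // flat-bottom COM restraint: 0 below r0, (1/2) K (r - r0)^2 at or above
  if (s.restr_on) {
    double dv[3], Ma, Mb;
    double r = com_dist(x, s.ga, s.gb, s.masses, dv, &Ma, &Mb);
    if (r >= s.rr0) {
      double dr = r - s.rr0;
      comps[7] += 0.5 * s.rK * dr * dr;
      if (F && r > 1e-12) {
        double dEdr = s.rK * dr;
        for (int a = 0; a < s.ga.size(); ++a) {
          int i = s.ga[a]; double w = s.masses[i] / Ma;
          for (int d = 0; d < 3; ++d) (*F)(i, d) += -dEdr * w * dv[d] / r;
        }
        for (int a = 0; a < s.gb.size(); ++a) {
          int i = s.gb[a]; double w = s.masses[i] / Mb;
          for (int d = 0; d < 3; ++d) (*F)(i, d) += dEdr * w * dv[d] / r;
        }
      }
    }
  }
  double tot = 0.0;
  for (int c = 0; c < 8; ++c) tot += comps[c];
  return tot;
}

// [[Rcpp::export]]
List cpp_eval(NumericMatrix coords, List sys, double lambda_elec,
              double lambda_vdw, bool forces) {
  Sys s = parse_sys(sys);
  double comps[8];
  if (forces) {
    NumericMatrix F(s.natoms, 3);
    double tot = eval_all(coords, s, lambda_elec, lambda_vdw, &F, comps);
    return List::create(_["total"] = tot,
                        _["components"] = NumericVector(comps, comps + 8),
                        _["forces"] = F);
  }
  double tot = eval_all(coords, s, lambda_elec, lambda_vdw, nullptr, comps);
  return List::create(_["total"] = tot,
                      _["components"] = NumericVector(comps, comps + 8));
}

// Total energies of many configurations at many lambda states (rows =
// states, cols = snapshots); the workhorse behind MBAR input matrices.
// [[Rcpp::export]]
NumericMatrix cpp_energy_grid(List coords_list, List sys,
                              NumericVector lambda_elec,
                              NumericVector lambda_vdw) {
  Sys s = parse_sys(sys);
  int K = lambda_elec.size(), S = coords_list.size();
  NumericMatrix U(K, S);
  double comps[8];
  for (int n = 0; n < S; ++n) {
    NumericMatrix x = coords_list[n];
    for (int k = 0; k < K; ++k)
      U(k, n) = eval_all(x, s, lambda_elec[k], lambda_vdw[k], nullptr, comps);
  }
  return U;
}

// Design matrix of bonded basis forces for force matching, one configuration.
// Column order: per bond (-grad b^2, +grad b); per angle (-grad th^2,
// +grad th); per dihedral Fourier term (-grad cos(n phi - delta)); per
// improper (-grad psi^2, +grad psi). Rows are atom-major (atom1 x,y,z, ...).
// [[Rcpp::export]]
NumericMatrix cpp_basis(NumericMatrix coords, List sys) {
  Sys s = parse_sys(sys);
  int P = 2 * s.bonds.nrow() + 2 * s.angles.nrow() + s.dih.nrow() +
          2 * s.imp.nrow();
  NumericMatrix X(3 * s.natoms, P);
  double ri[3], rj[3], rk[3], rl[3], gi[3], gj[3], gk[3], gl[3];
  int col = 0;
  for (int t = 0; t < s.bonds.nrow(); ++t) {
    int i = s.bonds(t, 0), j = s.bonds(t, 1);
    getr(coords, i, ri); getr(coords, j, rj);
    double dv[3]; vsub(ri, rj, dv);
    double b = std::max(vnorm(dv), 1e-12);
    for (int d = 0; d < 3; ++d) {
      double gb = dv[d] / b; // d b / d ri
      X(3 * i + d, col) = -2.0 * b * gb;  X(3 * j + d, col) = 2.0 * b * gb;
      X(3 * i + d, col + 1) = gb;          X(3 * j + d, col + 1) = -gb;
    }
    col += 2;
  }
  for (int t = 0; t < s.angles.nrow(); ++t) {
    int i = s.angles(t, 0), j = s.angles(t, 1), k = s.angles(t, 2);
    getr(coords, i, ri); getr(coords, j, rj); getr(coords, k, rk);
    double th = angle_grad(ri, rj, rk, gi, gj, gk);
    for (int d = 0; d < 3; ++d) {
      X(3 * i + d, col) = -2.0 * th * gi[d];
      X(3 * j + d, col) = -2.0 * th * gj[d];
      X(3 * k + d, col) = -2.0 * th * gk[d];
      X(3 * i + d, col + 1) = gi[d];
      X(3 * j + d, col + 1) = gj[d];
      X(3 * k + d, col + 1) = gk[d];
    }
    col += 2;
  }
  for (int t = 0; t < s.dih.nrow(); ++t) {
    int i = s.dih(t, 0), j = s.dih(t, 1), k = s.dih(t, 2), l = s.dih(t, 3);
    getr(coords, i, ri); getr(coords, j, rj);
    getr(coords, k, rk); getr(coords, l, rl);
    double phi = dihedral_grad(ri, rj, rk, rl, gi, gj, gk, gl);
    double coef = s.dn[t] * std::sin(s.dn[t] * phi - s.ddelta[t]);
    for (int d = 0; d < 3; ++d) {
      X(3 * i + d, col) = coef * gi[d];
      X(3 * j + d, col) = coef * gj[d];
      X(3 * k + d, col) = coef * gk[d];
      X(3 * l + d, col) = coef * gl[d];
    }
    col += 1;
  }
  for (int t = 0; t < s.imp.nrow(); ++t) {
    int i = s.imp(t, 0), j = s.imp(t, 1), k = s.imp(t, 2), l = s.imp(t, 3);
    getr(coords, i, ri); getr(coords, j, rj);
    getr(coords, k, rk); getr(coords, l, rl);
    double psi = dihedral_grad(ri, rj, rk, rl, gi, gj, gk, gl);
    for (int d = 0; d < 3; ++d) {
      X(3 * i + d, col) = -2.0 * psi * gi[d];
      X(3 * j + d, col) = -2.0 * psi * gj[d];
      X(3 * k + d, col) = -2.0 * psi * gk[d];
      X(3 * l + d, col) = -2.0 * psi * gl[d];
      X(3 * i + d, col + 1) = gi[d];
      X(3 * j + d, col + 1) = gj[d];
      X(3 * k + d, col + 1) = gk[d];
      X(3 * l + d, col + 1) = gl[d];
    }
    col += 2;
  }
  return X;
}

// Metropolis Monte Carlo targeting exp(-beta U) at a fixed lambda state.
// One sweep = one single-atom trial move per movable atom. Uses R's RNG so
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List cpp_metropolis(NumericMatrix coords0, List sys, double lambda_elec,
                    double lambda_vdw, double beta, int nsweeps, double width,
                    int thin, int burn, double trans_width,
                    double rot_width) {
  Sys s = parse_sys(sys);
  if (s.movable.size() == 0) stop("no movable atoms");
  NumericMatrix x = clone(coords0);
  double comps[8];
  double U = eval_all(x, s, lambda_elec, lambda_vdw, nullptr, comps);
  int nsnap = nsweeps / thin;
  NumericVector out(Dimension(s.natoms, 3, nsnap));
  NumericVector Uout(nsnap), rout(nsnap);
  bool track_r = s.ga.size() > 0 && s.gb.size() > 0;
  long naccept = 0, ntrial = 0;
  int isnap = 0;
  RNGScope scope;
  for (int sweep = 1; sweep <= burn + nsweeps; ++sweep) {
    for (int a = 0; a < s.movable.size(); ++a) {
      int i = s.movable[a];
      double old[3] = {x(i, 0), x(i, 1), x(i, 2)};
      for (int d = 0; d < 3; ++d)
        x(i, d) = old[d] + width * (2.0 * unif_rand() - 1.0);
      double Unew = eval_all(x, s, lambda_elec, lambda_vdw, nullptr, comps);
      ++ntrial;
      if (Unew <= U || unif_rand() < std::exp(-beta * (Unew - U))) {
        U = Unew; ++naccept;
      } else {
        for (int d = 0; d < 3; ++d) x(i, d) = old[d];
      }
    }
    if (trans_width > 0.0) {
      // rigid translation of the whole movable group: leaves bonded
      // geometry intact, decorrelates the centre of mass quickly
      double dv[3];
      for (int d = 0; d < 3; ++d)
        dv[d] = trans_width * (2.0 * unif_rand() - 1.0);
      for (int a = 0; a < s.movable.size(); ++a)
        for (int d = 0; d < 3; ++d) x(s.movable[a], d) += dv[d];
      double Unew = eval_all(x, s, lambda_elec, lambda_vdw, nullptr, comps);
      ++ntrial;
      if (Unew <= U || unif_rand() < std::exp(-beta * (Unew - U))) {
        U = Unew; ++naccept;
      } else {
        for (int a = 0; a < s.movable.size(); ++a)
          for (int d = 0; d < 3; ++d) x(s.movable[a], d) -= dv[d];
      }
    }
    if (rot_width > 0.0 && s.movable.size() > 1) {
      // rigid rotation of the movable group about its unweighted centroid
      double c[3] = {0, 0, 0};
      int nm = s.movable.size();
      for (int a = 0; a < nm; ++a)
        for (int d = 0; d < 3; ++d) c[d] += x(s.movable[a], d) / nm;
      double ax[3];
      double nrm = 0.0;
      do {
        for (int d = 0; d < 3; ++d) ax[d] = 2.0 * unif_rand() - 1.0;
        nrm = std::sqrt(vdot(ax, ax));
      } while (nrm < 1e-8 || nrm > 1.0);
      for (int d = 0; d < 3; ++d) ax[d] /= nrm;
      double ang = rot_width * (2.0 * unif_rand() - 1.0);
      double ca = std::cos(ang), sa = std::sin(ang);
      std::vector<double> oldpos(3 * nm);
      for (int a = 0; a < nm; ++a) {
        int i = s.movable[a];
        double v[3], w[3];
        for (int d = 0; d < 3; ++d) {
          oldpos[3 * a + d] = x(i, d);
          v[d] = x(i, d) - c[d];
        }
        vcross(ax, v, w);
        double adotv = vdot(ax, v);
        for (int d = 0; d < 3; ++d)
          x(i, d) = c[d] + v[d] * ca + w[d] * sa +
            ax[d] * adotv * (1.0 - ca);
      }
      double Unew = eval_all(x, s, lambda_elec, lambda_vdw, nullptr, comps);
      ++ntrial;
      if (Unew <= U || unif_rand() < std::exp(-beta * (Unew - U))) {
        U = Unew; ++naccept;
      } else {
        for (int a = 0; a < nm; ++a)
          for (int d = 0; d < 3; ++d)
            x(s.movable[a], d) = oldpos[3 * a + d];
      }
    }
    if (sweep > burn && (sweep - burn) % thin == 0 && isnap < nsnap) {
      for (int i = 0; i < s.natoms; ++i)
        for (int d = 0; d < 3; ++d)
          out[i + s.natoms * d + s.natoms * 3 * isnap] = x(i, d);
      Uout[isnap] = U;
      if (track_r)
        rout[isnap] = com_dist(x, s.ga, s.gb, s.masses, nullptr, nullptr,
                               nullptr);
      ++isnap;
    }
  }
  return List::create(_["coords"] = out, _["energy"] = Uout,
                      _["r_com"] = track_r ? rout : NumericVector(0),
                      _["acceptance"] = double(naccept) / double(ntrial),
                      _["final"] = x);
}

// [[Rcpp::export]]
double cpp_coulomb_constant() { return COULOMB; }
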