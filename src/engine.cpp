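// Compiled core: pairwise neighbour search, bonded/non-bonded energies and
// forces, steepest-descent minimisation, velocity-Verlet dynamics with
// velocity-rescale or Langevin (BAOAB) thermostats, and a metadynamics bias
// on the surface-separation-distance (SSD) collective variable with
// on-the-fly accumulation of the unbiased mean force.
//
// Internal units: length A, energy kJ/mol, mass g/mol.  The derived time
// unit sqrt(g/mol * A^2 / (kJ/mol)) equals 0.1 ps, so dt[internal] =
// dt[fs] / 100.  Temperatures in K with kB = 8.314462618e-3 kJ/mol/K.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double KB = 8.314462618e-3;   // kJ/mol/K
static const double TCONV = 100.0;         // fs per internal time unit
static const double PS = 10.0;             // internal time units per ps

struct PairList {
  std::vector<int> i, j;
};

static inline void min_image(double* d, const double* box, const int* per) {
  for (int k = 0; k < 3; ++k)
    if (per[k]) d[k] -= box[k] * std::round(d[k] / box[k]);
}

// --- external 1-D potentials along the CV -------------------------------
// kind: 0 none, 1 smoothed square well, 2 harmonic, 3 quartic double well,
//       4 9-3 wall.  s in A, energy kJ/mol, derivative kJ/mol/A.
static void ext_potential(int kind, const std::vector<double>& p, double s,
                          double* u, double* duds) {
  *u = 0.0; *duds = 0.0;
  switch (kind) {
  case 1: { // depth, s_on, s_off, edge width, core k (A units, kJ/mol/A^2)
    double D = p[0], a = p[1], b = p[2], w = p[3], krep = p[4];
    double xa = (s - a) / w, xb = (b - s) / w;
    double sa = 1.0 / (1.0 + std::exp(-xa));
    double sb = 1.0 / (1.0 + std::exp(-xb));
    *u = -D * sa * sb;
    double dsa = sa * (1.0 - sa) / w;
    double dsb = -sb * (1.0 - sb) / w;
    *duds = -D * (dsa * sb + sa * dsb);
    if (s < a) { // repulsive contact core
      *u += 0.5 * krep * (a - s) * (a - s);
      *duds += -krep * (a - s);
    }
    break;
  }
  case 2: { // k (kJ/mol/A^2), s0
    double k = p[0], s0 = p[1];
    *u = 0.5 * k * (s - s0) * (s - s0);
    *duds = k * (s - s0);
    break;
  }
  case 3: { // barrier B, centre c, half-separation w: B((s-c)^2-w^2)^2/w^4
    double B = p[0], c = p[1], w = p[2];
    double x = s - c, w4 = w * w * w * w;
    double q = x * x - w * w;
    *u = B * q * q / w4;
    *duds = 4.0 * B * q * x / w4;
    break;
  }
  case 4: { // eps, sigma: eps*(2/15 (sig/s)^9 - (sig/s)^3)
    double e = p[0], sg = p[1];
    double r3 = std::pow(sg / s, 3.0), r9 = r3 * r3 * r3;
    *u = e * (2.0 / 15.0 * r9 - r3);
    *duds = e * (-9.0 * 2.0 / 15.0 * r9 + 3.0 * r3) / s;
    break;
  }
  default: break;
  }
}

// --- softmin SSD and its gradient ---------------------------------------
// s = -1/beta * log sum_i exp(-beta * d_i), d_i = |x_ref - surf_i|.
// beta <= 0 selects the hard minimum (gradient of the argmin branch).
// grad_ref receives ds/dx_ref (3-vector); per-surface-atom reaction forces
// are -w_i * unit_i (returned via wsum if needed by caller).
static double ssd_value_grad(const double* xref,
                             const std::vector<double>& surf, int nsurf,
                             const double* box, const int* per,
                             double beta, double* grad_ref) {
  double dmin = R_PosInf;
  std::vector<double> d(nsurf), ux(nsurf), uy(nsurf), uz(nsurf);
  for (int i = 0; i < nsurf; ++i) {
    double dv[3] = { xref[0] - surf[3 * i], xref[1] - surf[3 * i + 1],
                     xref[2] - surf[3 * i + 2] };
    min_image(dv, box, per);
    double r = std::sqrt(dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2]);
    d[i] = r;
    if (r < dmin) dmin = r;
    double inv = (r > 1e-12) ? 1.0 / r : 0.0;
    ux[i] = dv[0] * inv; uy[i] = dv[1] * inv; uz[i] = dv[2] * inv;
  }
  if (beta <= 0.0) { // hard minimum
    int k = int(std::min_element(d.begin(), d.end()) - d.begin());
    grad_ref[0] = ux[k]; grad_ref[1] = uy[k]; grad_ref[2] = uz[k];
    return dmin;
  }
  double zsum = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
  for (int i = 0; i < nsurf; ++i) {
    double w = std::exp(-beta * (d[i] - dmin));
    zsum += w; gx += w * ux[i]; gy += w * uy[i]; gz += w * uz[i];
  }
  grad_ref[0] = gx / zsum; grad_ref[1] = gy / zsum; grad_ref[2] = gz / zsum;
  return dmin - std::log(zsum) / beta;
}

// --- force field container ----------------------------------------------
struct FFData {
  bool use_ff;
  std::vector<int> b1, b2;            // bonds
  std::vector<double> bkb, br0;
  std::vector<int> a1, a2, a3;        // angles (end, apex, end)
  std::vector<double> ak, at0;        // at0 in rad
  std::vector<double> q;              // charges
  std::vector<int> type;              // 0-based species index
  std::vector<double> sig, eps;       // ntype x ntype, row-major
  int ntype;
  std::vector<std::vector<int>> excl; // sorted per-atom exclusion lists
  double cutoff, kC;
  bool shifted_force, use_coulomb, use_lj;
};

static bool is_excluded(const FFData& ff, int i, int j) {
  const std::vector<int>& e = ff.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

static void build_pairs(const std::vector<double>& pos, int n,
                        const double* box, const int* per,
                        const FFData& ff, double rlist, PairList& pl) {
  pl.i.clear(); pl.j.clear();
  double rl2 = rlist * rlist;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d[3] = { pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                      pos[3 * i + 2] - pos[3 * j + 2] };
      min_image(d, box, per);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < rl2 && !is_excluded(ff, i, j)) { pl.i.push_back(i); pl.j.push_back(j); }
    }
}

struct ExtData {
  int kind;                  // 0 = none
  std::vector<double> par;
  std::vector<int> group;    // atoms whose COM defines the coordinate
  std::vector<int> surf;     // reference atoms
  double beta;               // softmin sharpness, A^-1 (<=0 hard)
};

// Compute systematic forces (FF + external potential; no bias, no wall).
// Returns potential energy; breakdown: bond, angle, lj, coul, ext.
static double compute_forces(const std::vector<double>& pos, int n,
                             const double* box, const int* per,
                             const FFData& ff, const ExtData& ext,
                             const std::vector<double>& mass,
                             const PairList& pl,
                             std::vector<double>& f, double* breakdown) {
  std::fill(f.begin(), f.end(), 0.0);
  double eb = 0, ea = 0, elj = 0, ec = 0, ee = 0;
  if (ff.use_ff) {
    // bonds
    for (size_t m = 0; m < ff.b1.size(); ++m) {
      int i = ff.b1[m], j = ff.b2[m];
      double d[3] = { pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                      pos[3 * i + 2] - pos[3 * j + 2] };
      min_image(d, box, per);
      double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (r < 1e-6) stop("overlapping bonded atoms (r < 1e-6 A)");
      double dr = r - ff.br0[m];
      eb += 0.5 * ff.bkb[m] * dr * dr;
      double fac = -ff.bkb[m] * dr / r;
      for (int k = 0; k < 3; ++k) { f[3 * i + k] += fac * d[k]; f[3 * j + k] -= fac * d[k]; }
    }
    // angles: (a1, a2=apex, a3)
    for (size_t m = 0; m < ff.a1.size(); ++m) {
      int i = ff.a1[m], j = ff.a2[m], k = ff.a3[m];
      double A[3] = { pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                      pos[3 * i + 2] - pos[3 * j + 2] };
      double B[3] = { pos[3 * k] - pos[3 * j], pos[3 * k + 1] - pos[3 * j + 1],
                      pos[3 * k + 2] - pos[3 * j + 2] };
      min_image(A, box, per); min_image(B, box, per);
      double la = std::sqrt(A[0] * A[0] + A[1] * A[1] + A[2] * A[2]);
      double lb = std::sqrt(B[0] * B[0] + B[1] * B[1] + B[2] * B[2]);
      double ct = (A[0] * B[0] + A[1] * B[1] + A[2] * B[2]) / (la * lb);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
      double dth = th - ff.at0[m];
      ea += 0.5 * ff.ak[m] * dth * dth;
      double coef = -ff.ak[m] * dth;
      for (int c = 0; c < 3; ++c) {
        double dthdi = (ct * A[c] / la - B[c] / lb) / (la * st);
        double dthdk = (ct * B[c] / lb - A[c] / la) / (lb * st);
        f[3 * i + c] += coef * dthdi;
        f[3 * k + c] += coef * dthdk;
        f[3 * j + c] -= coef * (dthdi + dthdk);
      }
    }
    // non-bonded
    double rc = ff.cutoff, rc2 = rc * rc;
    for (size_t m = 0; m < pl.i.size(); ++m) {
      int i = pl.i[m], j = pl.j[m];
      double d[3] = { pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                      pos[3 * i + 2] - pos[3 * j + 2] };
      min_image(d, box, per);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-6) stop("overlapping non-bonded atoms (r < 1e-6 A)");
      double ftot = 0.0;
      if (ff.use_lj) {
        int ti = ff.type[i], tj = ff.type[j];
        double sg = ff.sig[ti * ff.ntype + tj], ep = ff.eps[ti * ff.ntype + tj];
        if (ep > 0.0) {
          double sr6 = std::pow(sg / r, 6.0), sr12 = sr6 * sr6;
          double u = 4.0 * ep * (sr12 - sr6);
          double du = -4.0 * ep * (12.0 * sr12 - 6.0 * sr6) / r; // dU/dr
          if (ff.shifted_force) {
            double src6 = std::pow(sg / rc, 6.0), src12 = src6 * src6;
            double urc = 4.0 * ep * (src12 - src6);
            double durc = -4.0 * ep * (12.0 * src12 - 6.0 * src6) / rc;
            u = u - urc - (r - rc) * durc;
            du = du - durc;
          }
          elj += u; ftot += -du;
        }
      }
      if (ff.use_coulomb) {
        double qq = ff.kC * ff.q[i] * ff.q[j];
        if (qq != 0.0) {
          double u = qq / r, du = -qq / r2;
          if (ff.shifted_force) {
            double urc = qq / rc, durc = -qq / (rc * rc);
            u = u - urc - (r - rc) * durc;
            du = du - durc;
          }
          ec += u; ftot += -du;
        }
      }
      double fac = ftot / r;
      for (int c = 0; c < 3; ++c) { f[3 * i + c] += fac * d[c]; f[3 * j + c] -= fac * d[c]; }
    }
  }
  // external potential along the COM-to-surface separation
  if (ext.kind > 0) {
    double M = 0.0, com[3] = { 0, 0, 0 };
    for (size_t g = 0; g < ext.group.size(); ++g) {
      int i = ext.group[g];
      M += mass[i];
      for (int c = 0; c < 3; ++c) com[c] += mass[i] * pos[3 * i + c];
    }
    for (int c = 0; c < 3; ++c) com[c] /= M;
    std::vector<double> sp(3 * ext.surf.size());
    for (size_t g = 0; g < ext.surf.size(); ++g)
      for (int c = 0; c < 3; ++c) sp[3 * g + c] = pos[3 * ext.surf[g] + c];
    double grad[3];
    double s = ssd_value_grad(com, sp, (int)ext.surf.size(), box, per, ext.beta, grad);
    double u, duds;
    ext_potential(ext.kind, ext.par, s, &u, &duds);
    ee += u;
    for (size_t g = 0; g < ext.group.size(); ++g) {
      int i = ext.group[g];
      double w = mass[i] / M;
      for (int c = 0; c < 3; ++c) f[3 * i + c] -= duds * w * grad[c];
    }
  }
  breakdown[0] = eb; breakdown[1] = ea; breakdown[2] = elj;
  breakdown[3] = ec; breakdown[4] = ee;
  return eb + ea + elj + ec + ee;
}

// --- unpack helpers ------------------------------------------------------
static FFData unpack_ff(List ffl, int n) {
  FFData ff;
  ff.use_ff = as<bool>(ffl["use_ff"]);
  ff.excl.assign(n, std::vector<int>());
  if (ff.use_ff) {
    IntegerMatrix bonds = ffl["bonds"];
    NumericVector bkb = ffl["bond_kb"], br0 = ffl["bond_r0"];
    for (int m = 0; m < bonds.nrow(); ++m) {
      ff.b1.push_back(bonds(m, 0)); ff.b2.push_back(bonds(m, 1));
      ff.bkb.push_back(bkb[m]); ff.br0.push_back(br0[m]);
    }
    IntegerMatrix ang = ffl["angles"];
    NumericVector ak = ffl["angle_k"], at0 = ffl["angle_theta0"];
    for (int m = 0; m < ang.nrow(); ++m) {
      ff.a1.push_back(ang(m, 0)); ff.a2.push_back(ang(m, 1)); ff.a3.push_back(ang(m, 2));
      ff.ak.push_back(ak[m]); ff.at0.push_back(at0[m]);
    }
    ff.q = as<std::vector<double>>(ffl["charge"]);
    ff.type = as<std::vector<int>>(ffl["type"]);
    NumericMatrix sig = ffl["sigma"], eps = ffl["epsilon"];
    ff.ntype = sig.nrow();
    ff.sig.resize(ff.ntype * ff.ntype); ff.eps.resize(ff.ntype * ff.ntype);
    for (int a = 0; a < ff.ntype; ++a)
      for (int b = 0; b < ff.ntype; ++b) {
        ff.sig[a * ff.ntype + b] = sig(a, b);
        ff.eps[a * ff.ntype + b] = eps(a, b);
      }
    List ex = ffl["exclusions"];
    for (int i = 0; i < n; ++i) {
      IntegerVector e = ex[i];
      ff.excl[i] = as<std::vector<int>>(e);
      std::sort(ff.excl[i].begin(), ff.excl[i].end());
    }
    ff.cutoff = as<double>(ffl["cutoff"]);
    ff.kC = as<double>(ffl["kC"]);
    ff.shifted_force = as<bool>(ffl["shifted_force"]);
    ff.use_coulomb = as<bool>(ffl["use_coulomb"]);
    ff.use_lj = as<bool>(ffl["use_lj"]);
  } else {
    ff.cutoff = 0.0; ff.kC = 0.0;
    ff.shifted_force = true; ff.use_coulomb = false; ff.use_lj = false;
    ff.ntype = 0;
  }
  return ff;
}

static ExtData unpack_ext(List el) {
  ExtData e;
  e.kind = as<int>(el["kind"]);
  if (e.kind > 0) {
    e.par = as<std::vector<double>>(el["params"]);
    e.group = as<std::vector<int>>(el["group"]);
    e.surf = as<std::vector<int>>(el["surf"]);
    e.beta = as<double>(el["beta"]);
  }
  return e;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos_, NumericVector box_,
                       IntegerVector periodic_, List ffl, List extl,
                       NumericVector mass_) {
  int n = pos_.nrow();
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) pos[3 * i + c] = pos_(i, c);
  double box[3] = { box_[0], box_[1], box_[2] };
  int per[3] = { periodic_[0], periodic_[1], periodic_[2] };
  FFData ff = unpack_ff(ffl, n);
  ExtData ext = unpack_ext(extl);
  std::vector<double> mass = as<std::vector<double>>(mass_);
  PairList pl;
  if (ff.use_ff) build_pairs(pos, n, box, per, ff, ff.cutoff, pl);
  std::vector<double> f(3 * n);
  double bd[5];
  double e = compute_forces(pos, n, box, per, ff, ext, mass, pl, f, bd);
  NumericMatrix fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) fout(i, c) = f[3 * i + c];
  return List::create(_["energy"] = e, _["forces"] = fout,
                      _["breakdown"] = NumericVector::create(
                        _["bond"] = bd[0], _["angle"] = bd[1], _["lj"] = bd[2],
                        _["coulomb"] = bd[3], _["external"] = bd[4]));
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos_, NumericVector box_,
                  IntegerVector periodic_, List ffl, List extl,
                  NumericVector mass_, NumericMatrix mobile_,
                  int max_steps, double force_tol, double init_step,
                  double skin, int nlist_every) {
  int n = pos_.nrow();
  std::vector<double> pos(3 * n), mob(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      pos[3 * i + c] = pos_(i, c);
      mob[3 * i + c] = mobile_(i, c);
    }
  double box[3] = { box_[0], box_[1], box_[2] };
  int per[3] = { periodic_[0], periodic_[1], periodic_[2] };
  FFData ff = unpack_ff(ffl, n);
  ExtData ext = unpack_ext(extl);
  std::vector<double> mass = as<std::vector<double>>(mass_);
  PairList pl;
  std::vector<double> f(3 * n), trial(3 * n), ftrial(3 * n);
  double bd[5];
  if (ff.use_ff) build_pairs(pos, n, box, per, ff, ff.cutoff + skin, pl);
  double e = compute_forces(pos, n, box, per, ff, ext, mass, pl, f, bd);
  if (!std::isfinite(e)) stop("non-finite energy at start of minimisation");
  std::vector<double> etrace;
  etrace.push_back(e);
  double alpha = init_step;
  int step = 0;
  double fmax = 0.0;
  for (step = 0; step < max_steps; ++step) {
    fmax = 0.0;
    for (int i = 0; i < 3 * n; ++i) {
      double fi = std::fabs(f[i] * mob[i]);
      if (fi > fmax) fmax = fi;
    }
    if (fmax < force_tol || alpha < 1e-10) break;
    for (int i = 0; i < 3 * n; ++i)
      trial[i] = pos[i] + alpha * f[i] * mob[i] / fmax;
    if (ff.use_ff && (step % nlist_every == 0))
      build_pairs(trial, n, box, per, ff, ff.cutoff + skin, pl);
    double et = compute_forces(trial, n, box, per, ff, ext, mass, pl, ftrial, bd);
    if (et < e) {
      pos.swap(trial); f.swap(ftrial); e = et;
      alpha *= 1.2;
    } else {
      alpha *= 0.5;
    }
    etrace.push_back(e);
  }
  NumericMatrix pout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) pout(i, c) = pos[3 * i + c];
  return List::create(_["positions"] = pout, _["energy"] = e,
                      _["energy_trace"] = wrap(etrace),
                      _["steps"] = step, _["max_force"] = fmax);
}

// --- bias grid -----------------------------------------------------------
struct BiasGrid {
  double lo, hi, ds;
  int nb;
  std::vector<double> v, dv;
  void init(double lo_, double hi_, int nb_) {
    lo = lo_; hi = hi_; nb = nb_; ds = (hi - lo) / (nb - 1);
    v.assign(nb, 0.0); dv.assign(nb, 0.0);
  }
  void add_hill(double s0, double sig, double w) {
    for (int i = 0; i < nb; ++i) {
      double s = lo + i * ds, x = s - s0;
      double g = w * std::exp(-x * x / (2.0 * sig * sig));
      v[i] += g;
      dv[i] += -x / (sig * sig) * g;
    }
  }
  void eval(double s, double* u, double* duds) const {
    if (s <= lo) { *u = v[0]; *duds = 0.0; return; }
    if (s >= hi) { *u = v[nb - 1]; *duds = 0.0; return; }
    double x = (s - lo) / ds;
    int i = (int)x;
    if (i >= nb - 1) i = nb - 2;
    double fr = x - i;
    *u = v[i] * (1 - fr) + v[i + 1] * fr;
    *duds = dv[i] * (1 - fr) + dv[i + 1] * fr;
  }
};

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos_, NumericMatrix vel_, NumericVector mass_,
                NumericVector box_, IntegerVector periodic_,
                NumericMatrix mobile_, List ffl, List extl, List metadl,
                List runl) {
  int n = pos_.nrow();
  std::vector<double> pos(3 * n), vel(3 * n), mob(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      pos[3 * i + c] = pos_(i, c);
      vel[3 * i + c] = vel_(i, c);
      mob[3 * i + c] = mobile_(i, c);
    }
  double box[3] = { box_[0], box_[1], box_[2] };
  int per[3] = { periodic_[0], periodic_[1], periodic_[2] };
  FFData ff = unpack_ff(ffl, n);
  ExtData ext = unpack_ext(extl);
  std::vector<double> mass = as<std::vector<double>>(mass_);

  // run parameters
  double dt = as<double>(runl["dt_fs"]) / TCONV;     // internal units
  int nsteps = as<int>(runl["nsteps"]);
  int thermo = as<int>(runl["thermostat"]);          // 0 none, 1 vrescale, 2 langevin
  double T0 = as<double>(runl["temperature"]);
  double tau_t = as<double>(runl["tau_t_ps"]) * PS;
  double gamma = as<double>(runl["gamma_ps"]) / PS;
  int stride = as<int>(runl["stride"]);
  int log_stride = as<int>(runl["log_stride"]);
  double skin = as<double>(runl["skin"]);
  int nlist_every = as<int>(runl["nlist_every"]);

  // degrees of freedom = mobile components
  int ndof = 0;
  for (int i = 0; i < 3 * n; ++i) if (mob[i] > 0) ++ndof;
  if (ndof == 0) stop("no mobile degrees of freedom");

  // metadynamics setup
  bool metad_on = as<bool>(metadl["on"]);
  std::vector<int> cv_group, cv_surf;
  double cv_beta = 0.0, omega = 0.0, sigma_g = 0.0;
  int tau_steps = 0, burnin = 0, block_steps = 0, cv_stride = 1;
  double wall_a = 0.0, wall_kappa = 0.0;
  bool wall_two_sided = false;
  double bin_lo = 0.0, bin_w = 0.0;
  int nbins = 0;
  BiasGrid grid;
  std::vector<double> hill_t, hill_s;
  std::vector<double> fbin_sum, fbin_cnt; // nbins x nblocks, column major
  int nblocks = 0;
  if (metad_on) {
    cv_group = as<std::vector<int>>(metadl["group"]);
    cv_surf = as<std::vector<int>>(metadl["surf"]);
    cv_beta = as<double>(metadl["beta"]);
    omega = as<double>(metadl["omega"]);
    sigma_g = as<double>(metadl["sigma_g"]);
    tau_steps = as<int>(metadl["tau_steps"]);
    wall_a = as<double>(metadl["wall_a"]);
    wall_kappa = as<double>(metadl["wall_kappa"]);
    wall_two_sided = as<bool>(metadl["wall_two_sided"]);
    bin_lo = as<double>(metadl["bin_lo"]);
    bin_w = as<double>(metadl["bin_w"]);
    nbins = as<int>(metadl["nbins"]);
    burnin = as<int>(metadl["burnin_steps"]);
    block_steps = as<int>(metadl["block_steps"]);
    cv_stride = as<int>(metadl["cv_stride"]);
    if (block_steps <= 0) block_steps = nsteps;
    nblocks = (nsteps - burnin + block_steps - 1) / block_steps;
    if (nblocks < 1) nblocks = 1;
    fbin_sum.assign((size_t)nbins * nblocks, 0.0);
    fbin_cnt.assign((size_t)nbins * nblocks, 0.0);
    double ghi = std::max(wall_a + 10.0 * sigma_g, bin_lo + nbins * bin_w + 5.0 * sigma_g);
    grid.init(0.0, ghi, std::max(200, (int)(ghi / (sigma_g / 5.0))));
  }

  PairList pl;
  if (ff.use_ff) build_pairs(pos, n, box, per, ff, ff.cutoff + skin, pl);
  std::vector<double> f(3 * n);
  double bd[5];
  double epot = compute_forces(pos, n, box, per, ff, ext, mass, pl, f, bd);
  if (!std::isfinite(epot)) stop("non-finite energy at start of dynamics");

  // storage
  int nframes = nsteps / stride + 1;
  NumericMatrix frames(nframes, 3 * n);
  std::vector<double> frame_t;
  int nlog = nsteps / log_stride + 1;
  NumericMatrix elog(nlog, 6);
  std::vector<double> cv_t, cv_s, cv_f, cv_eb;

  RNGScope rngscope;
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  // helper lambdas ---------------------------------------------------------
  auto kinetic = [&]() {
    double ek = 0.0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        if (mob[3 * i + c] > 0) ek += 0.5 * mass[i] * vel[3 * i + c] * vel[3 * i + c];
    return ek;
  };

  // metadynamics state used across the step
  double ebias_cur = 0.0;
  int ifr = 0, ilog = 0;

  auto apply_bias = [&](bool accumulate, int step) {
    // compute CV, add bias+wall forces in-place into f, accumulate mean force
    if (!metad_on) return;
    double M = 0.0, com[3] = { 0, 0, 0 };
    for (size_t g = 0; g < cv_group.size(); ++g) {
      int i = cv_group[g];
      M += mass[i];
      for (int c = 0; c < 3; ++c) com[c] += mass[i] * pos[3 * i + c];
    }
    for (int c = 0; c < 3; ++c) com[c] /= M;
    std::vector<double> sp(3 * cv_surf.size());
    for (size_t g = 0; g < cv_surf.size(); ++g)
      for (int c = 0; c < 3; ++c) sp[3 * g + c] = pos[3 * cv_surf[g] + c];
    double grad[3];
    double s = ssd_value_grad(com, sp, (int)cv_surf.size(), box, per, cv_beta, grad);

    // unbiased generalised force F_s = (grad_s . F_sys) / |grad_s|^2
    // ds/dx_i = (m_i/M) * grad for group atoms
    double num = 0.0, den = 0.0;
    for (size_t g = 0; g < cv_group.size(); ++g) {
      int i = cv_group[g];
      double w = mass[i] / M;
      for (int c = 0; c < 3; ++c) {
        double gi = w * grad[c];
        num += gi * f[3 * i + c];
        den += gi * gi;
      }
    }
    double fs = (den > 1e-12) ? num / den : 0.0;
    if (accumulate && step >= burnin) {
      int ib = (int)((s - bin_lo) / bin_w);
      if (ib >= 0 && ib < nbins) {
        int blk = (step - burnin) / block_steps;
        if (blk >= nblocks) blk = nblocks - 1;
        fbin_sum[(size_t)blk * nbins + ib] += fs;
        fbin_cnt[(size_t)blk * nbins + ib] += 1.0;
      }
      if (step % cv_stride == 0) {
        cv_t.push_back(step * dt / PS);
        cv_s.push_back(s);
        cv_f.push_back(fs);
      }
    }
    // hill deposition
    if (accumulate && tau_steps > 0 && step > 0 && (step % tau_steps == 0) && omega > 0.0) {
      grid.add_hill(s, sigma_g, omega);
      hill_t.push_back(step * dt / PS);
      hill_s.push_back(s);
    }
    // bias + wall forces
    double ub, dub;
    grid.eval(s, &ub, &dub);
    double uw = 0.0, duw = 0.0;
    double x = s - wall_a;
    if (x > 0.0 || (wall_two_sided && x < 0.0)) {
      uw = wall_kappa * x * x * x * x;
      duw = 4.0 * wall_kappa * x * x * x;
    }
    ebias_cur = ub + uw;
    if (accumulate && step >= burnin && step % cv_stride == 0)
      cv_eb.push_back(ub);
    double dtot = dub + duw;
    for (size_t g = 0; g < cv_group.size(); ++g) {
      int i = cv_group[g];
      double w = mass[i] / M;
      for (int c = 0; c < 3; ++c) f[3 * i + c] -= dtot * w * grad[c];
    }
  };

  apply_bias(false, 0);

  for (int step = 0; step <= nsteps; ++step) {
    // logging / frames
    if (step % stride == 0 && ifr < nframes) {
      for (int i = 0; i < 3 * n; ++i) frames(ifr, i) = pos[i];
      frame_t.push_back(step * dt / PS);
      ++ifr;
    }
    if (step % log_stride == 0 && ilog < nlog) {
      double ek = kinetic();
      elog(ilog, 0) = step;
      elog(ilog, 1) = step * dt / PS;
      elog(ilog, 2) = epot;
      elog(ilog, 3) = ek;
      elog(ilog, 4) = (ndof > 0) ? 2.0 * ek / (ndof * KB) : 0.0;
      elog(ilog, 5) = ebias_cur;
      ++ilog;
    }
    if (step == nsteps) break;
    if (!std::isfinite(epot) || epot > 1e6)
      stop("energy divergence at step %d (E_pot = %g kJ/mol)", step, epot);

    // --- integrate one step (velocity Verlet / BAOAB) ---
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        if (mob[3 * i + c] > 0)
          vel[3 * i + c] += 0.5 * dt * f[3 * i + c] / mass[i];
    if (thermo == 2) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          if (mob[3 * i + c] > 0) pos[3 * i + c] += 0.5 * dt * vel[3 * i + c];
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(KB * T0 / mass[i]);
        for (int c = 0; c < 3; ++c)
          if (mob[3 * i + c] > 0)
            vel[3 * i + c] = c1 * vel[3 * i + c] + c2 * sd * norm_rand();
      }
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          if (mob[3 * i + c] > 0) pos[3 * i + c] += 0.5 * dt * vel[3 * i + c];
    } else {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          if (mob[3 * i + c] > 0) pos[3 * i + c] += dt * vel[3 * i + c];
    }
    if (ff.use_ff && ((step + 1) % nlist_every == 0))
      build_pairs(pos, n, box, per, ff, ff.cutoff + skin, pl);
    epot = compute_forces(pos, n, box, per, ff, ext, mass, pl, f, bd);
    apply_bias(true, step + 1);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        if (mob[3 * i + c] > 0)
          vel[3 * i + c] += 0.5 * dt * f[3 * i + c] / mass[i];
    if (thermo == 1) {
      double ek = kinetic();
      double tinst = 2.0 * ek / (ndof * KB);
      if (tinst > 1e-12) {
        double lam2 = 1.0 + dt / tau_t * (T0 / tinst - 1.0);
        double lam = std::sqrt(std::max(0.0, lam2));
        for (int i = 0; i < 3 * n; ++i)
          if (mob[i] > 0) vel[i] *= lam;
      }
    }
  }

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { pout(i, c) = pos[3 * i + c]; vout(i, c) = vel[3 * i + c]; }
  List metout = R_NilValue;
  if (metad_on) {
    NumericMatrix fbs(nbins, nblocks), fbc(nbins, nblocks);
    for (int b = 0; b < nblocks; ++b)
      for (int i = 0; i < nbins; ++i) {
        fbs(i, b) = fbin_sum[(size_t)b * nbins + i];
        fbc(i, b) = fbin_cnt[(size_t)b * nbins + i];
      }
    metout = List::create(
      _["hill_t"] = wrap(hill_t), _["hill_s"] = wrap(hill_s),
      _["cv_t"] = wrap(cv_t), _["cv_s"] = wrap(cv_s),
      _["cv_f"] = wrap(cv_f), _["cv_ebias"] = wrap(cv_eb),
      _["fbin_sum"] = fbs, _["fbin_cnt"] = fbc,
      _["bin_lo"] = bin_lo, _["bin_w"] = bin_w, _["nbins"] = nbins);
  }
  return List::create(_["frames"] = frames, _["frame_times"] = wrap(frame_t),
                      _["elog"] = elog, _["positions"] = pout,
                      _["velocities"] = vout, _["metad"] = metout);
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos_, NumericVector box_,
                                 IntegerVector periodic_, double cutoff) {
  int n = pos_.nrow();
  double box[3] = { box_[0], box_[1], box_[2] };
  int per[3] = { periodic_[0], periodic_[1], periodic_[2] };
  double rc2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d[3] = { pos_(i, 0) - pos_(j, 0), pos_(i, 1) - pos_(j, 1),
                      pos_(i, 2) - pos_(j, 2) };
      min_image(d, box, per);
      if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < rc2) {
        ii.push_back(i + 1); jj.push_back(j + 1); // 1-based for R
      }
    }
  IntegerMatrix out(ii.size(), 2);
  for (size_t m = 0; m < ii.size(); ++m) { out(m, 0) = ii[m]; out(m, 1) = jj[m]; }
  return out;
}

// [[Rcpp::export]]
List cpp_ssd(NumericVector xref_, NumericMatrix surf_, NumericVector box_,
             IntegerVector periodic_, double beta) {
  double xref[3] = { xref_[0], xref_[1], xref_[2] };
  int ns = surf_.nrow();
  std::vector<double> sp(3 * ns);
  for (int i = 0; i < ns; ++i)
    for (int c = 0; c < 3; ++c) sp[3 * i + c] = surf_(i, c);
  double box[3] = { box_[0], box_[1], box_[2] };
  int per[3] = { periodic_[0], periodic_[1], periodic_[2] };
  double grad[3];
  double s = ssd_value_grad(xref, sp, ns, box, per, beta, grad);
  return List::create(_["s"] = s,
                      _["grad"] = NumericVector::create(grad[0], grad[1], grad[2]));
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_distances_min(NumericMatrix a_, NumericMatrix b_,
                                     NumericVector box_, IntegerVector periodic_) {
  // for each row of a, distance to nearest row of b (min-image)
  int na = a_.nrow(), nb = b_.nrow();
  double box[3] = { box_[0], box_[1], box_[2] };
  int per[3] = { periodic_[0], periodic_[1], periodic_[2] };
  NumericMatrix out(na, 1);
  for (int i = 0; i < na; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double d[3] = { a_(i, 0) - b_(j, 0), a_(i, 1) - b_(j, 1), a_(i, 2) - b_(j, 2) };
      min_image(d, box, per);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < dmin) dmin = r2;
    }
    out(i, 0) = std::sqrt(dmin);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_all_pair_dists(NumericMatrix a_, NumericMatrix b_,
                                 NumericVector box_, IntegerVector periodic_,
                                 double rmax, bool same_group) {
  // flat vector of all min-image distances < rmax between rows of a and b
  int na = a_.nrow(), nb = b_.nrow();
  double box[3] = { box_[0], box_[1], box_[2] };
  int per[3] = { periodic_[0], periodic_[1], periodic_[2] };
  double r2max = rmax * rmax;
  std::vector<double> out;
  for (int i = 0; i < na; ++i) {
    int j0 = same_group ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      double d[3] = { a_(i, 0) - b_(j, 0), a_(i, 1) - b_(j, 1), a_(i, 2) - b_(j, 2) };
      min_image(d, box, per);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < r2max) out.push_back(std::sqrt(r2));
    }
  }
  return wrap(out);
}
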