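// Metropolis Monte Carlo engine for periodic Lennard-Jones / point-charge
// fluids of rigid molecules. All energies kJ/mol, lengths nm, charges e.
//
// Conventions shared with the R layer:
//   - minimum-image convention in a cubic box; r_cut must satisfy
//     r_cut <= box/2 (the R wrappers enforce/clamp this);
//   - LJ interactions are truncated (not shifted) at r_cut with an optional
//     analytic isotropic tail correction for energy and virial;
//   - electrostatics are truncated-and-shifted Coulomb (no Ewald);
//   - alchemical runs scale only solute-solvent interactions: LJ through the
//     1-1-48 softcore, Coulomb linearly in lambda.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double COULOMB_K = 138.935458;   // kJ mol^-1 nm e^-2
static const double PV_CONV   = 0.0602214076; // kJ mol^-1 per bar nm^3
static const double GAS_R     = 8.314462618e-3; // kJ mol^-1 K^-1
static const double MASS_CONV = 1.66053907;   // (g/mol)/nm^3 -> kg/m^3

struct Engine {
  int nsites, nmol, ntype;
  std::vector<double> x, y, z;     // site coordinates
  std::vector<int> mol, typ;
  std::vector<double> q;
  std::vector<double> epsm, sigm;  // ntype x ntype combined parameters
  std::vector< std::vector<int> > mol_sites;
  double box, rcut;
  double rc_eff, rc2_eff, half_box; // cached; refresh via set_box()
  bool tail, any_charge;
  // alchemical state: solute molecule id (-1 = none), simulation lambda
  int smol;
  double lam;
  double sc_alpha; int sc_pow; // softcore distance power (48)

  inline double eps(int a, int b) const { return epsm[a * ntype + b]; }
  inline double sig(int a, int b) const { return sigm[a * ntype + b]; }

  void set_box(double b) {
    box = b;
    half_box = 0.5 * b;
    rc_eff = rcut < half_box ? rcut : half_box * 0.9999;
    rc2_eff = rc_eff * rc_eff;
  }

  inline double mi(double d) const {
    if (d >  half_box) d -= box;
    else if (d < -half_box) d += box;
    return d;
  }

  inline double lj(double e, double s, double r2) const {
    double sr2 = s * s / r2, sr6 = sr2 * sr2 * sr2;
    return 4.0 * e * sr6 * (sr6 - 1.0);
  }

  // 1-1-48 softcore: r_sc^p = alpha sigma^p (1-lambda) + r^p, V = lambda lj(r_sc)
  inline double softcore(double e, double s, double r2, double l) const {
    if (l <= 0.0) return 0.0;
    if (l >= 1.0) return lj(e, s, r2);
    double rp = std::pow(r2, sc_pow / 2.0);
    double sp = std::pow(s * s, sc_pow / 2.0);
    double rscp = sc_alpha * sp * (1.0 - l) + rp;
    double rsc2 = std::pow(rscp, 2.0 / sc_pow);
    return l * lj(e, s, rsc2);
  }

  // pair energy of sites i, j at current lambda bookkeeping
  inline double pair(int i, int j) const {
    double dx = mi(x[i] - x[j]), dy = mi(y[i] - y[j]), dz = mi(z[i] - z[j]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2_eff) return 0.0;
    const double rc = rc_eff;
    bool cross = smol >= 0 && ((mol[i] == smol) != (mol[j] == smol));
    double u;
    if (cross) {
      u = softcore(eps(typ[i], typ[j]), sig(typ[i], typ[j]), r2, lam);
      if (any_charge && q[i] != 0.0 && q[j] != 0.0) {
        double r = std::sqrt(r2);
        u += lam * COULOMB_K * q[i] * q[j] * (1.0 / r - 1.0 / rc);
      }
    } else {
      u = lj(eps(typ[i], typ[j]), sig(typ[i], typ[j]), r2);
      if (any_charge && q[i] != 0.0 && q[j] != 0.0) {
        double r = std::sqrt(r2);
        u += COULOMB_K * q[i] * q[j] * (1.0 / r - 1.0 / rc);
      }
    }
    return u;
  }

  inline double effective_rcut() const { return rc_eff; }

  // fast path: plain LJ, no charges, no solute scaling
  inline bool simple() const { return !any_charge && smol < 0; }

  inline double lj_pair_fast(int i, int j) const {
    double dx = mi(x[i] - x[j]), dy = mi(y[i] - y[j]), dz = mi(z[i] - z[j]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2_eff) return 0.0;
    double s = sigm[typ[i] * ntype + typ[j]];
    double sr2 = s * s / r2, sr6 = sr2 * sr2 * sr2;
    return 4.0 * epsm[typ[i] * ntype + typ[j]] * sr6 * (sr6 - 1.0);
  }

  double mol_energy(int m) const {
    double u = 0.0;
    if (simple()) {
      for (int i : mol_sites[m])
        for (int j = 0; j < nsites; ++j)
          if (mol[j] != m) u += lj_pair_fast(i, j);
      return u;
    }
    for (int i : mol_sites[m])
      for (int j = 0; j < nsites; ++j)
        if (mol[j] != m) u += pair(i, j);
    return u;
  }

  double pair_sum() const {
    double u = 0.0;
    if (simple()) {
      for (int i = 0; i < nsites - 1; ++i)
        for (int j = i + 1; j < nsites; ++j)
          if (mol[i] != mol[j]) u += lj_pair_fast(i, j);
      return u;
    }
    for (int i = 0; i < nsites - 1; ++i)
      for (int j = i + 1; j < nsites; ++j)
        if (mol[i] != mol[j]) u += pair(i, j);
    return u;
  }

  // analytic isotropic LJ tail correction; counts all site pairs, intramolecular
  // included (the standard mixture approximation). Solute-solvent softcore
  // pairs are excluded from the tail when decoupling (smol >= 0): only the
  // fully coupled solvent-solvent contribution is corrected.
  double tail_energy(double volume) const {
    if (!tail) return 0.0;
    double rc = effective_rcut();
    std::vector<double> cnt(ntype, 0.0);
    int ns = 0;
    for (int i = 0; i < nsites; ++i) {
      if (smol >= 0 && mol[i] == smol) continue;
      cnt[typ[i]] += 1.0; ++ns;
    }
    double acc = 0.0;
    for (int a = 0; a < ntype; ++a)
      for (int b = 0; b < ntype; ++b) {
        if (cnt[a] == 0.0 || cnt[b] == 0.0) continue;
        double e = eps(a, b), s = sig(a, b);
        if (e == 0.0) continue;
        double sr3 = std::pow(s / rc, 3.0), sr9 = sr3 * sr3 * sr3;
        acc += cnt[a] * cnt[b] * e * std::pow(s, 3.0) * (sr9 / 3.0 - sr3);
      }
    (void)ns;
    return 8.0 * M_PI / (3.0 * volume) * acc;
  }

  double total_energy() const { return pair_sum() + tail_energy(box * box * box); }
};

static Engine make_engine(NumericMatrix pos, IntegerVector mol, IntegerVector typ,
                          NumericVector q, NumericMatrix epsm, NumericMatrix sigm,
                          double box, double rcut, bool tail,
                          int smol = -1, double lam = 1.0,
                          double sc_alpha = 0.003, int sc_pow = 48) {
  Engine E;
  E.nsites = pos.nrow();
  E.ntype = epsm.nrow();
  E.rcut = rcut; E.set_box(box); E.tail = tail;
  E.smol = smol; E.lam = lam; E.sc_alpha = sc_alpha; E.sc_pow = sc_pow;
  E.x.resize(E.nsites); E.y.resize(E.nsites); E.z.resize(E.nsites);
  E.mol.resize(E.nsites); E.typ.resize(E.nsites); E.q.resize(E.nsites);
  int nmol = 0;
  E.any_charge = false;
  for (int i = 0; i < E.nsites; ++i) {
    E.x[i] = pos(i, 0); E.y[i] = pos(i, 1); E.z[i] = pos(i, 2);
    E.mol[i] = mol[i]; E.typ[i] = typ[i]; E.q[i] = q[i];
    if (q[i] != 0.0) E.any_charge = true;
    if (mol[i] + 1 > nmol) nmol = mol[i] + 1;
  }
  E.nmol = nmol;
  E.mol_sites.assign(nmol, std::vector<int>());
  for (int i = 0; i < E.nsites; ++i) E.mol_sites[mol[i]].push_back(i);
  E.epsm.assign(epsm.begin(), epsm.end());
  E.sigm.assign(sigm.begin(), sigm.end());
  return E;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, IntegerVector mol, IntegerVector typ,
                        NumericVector q, NumericMatrix epsm, NumericMatrix sigm,
                        double box, double rcut, bool tail) {
  Engine E = make_engine(pos, mol, typ, q, epsm, sigm, box, rcut, tail);
  return E.total_energy();
}

// [[Rcpp::export]]
double cpp_softcore_lj(double eps, double sigma, double r, double lambda,
                       double alpha, int dist_pow) {
  Engine E; E.sc_alpha = alpha; E.sc_pow = dist_pow; E.ntype = 1;
  return E.softcore(eps, sigma, r * r, lambda);
}

static void rotate_molecule(Engine &E, int m, double ang, double ux, double uy, double uz) {
  // Rodrigues rotation of molecule m about its centroid
  const std::vector<int> &ss = E.mol_sites[m];
  double cx = 0, cy = 0, cz = 0;
  for (int i : ss) { cx += E.x[i]; cy += E.y[i]; cz += E.z[i]; }
  cx /= ss.size(); cy /= ss.size(); cz /= ss.size();
  double c = std::cos(ang), s = std::sin(ang);
  for (int i : ss) {
    double px = E.x[i] - cx, py = E.y[i] - cy, pz = E.z[i] - cz;
    double dot = ux * px + uy * py + uz * pz;
    double rx = px * c + (uy * pz - uz * py) * s + ux * dot * (1 - c);
    double ry = py * c + (uz * px - ux * pz) * s + uy * dot * (1 - c);
    double rz = pz * c + (ux * py - uy * px) * s + uz * dot * (1 - c);
    E.x[i] = cx + rx; E.y[i] = cy + ry; E.z[i] = cz + rz;
  }
}

static void wrap_molecule(Engine &E, int m) {
  const std::vector<int> &ss = E.mol_sites[m];
  double cx = 0, cy = 0, cz = 0;
  for (int i : ss) { cx += E.x[i]; cy += E.y[i]; cz += E.z[i]; }
  cx /= ss.size(); cy /= ss.size(); cz /= ss.size();
  double sx = std::floor(cx / E.box) * E.box;
  double sy = std::floor(cy / E.box) * E.box;
  double sz = std::floor(cz / E.box) * E.box;
  for (int i : ss) { E.x[i] -= sx; E.y[i] -= sy; E.z[i] -= sz; }
}

// One unified NVT/NPT Metropolis runner. Sweeps = nmol single-molecule move
// attempts (+ 1 volume move attempt per sweep under NPT). Samples are recorded
// every `sample_interval` sweeps after `equil_sweeps`.
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos, IntegerVector mol, IntegerVector typ,
                NumericVector q, NumericMatrix epsm, NumericMatrix sigm,
                double box, double rcut, bool tail,
                double temperature, double pressure, bool npt,
                int n_sweeps, int equil_sweeps, int sample_interval,
                double max_disp, double vol_scale, double max_rot,
                double total_mass, bool store_configs,
                int smol, double lambda, double sc_alpha, int sc_pow) {
  Engine E = make_engine(pos, mol, typ, q, epsm, sigm, box, rcut, tail,
                         smol, lambda, sc_alpha, sc_pow);
  RNGScope scope;
  const double RT = GAS_R * temperature;
  double e_pair = E.pair_sum();
  long n_try_d = 0, n_acc_d = 0, n_try_v = 0, n_acc_v = 0;

  int n_prod = n_sweeps - equil_sweeps;
  int n_samp = n_prod > 0 ? n_prod / sample_interval : 0;
  NumericVector e_samp(n_samp), v_samp(n_samp), rho_samp(n_samp);
  NumericMatrix conf(store_configs ? n_samp : 0, store_configs ? 3 * E.nsites : 0);
  NumericVector conf_box(store_configs ? n_samp : 0);
  int isamp = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int t = 0; t < E.nmol; ++t) {
      int m = (int)std::floor(unif_rand() * E.nmol);
      if (m >= E.nmol) m = E.nmol - 1;
      ++n_try_d;
      double e_old = E.mol_energy(m);
      std::vector<double> sx, sy, sz;
      for (int i : E.mol_sites[m]) { sx.push_back(E.x[i]); sy.push_back(E.y[i]); sz.push_back(E.z[i]); }
      bool rot = E.mol_sites[m].size() > 1 && unif_rand() < 0.5;
      if (rot) {
        double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
        double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (nn < 1e-12) { ux = 1; uy = 0; uz = 0; nn = 1; }
        rotate_molecule(E, m, (2.0 * unif_rand() - 1.0) * max_rot, ux / nn, uy / nn, uz / nn);
      } else {
        double dx = (2.0 * unif_rand() - 1.0) * max_disp;
        double dy = (2.0 * unif_rand() - 1.0) * max_disp;
        double dz = (2.0 * unif_rand() - 1.0) * max_disp;
        for (int i : E.mol_sites[m]) { E.x[i] += dx; E.y[i] += dy; E.z[i] += dz; }
      }
      wrap_molecule(E, m);
      double e_new = E.mol_energy(m);
      double dU = e_new - e_old;
      if (dU <= 0.0 || unif_rand() < std::exp(-dU / RT)) {
        e_pair += dU; ++n_acc_d;
      } else {
        int k = 0;
        for (int i : E.mol_sites[m]) { E.x[i] = sx[k]; E.y[i] = sy[k]; E.z[i] = sz[k]; ++k; }
      }
    }
    if (npt) {
      ++n_try_v;
      double V = E.box * E.box * E.box;
      double lnV = std::log(V) + (2.0 * unif_rand() - 1.0) * vol_scale;
      double Vn = std::exp(lnV);
      double scale = std::cbrt(Vn / V);
      Engine trial = E;
      trial.set_box(E.box * scale);
      // scale molecule centroids, keep internal geometry rigid
      for (int m = 0; m < E.nmol; ++m) {
        const std::vector<int> &ss = E.mol_sites[m];
        double cx = 0, cy = 0, cz = 0;
        for (int i : ss) { cx += E.x[i]; cy += E.y[i]; cz += E.z[i]; }
        cx /= ss.size(); cy /= ss.size(); cz /= ss.size();
        for (int i : ss) {
          trial.x[i] = E.x[i] + cx * (scale - 1.0);
          trial.y[i] = E.y[i] + cy * (scale - 1.0);
          trial.z[i] = E.z[i] + cz * (scale - 1.0);
        }
      }
      double e_old_tot = e_pair + E.tail_energy(V);
      double e_new_pair = trial.pair_sum();
      double e_new_tot = e_new_pair + trial.tail_energy(Vn);
      double dW = (e_new_tot - e_old_tot) + pressure * (Vn - V) * PV_CONV
                  - (E.nmol + 1) * RT * std::log(Vn / V);
      if (dW <= 0.0 || unif_rand() < std::exp(-dW / RT)) {
        E = trial; e_pair = e_new_pair; ++n_acc_v;
        for (int m = 0; m < E.nmol; ++m) wrap_molecule(E, m);
      }
    }
    if (sweep >= equil_sweeps && (sweep - equil_sweeps) % sample_interval == sample_interval - 1
        && isamp < n_samp) {
      double V = E.box * E.box * E.box;
      e_samp[isamp] = e_pair + E.tail_energy(V);
      v_samp[isamp] = V;
      rho_samp[isamp] = MASS_CONV * total_mass / V;
      if (store_configs) {
        for (int i = 0; i < E.nsites; ++i) {
          conf(isamp, 3 * i) = E.x[i]; conf(isamp, 3 * i + 1) = E.y[i]; conf(isamp, 3 * i + 2) = E.z[i];
        }
        conf_box[isamp] = E.box;
      }
      ++isamp;
    }
  }

  NumericMatrix final_pos(E.nsites, 3);
  for (int i = 0; i < E.nsites; ++i) {
    final_pos(i, 0) = E.x[i]; final_pos(i, 1) = E.y[i]; final_pos(i, 2) = E.z[i];
  }
  return List::create(
    _["energy"] = e_samp, _["volume"] = v_samp, _["density"] = rho_samp,
    _["acc_displacement"] = n_try_d ? (double)n_acc_d / n_try_d : NA_REAL,
    _["acc_volume"] = n_try_v ? (double)n_acc_v / n_try_v : NA_REAL,
    _["final_positions"] = final_pos, _["final_box"] = E.box,
    _["final_pair_energy"] = e_pair,
    _["recomputed_pair_energy"] = E.pair_sum(),
    _["configs"] = conf, _["config_box"] = conf_box);
}

// Evaluate the solute-solvent interaction energy (softcore LJ + linear Coulomb)
// of stored configurations at a vector of lambda values. Rows = lambdas.
// [[Rcpp::export]]
NumericMatrix cpp_eval_lambda_energies(NumericMatrix configs, NumericVector config_box,
                                       IntegerVector mol, IntegerVector typ,
                                       NumericVector q, NumericMatrix epsm,
                                       NumericMatrix sigm, double rcut,
                                       int smol, NumericVector lambdas,
                                       double sc_alpha, int sc_pow) {
  int nconf = configs.nrow(), K = lambdas.size(), nsites = typ.size();
  NumericMatrix out(K, nconf);
  NumericMatrix pos(nsites, 3);
  for (int n = 0; n < nconf; ++n) {
    for (int i = 0; i < nsites; ++i) {
      pos(i, 0) = configs(n, 3 * i); pos(i, 1) = configs(n, 3 * i + 1); pos(i, 2) = configs(n, 3 * i + 2);
    }
    Engine E = make_engine(pos, mol, typ, q, epsm, sigm, config_box[n], rcut,
                           false, smol, 1.0, sc_alpha, sc_pow);
    double rc = E.effective_rcut();
    for (int k = 0; k < K; ++k) out(k, n) = 0.0;
    for (int i : E.mol_sites[smol]) {
      for (int j = 0; j < nsites; ++j) {
        if (E.mol[j] == smol) continue;
        double dx = E.mi(E.x[i] - E.x[j]), dy = E.mi(E.y[i] - E.y[j]), dz = E.mi(E.z[i] - E.z[j]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc * rc) continue;
        double e = E.eps(E.typ[i], E.typ[j]), s = E.sig(E.typ[i], E.typ[j]);
        double qq = (E.q[i] != 0.0 && E.q[j] != 0.0)
          ? COULOMB_K * E.q[i] * E.q[j] * (1.0 / std::sqrt(r2) - 1.0 / rc) : 0.0;
        for (int k = 0; k < K; ++k)
          out(k, n) += E.softcore(e, s, r2, lambdas[k]) + lambdas[k] * qq;
      }
    }
  }
  return out;
}

// Widom test-particle insertion: for each stored solvent configuration perform
// n_insert random insertions of a rigid solute and return the per-configuration
// mean of exp(-beta dU). dU is the full (not softcore) solute-solvent energy.
// [[Rcpp::export]]
NumericVector cpp_widom(NumericMatrix configs, NumericVector config_box,
                        IntegerVector typ, NumericVector q,
                        NumericMatrix epsm, NumericMatrix sigm, double rcut,
                        NumericMatrix solute_offsets, IntegerVector solute_typ,
                        NumericVector solute_q, int n_insert, double beta) {
  RNGScope scope;
  int nconf = configs.nrow(), nsites = typ.size(), nsol = solute_typ.size();
  NumericVector out(nconf);
  for (int n = 0; n < nconf; ++n) {
    double box = config_box[n];
    double rc = rcut < 0.5 * box ? rcut : 0.5 * box * 0.9999;
    double acc = 0.0;
    for (int t = 0; t < n_insert; ++t) {
      double ox = unif_rand() * box, oy = unif_rand() * box, oz = unif_rand() * box;
      // random rotation for multi-site solutes (Rodrigues about random axis)
      double ang = 0, ux = 1, uy = 0, uz = 0;
      if (nsol > 1) {
        ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
        double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (nn < 1e-12) { ux = 1; uy = 0; uz = 0; nn = 1; }
        ux /= nn; uy /= nn; uz /= nn;
        ang = unif_rand() * 2.0 * M_PI;
      }
      double c = std::cos(ang), s = std::sin(ang);
      double dU = 0.0;
      for (int a = 0; a < nsol; ++a) {
        double px = solute_offsets(a, 0), py = solute_offsets(a, 1), pz = solute_offsets(a, 2);
        double dot = ux * px + uy * py + uz * pz;
        double rx = px * c + (uy * pz - uz * py) * s + ux * dot * (1 - c) + ox;
        double ry = py * c + (uz * px - ux * pz) * s + uy * dot * (1 - c) + oy;
        double rz = pz * c + (ux * py - uy * px) * s + uz * dot * (1 - c) + oz;
        for (int j = 0; j < nsites; ++j) {
          double dx = rx - configs(n, 3 * j), dy = ry - configs(n, 3 * j + 1), dz = rz - configs(n, 3 * j + 2);
          if (dx > 0.5 * box) dx -= box; else if (dx < -0.5 * box) dx += box;
          if (dy > 0.5 * box) dy -= box; else if (dy < -0.5 * box) dy += box;
          if (dz > 0.5 * box) dz -= box; else if (dz < -0.5 * box) dz += box;
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= rc * rc) continue;
          double e = epsm(solute_typ[a], typ[j]), sg = sigm(solute_typ[a], typ[j]);
          double sr2 = sg * sg / r2, sr6 = sr2 * sr2 * sr2;
          dU += 4.0 * e * sr6 * (sr6 - 1.0);
          if (solute_q[a] != 0.0 && q[j] != 0.0)
            dU += COULOMB_K * solute_q[a] * q[j] * (1.0 / std::sqrt(r2) - 1.0 / rc);
        }
      }
      acc += std::exp(-beta * dU);
    }
    out[n] = acc / n_insert;
  }
  return out;
}
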