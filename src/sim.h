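#pragma once
#include <Rcpp.h>
#include <vector>
#include <array>
#include <complex>
#include <cmath>
#include <algorithm>
#include "rng.h"

typedef std::complex<double> cd;

// Species codes (0-based in C++; R passes 1-based):
// 0 MH, 1 M-, 2 Na+, 3 Cl-, 4 K+, 5 OH-, 6 Mg2+, 7 SO4^2-
static const int N_SPECIES = 8;
static const double SP_CHARGE[N_SPECIES] = {0, -1, +1, -1, +1, -1, +2, -2};

// Coulomb handling modes
enum { COUL_NONE = 0, COUL_EWALD = 1, COUL_DH = 2 };

struct FF {
  double eps, rcut_mm, rcut_ion;   // truncated-shifted LJ
  double K, R0;                    // FENE
  double lambdaB;                  // Bjerrum length (sigma)
  int coulomb;                     // COUL_NONE / COUL_EWALD / COUL_DH
  double ew_accuracy, ew_rcut;     // Ewald controls
  double lambdaD, dh_rcut;         // Debye-Hueckel mode
  bool lj_on;
  // derived
  double shift_mm, shift_ion, rcut_mm2, rcut_ion2, R02, dh_shift;

  void finalize() {
    shift_mm = ulj_raw(rcut_mm);
    shift_ion = ulj_raw(rcut_ion);
    rcut_mm2 = rcut_mm * rcut_mm;
    rcut_ion2 = rcut_ion * rcut_ion;
    R02 = R0 * R0;
    dh_shift = (lambdaD > 0 && std::isfinite(lambdaD))
      ? std::exp(-dh_rcut / lambdaD) / dh_rcut
      : 1.0 / dh_rcut;  // lambdaD = Inf limit: bare 1/r shift
  }
  double ulj_raw(double r) const {
    double sr6 = 1.0 / (r * r * r * r * r * r);
    return 4.0 * eps * (sr6 * sr6 - sr6);
  }
};

struct Ewald {
  double alpha, rcut, L, V, lambdaB, self_pref;
  int kmax;
  std::vector<double> gx, gy, gz, coef;  // half reciprocal space
  std::vector<int> nx, ny, nz;

  void setup(double L_, double lambdaB_, double accuracy, double rcut_) {
    L = L_; V = L * L * L; lambdaB = lambdaB_; rcut = rcut_;
    // splitting parameter from the standard real-space error estimate,
    // reciprocal cutoff chosen so the Gaussian tail matches the same accuracy
    alpha = (1.35 - 0.15 * std::log(accuracy)) / rcut;
    double kcut = 2.0 * alpha * std::sqrt(-std::log(accuracy));
    kmax = (int)std::ceil(kcut * L / (2.0 * M_PI));
    double kcut2 = kcut * kcut;
    double tpL = 2.0 * M_PI / L;
    gx.clear(); gy.clear(); gz.clear(); coef.clear();
    nx.clear(); ny.clear(); nz.clear();
    for (int a = 0; a <= kmax; a++) {
      int blo = (a == 0) ? 0 : -kmax;
      for (int b = blo; b <= kmax; b++) {
        int clo = (a == 0 && b == 0) ? 1 : -kmax;
        for (int c = clo; c <= kmax; c++) {
          double kx = tpL * a, ky = tpL * b, kz = tpL * c;
          double k2 = kx * kx + ky * ky + kz * kz;
          if (k2 > kcut2) continue;
          nx.push_back(a); ny.push_back(b); nz.push_back(c);
          gx.push_back(kx); gy.push_back(ky); gz.push_back(kz);
          coef.push_back(4.0 * M_PI * lambdaB *
                         std::exp(-k2 / (4.0 * alpha * alpha)) / (V * k2));
        }
      }
    }
    self_pref = -lambdaB * alpha / std::sqrt(M_PI);
  }
  int n_kvec() const { return (int)coef.size(); }
};

struct Pert { double x, y, z, dq; };

struct MoveStats {
  long att_rxmc = 0, acc_rxmc = 0;
  long att_gcmc_salt = 0, acc_gcmc_salt = 0;
  long att_gcmc_koh = 0, acc_gcmc_koh = 0;
  long att_anneal = 0, acc_anneal = 0;
};

struct Sim {
  double L, V, temperature;
  FF ff;
  std::vector<double> px, py, pz, vx, vy, vz;
  std::vector<int> sp;
  int nmono;
  std::vector<std::array<int, 2>> bonds;
  std::vector<std::vector<int>> adj;   // monomer bond graph (unwrapping)
  Ewald ew;
  bool use_ewald;
  std::vector<cd> Sk;
  RNG rng;
  double Utot;
  double max_drift;
  long counts[N_SPECIES];
  MoveStats stats;

  // neighbor lists
  double skin;
  std::vector<int> lj_i, lj_j, cr_i, cr_j;
  std::vector<double> ref_x, ref_y, ref_z;
  std::vector<double> fx, fy, fz;
  std::vector<int> charged_idx;

  Sim(uint64_t seed) : rng(seed) {
    L = V = 0; temperature = 1.0; nmono = 0; use_ewald = false;
    Utot = 0; max_drift = 0; skin = 0.4;
    for (int i = 0; i < N_SPECIES; i++) counts[i] = 0;
  }

  int n() const { return (int)sp.size(); }
  double q_of(int i) const { return SP_CHARGE[sp[i]]; }

  // positions are kept wrapped in [0, L), so pair differences lie in
  // (-L, L) and the minimum image needs only comparisons (the rounding
  // intrinsic is a libm call on pre-SSE4 targets and dominates pair loops)
  inline double min_img(double d) const {
    if (d > 0.5 * L) return d - L;
    if (d < -0.5 * L) return d + L;
    return d;
  }

  inline double dist2(int i, int j) const {
    double dx = min_img(px[i] - px[j]);
    double dy = min_img(py[i] - py[j]);
    double dz = min_img(pz[i] - pz[j]);
    return dx * dx + dy * dy + dz * dz;
  }

  void wrap_all() {
    for (int i = 0; i < n(); i++) {
      px[i] -= L * std::floor(px[i] / L);
      py[i] -= L * std::floor(py[i] / L);
      pz[i] -= L * std::floor(pz[i] / L);
    }
  }

  // cheap re-wrap for MD steps (displacement per step is far below L)
  inline void wrap_step() {
    for (int i = 0; i < n(); i++) {
      if (px[i] >= L) px[i] -= L; else if (px[i] < 0) px[i] += L;
      if (py[i] >= L) py[i] -= L; else if (py[i] < 0) py[i] += L;
      if (pz[i] >= L) pz[i] -= L; else if (pz[i] < 0) pz[i] += L;
    }
  }

  void tally_counts() {
    for (int i = 0; i < N_SPECIES; i++) counts[i] = 0;
    for (int i = 0; i < n(); i++) counts[sp[i]]++;
  }

  double net_charge() const {
    double q = 0;
    for (int i = 0; i < n(); i++) q += q_of(i);
    return q;
  }

  void build_adj() {
    adj.assign(nmono, {});
    for (auto &b : bonds) { adj[b[0]].push_back(b[1]); adj[b[1]].push_back(b[0]); }
  }

  // ---------- pair terms ----------
  inline double lj_pair_e(double r2, bool mm) const {
    if (!ff.lj_on) return 0.0;
    double rc2 = mm ? ff.rcut_mm2 : ff.rcut_ion2;
    if (r2 >= rc2) return 0.0;
    double sr6 = 1.0 / (r2 * r2 * r2);
    return 4.0 * ff.eps * (sr6 * sr6 - sr6) - (mm ? ff.shift_mm : ff.shift_ion);
  }

  // short-range Coulomb kernel for unit charge product
  inline double phi(double r) const {
    if (ff.coulomb == COUL_EWALD) {
      if (r >= ew.rcut) return 0.0;
      return ff.lambdaB * std::erfc(ew.alpha * r) / r;
    }
    if (ff.coulomb == COUL_DH) {
      if (r >= ff.dh_rcut) return 0.0;
      double inv = (std::isfinite(ff.lambdaD)) ? std::exp(-r / ff.lambdaD) / r : 1.0 / r;
      return ff.lambdaB * (inv - ff.dh_shift);
    }
    return 0.0;
  }

  // energy of a trial particle (x,y,z,species s) against all current
  // particles except skip1/skip2
  double env_energy(double x, double y, double z, int s,
                    int skip1 = -1, int skip2 = -1) const {
    double q = SP_CHARGE[s];
    double e = 0.0;
    for (int j = 0; j < n(); j++) {
      if (j == skip1 || j == skip2) continue;
      double dx = min_img(x - px[j]);
      double dy = min_img(y - py[j]);
      double dz = min_img(z - pz[j]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12) return 1e30;
      bool mm = (s <= 1 && sp[j] <= 1);
      e += lj_pair_e(r2, mm);
      if (ff.coulomb != COUL_NONE) {
        double qq = q * q_of(j);
        if (qq != 0.0) e += qq * phi(std::sqrt(r2));
      }
    }
    return e;
  }

  double env_energy_of(int i, int skip = -1) const {
    return env_energy(px[i], py[i], pz[i], sp[i], i, skip);
  }

  // sum_{k != i, skip} q_k phi(r_ik)  (for charge-change moves)
  double charge_env(int i, int skip = -1) const {
    double e = 0.0;
    if (ff.coulomb == COUL_NONE) return 0.0;
    for (int j = 0; j < n(); j++) {
      if (j == i || j == skip) continue;
      double qj = q_of(j);
      if (qj == 0.0) continue;
      double r2 = dist2(i, j);
      if (r2 < 1e-12) return 1e30;
      e += qj * phi(std::sqrt(r2));
    }
    return e;
  }

  // ---------- Ewald structure factor ----------
  // per-particle axis phase tables, kept as raw re/im arrays so the inner
  // loops stay free of libm complex-multiply calls
  struct KPhase {
    std::vector<double> xr, xi, yr, yi, zr, zi;
    void build(double x, double y, double z, double L, int km) {
      double tp = 2.0 * M_PI / L;
      xr.resize(km + 1); xi.resize(km + 1);
      yr.resize(km + 1); yi.resize(km + 1);
      zr.resize(km + 1); zi.resize(km + 1);
      xr[0] = yr[0] = zr[0] = 1.0; xi[0] = yi[0] = zi[0] = 0.0;
      double cx = std::cos(tp * x), sx = std::sin(tp * x);
      double cy = std::cos(tp * y), sy = std::sin(tp * y);
      double cz = std::cos(tp * z), sz = std::sin(tp * z);
      for (int m = 1; m <= km; m++) {
        xr[m] = xr[m - 1] * cx - xi[m - 1] * sx;
        xi[m] = xr[m - 1] * sx + xi[m - 1] * cx;
        yr[m] = yr[m - 1] * cy - yi[m - 1] * sy;
        yi[m] = yr[m - 1] * sy + yi[m - 1] * cy;
        zr[m] = zr[m - 1] * cz - zi[m - 1] * sz;
        zi[m] = zr[m - 1] * sz + zi[m - 1] * cz;
      }
    }
  };

  inline void kfac(const KPhase &p, int k, double &re, double &im) const {
    int a = ew.nx[k], b = ew.ny[k], c = ew.nz[k];
    double br = (b >= 0) ? p.yr[b] : p.yr[-b];
    double bi = (b >= 0) ? p.yi[b] : -p.yi[-b];
    double cr = (c >= 0) ? p.zr[c] : p.zr[-c];
    double ci = (c >= 0) ? p.zi[c] : -p.zi[-c];
    double abr = p.xr[a] * br - p.xi[a] * bi;
    double abi = p.xr[a] * bi + p.xi[a] * br;
    re = abr * cr - abi * ci;
    im = abr * ci + abi * cr;
  }

  void compute_Sk(std::vector<cd> &S) const {
    int nk = ew.n_kvec();
    std::vector<double> Sr(nk, 0.0), Si(nk, 0.0);
    KPhase ph;
    for (int i = 0; i < n(); i++) {
      double q = q_of(i);
      if (q == 0.0) continue;
      ph.build(px[i], py[i], pz[i], L, ew.kmax);
      for (int k = 0; k < nk; k++) {
        double re, im;
        kfac(ph, k, re, im);
        Sr[k] += q * re; Si[k] += q * im;
      }
    }
    S.resize(nk);
    for (int k = 0; k < nk; k++) S[k] = cd(Sr[k], Si[k]);
  }

  double recip_energy(const std::vector<cd> &S) const {
    double e = 0.0;
    for (int k = 0; k < ew.n_kvec(); k++) e += ew.coef[k] * std::norm(S[k]);
    return e;
  }

  double sum_q2() const {
    double s = 0.0;
    for (int i = 0; i < n(); i++) { double q = q_of(i); s += q * q; }
    return s;
  }

  // reciprocal-space energy change for a set of point-charge perturbations;
  // fills dS so the caller can apply it on acceptance
  double recip_delta(const std::vector<Pert> &ps, std::vector<cd> &dS) const {
    if (!use_ewald) return 0.0;
    int nk = ew.n_kvec();
    dS.assign(nk, cd(0, 0));
    KPhase ph;
    for (const Pert &p : ps) {
      if (p.dq == 0.0) continue;
      ph.build(p.x, p.y, p.z, L, ew.kmax);
      for (int k = 0; k < nk; k++) {
        double re, im;
        kfac(ph, k, re, im);
        dS[k] += cd(p.dq * re, p.dq * im);
      }
    }
    double du = 0.0;
    for (int k = 0; k < nk; k++)
      du += ew.coef[k] * (std::norm(Sk[k] + dS[k]) - std::norm(Sk[k]));
    return du;
  }

  void apply_dS(const std::vector<cd> &dS) {
    for (size_t k = 0; k < dS.size(); k++) Sk[k] += dS[k];
  }

  // ---------- full energies ----------
  double fene_energy_total() const {
    double e = 0.0;
    for (auto &b : bonds) {
      double r2 = dist2(b[0], b[1]);
      if (r2 >= ff.R02)
        Rcpp::stop("FENE bond overstretched (r >= R0 = %g): bond %d-%d",
                   ff.R0, b[0] + 1, b[1] + 1);
      e += -0.5 * ff.K * ff.R02 * std::log(1.0 - r2 / ff.R02);
    }
    return e;
  }

  void full_energy(double &elj, double &efene, double &ecoul) const {
    elj = 0.0; ecoul = 0.0;
    int N = n();
    for (int i = 0; i < N; i++) {
      double qi = q_of(i);
      for (int j = i + 1; j < N; j++) {
        double r2 = dist2(i, j);
        bool mm = (sp[i] <= 1 && sp[j] <= 1);
        elj += lj_pair_e(r2, mm);
        double qq = qi * q_of(j);
        if (qq != 0.0) ecoul += qq * phi(std::sqrt(r2));
      }
    }
    efene = fene_energy_total();
    if (use_ewald) {
      std::vector<cd> S;
      compute_Sk(S);
      ecoul += recip_energy(S) + ew.self_pref * sum_q2();
    }
  }

  double full_energy_total() const {
    double a, b, c;
    full_energy(a, b, c);
    return a + b + c;
  }

  void refresh_caches() {
    if (use_ewald) compute_Sk(Sk);
    Utot = full_energy_total();
  }

  // ---------- particle bookkeeping ----------
  void add_particle(double x, double y, double z, int s) {
    px.push_back(x); py.push_back(y); pz.push_back(z);
    double sd = std::sqrt(temperature);
    vx.push_back(sd * rng.norm());
    vy.push_back(sd * rng.norm());
    vz.push_back(sd * rng.norm());
    sp.push_back(s);
    counts[s]++;
  }

  void remove_particle(int j) {
    int last = n() - 1;
    counts[sp[j]]--;
    if (j != last) {
      px[j] = px[last]; py[j] = py[last]; pz[j] = pz[last];
      vx[j] = vx[last]; vy[j] = vy[last]; vz[j] = vz[last];
      sp[j] = sp[last];
    }
    px.pop_back(); py.pop_back(); pz.pop_back();
    vx.pop_back(); vy.pop_back(); vz.pop_back();
    sp.pop_back();
  }

  // random particle of species s (counts[s] must be >= 1)
  int pick_species(int s) {
    int target = rng.unif_int((int)counts[s]);
    for (int i = 0; i < n(); i++) {
      if (sp[i] == s) { if (target == 0) return i; target--; }
    }
    Rcpp::stop("internal: species count inconsistent");
    return -1;
  }

  // random monomer in charge state s (0 = MH, 1 = M-)
  int pick_monomer(int s) {
    int target = rng.unif_int((int)counts[s]);
    for (int i = 0; i < nmono; i++) {
      if (sp[i] == s) { if (target == 0) return i; target--; }
    }
    Rcpp::stop("internal: monomer count inconsistent");
    return -1;
  }

  // ---------- Monte Carlo moves ----------
  bool metropolis(double a) { return a >= 1.0 || rng.unif() < a; }

  void move_rxmc(double mu_rxn) {
    stats.att_rxmc++;
    if (rng.unif() < 0.5) rxmc_deprotonate(mu_rxn);
    else rxmc_protonate(mu_rxn);
  }

  // implicit-salt titration (Debye-Hueckel comparison mode): the base is
  // not represented, so the move is a bare identity change weighted by the
  // charging chemical potential mu = ln10 (pH - pKa)
  void move_rxmc_implicit(double mu) {
    stats.att_rxmc++;
    long nMH = counts[0], nMm = counts[1];
    if (rng.unif() < 0.5) {  // deprotonate
      if (nMH < 1) return;
      int i = pick_monomer(0);
      double du = -1.0 * charge_env(i);
      std::vector<Pert> ps = { {px[i], py[i], pz[i], -1.0} };
      std::vector<cd> dS;
      du += recip_delta(ps, dS);
      if (use_ewald) du += ew.self_pref * 1.0;
      double a = (double)nMH / (nMm + 1.0) * std::exp(mu - du);
      if (metropolis(a)) {
        sp[i] = 1; counts[0]--; counts[1]++;
        if (use_ewald) apply_dS(dS);
        Utot += du; stats.acc_rxmc++;
      }
    } else {  // protonate
      if (nMm < 1) return;
      int i = pick_monomer(1);
      double du = +1.0 * charge_env(i);
      std::vector<Pert> ps = { {px[i], py[i], pz[i], +1.0} };
      std::vector<cd> dS;
      du += recip_delta(ps, dS);
      if (use_ewald) du -= ew.self_pref * 1.0;
      double a = (double)nMm / (nMH + 1.0) * std::exp(-mu - du);
      if (metropolis(a)) {
        sp[i] = 0; counts[1]--; counts[0]++;
        if (use_ewald) apply_dS(dS);
        Utot += du; stats.acc_rxmc++;
      }
    }
  }

  void rxmc_deprotonate(double mu_rxn) {
    long nMH = counts[0], nMm = counts[1], nOH = counts[5];
    if (nMH < 1 || nOH < 1) return;
    int i = pick_monomer(0);
    int j = pick_species(5);
    // affected pairs: i changes charge 0 -> -1; j (OH-) removed
    double du = -1.0 * charge_env(i, j);          // (i,k), k != i,j
    double r2ij = dist2(i, j);
    du -= lj_pair_e(r2ij, false);                 // pair (i,j): coul was 0
    du -= env_energy_of(j, i);                    // (j,k), k != i,j
    std::vector<Pert> ps = {
      {px[i], py[i], pz[i], -1.0},
      {px[j], py[j], pz[j], -SP_CHARGE[5]}
    };
    std::vector<cd> dS;
    du += recip_delta(ps, dS);
    if (use_ewald) du += ew.self_pref * ((1.0 - 0.0) - 1.0);  // d(sum q^2) = 0
    double a = (1.0 / V) * (double)nMH * (double)nOH / (nMm + 1.0) *
               std::exp(mu_rxn - du);
    if (metropolis(a)) {
      sp[i] = 1; counts[0]--; counts[1]++;
      remove_particle(j);
      if (use_ewald) apply_dS(dS);
      Utot += du;
      stats.acc_rxmc++;
    }
  }

  void rxmc_protonate(double mu_rxn) {
    long nMH = counts[0], nMm = counts[1], nOH = counts[5];
    if (nMm < 1) return;
    int i = pick_monomer(1);
    double ux = rng.unif() * L, uy = rng.unif() * L, uz = rng.unif() * L;
    // i changes charge -1 -> 0; OH- inserted at u
    double du = +1.0 * charge_env(i);             // (i,k) over current particles
    // new OH- vs existing; pair (u,i) uses the *new* monomer charge (0)
    du += env_energy(ux, uy, uz, 5, i);
    double dxi = min_img(ux - px[i]), dyi = min_img(uy - py[i]),
           dzi = min_img(uz - pz[i]);
    du += lj_pair_e(dxi * dxi + dyi * dyi + dzi * dzi, false);
    std::vector<Pert> ps = {
      {px[i], py[i], pz[i], +1.0},
      {ux, uy, uz, SP_CHARGE[5]}
    };
    std::vector<cd> dS;
    du += recip_delta(ps, dS);
    if (use_ewald) du += ew.self_pref * ((0.0 - 1.0) + 1.0);  // d(sum q^2) = 0
    double a = V * (double)nMm / ((nMH + 1.0) * (nOH + 1.0)) *
               std::exp(-mu_rxn - du);
    if (metropolis(a)) {
      sp[i] = 0; counts[1]--; counts[0]++;
      add_particle(ux, uy, uz, 5);
      if (use_ewald) apply_dS(dS);
      Utot += du;
      stats.acc_rxmc++;
    }
  }

  void move_anneal() {
    stats.att_anneal++;
    if (counts[0] < 1 || counts[1] < 1) return;
    int i = pick_monomer(1);  // charged
    int j = pick_monomer(0);  // neutral
    // swap: q_i -1 -> 0, q_j 0 -> -1; pair (i,j) term is 0 before and after
    double du = +1.0 * charge_env(i, j) - 1.0 * charge_env(j, i);
    std::vector<Pert> ps = {
      {px[i], py[i], pz[i], +1.0},
      {px[j], py[j], pz[j], -1.0}
    };
    std::vector<cd> dS;
    du += recip_delta(ps, dS);
    if (metropolis(std::exp(-du))) {
      sp[i] = 0; sp[j] = 1;
      if (use_ewald) apply_dS(dS);
      Utot += du;
      stats.acc_anneal++;
    }
  }

  // insertion/deletion of a charge-neutral two-species unit
  void move_gcmc(int s1, int s2, double mu1, double mu2, bool koh) {
    if (koh) stats.att_gcmc_koh++; else stats.att_gcmc_salt++;
    bool insert = rng.unif() < 0.5;
    double q1 = SP_CHARGE[s1], q2 = SP_CHARGE[s2];
    if (insert) {
      double x1 = rng.unif() * L, y1 = rng.unif() * L, z1 = rng.unif() * L;
      double x2 = rng.unif() * L, y2 = rng.unif() * L, z2 = rng.unif() * L;
      double du = env_energy(x1, y1, z1, s1) + env_energy(x2, y2, z2, s2);
      double dx = min_img(x1 - x2), dy = min_img(y1 - y2), dz = min_img(z1 - z2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12) return;
      du += lj_pair_e(r2, false);
      double qq = q1 * q2;
      if (qq != 0.0) du += qq * phi(std::sqrt(r2));
      std::vector<Pert> ps = { {x1, y1, z1, q1}, {x2, y2, z2, q2} };
      std::vector<cd> dS;
      du += recip_delta(ps, dS);
      if (use_ewald) du += ew.self_pref * (q1 * q1 + q2 * q2);
      double a = V / (counts[s1] + 1.0) * std::exp(mu1) *
                 V / (counts[s2] + 1.0) * std::exp(mu2) * std::exp(-du);
      if (metropolis(a)) {
        add_particle(x1, y1, z1, s1);
        add_particle(x2, y2, z2, s2);
        if (use_ewald) apply_dS(dS);
        Utot += du;
        if (koh) stats.acc_gcmc_koh++; else stats.acc_gcmc_salt++;
      }
    } else {
      if (counts[s1] < 1 || counts[s2] < 1) return;
      int j1 = pick_species(s1);
      int j2 = pick_species(s2);
      double rij = std::sqrt(dist2(j1, j2));
      double du = -env_energy_of(j1, j2) - env_energy_of(j2, j1);
      double r2 = rij * rij;
      du -= lj_pair_e(r2, false);
      double qq = q1 * q2;
      if (qq != 0.0) du -= qq * phi(rij);
      std::vector<Pert> ps = {
        {px[j1], py[j1], pz[j1], -q1},
        {px[j2], py[j2], pz[j2], -q2}
      };
      std::vector<cd> dS;
      du += recip_delta(ps, dS);
      if (use_ewald) du -= ew.self_pref * (q1 * q1 + q2 * q2);
      double a = (double)counts[s1] / V * std::exp(-mu1) *
                 (double)counts[s2] / V * std::exp(-mu2) * std::exp(-du);
      if (metropolis(a)) {
        // remove higher index first so the lower index stays valid
        int hi = std::max(j1, j2), lo = std::min(j1, j2);
        remove_particle(hi);
        remove_particle(lo);
        if (use_ewald) apply_dS(dS);
        Utot += du;
        if (koh) stats.acc_gcmc_koh++; else stats.acc_gcmc_salt++;
      }
    }
  }

  // ---------- neighbor lists and forces ----------
  void build_lists() {
    lj_i.clear(); lj_j.clear(); cr_i.clear(); cr_j.clear();
    charged_idx.clear();
    int N = n();
    double rl = std::max(ff.rcut_mm, ff.rcut_ion) + skin;
    double rl2 = rl * rl;
    double rc = 0.0;
    if (ff.coulomb == COUL_EWALD) rc = ew.rcut + skin;
    else if (ff.coulomb == COUL_DH) rc = ff.dh_rcut + skin;
    double rc2 = rc * rc;
    for (int i = 0; i < N; i++) {
      if (q_of(i) != 0.0) charged_idx.push_back(i);
      for (int j = i + 1; j < N; j++) {
        double r2 = dist2(i, j);
        if (ff.lj_on && r2 < rl2) { lj_i.push_back(i); lj_j.push_back(j); }
        if (rc > 0 && q_of(i) != 0.0 && q_of(j) != 0.0 && r2 < rc2) {
          cr_i.push_back(i); cr_j.push_back(j);
        }
      }
    }
    ref_x = px; ref_y = py; ref_z = pz;
  }

  bool need_rebuild() const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < n(); i++) {
      double dx = min_img(px[i] - ref_x[i]);
      double dy = min_img(py[i] - ref_y[i]);
      double dz = min_img(pz[i] - ref_z[i]);
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  void compute_forces() {
    int N = n();
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
    // LJ
    if (ff.lj_on) {
      for (size_t p = 0; p < lj_i.size(); p++) {
        int i = lj_i[p], j = lj_j[p];
        double dx = min_img(px[i] - px[j]);
        double dy = min_img(py[i] - py[j]);
        double dz = min_img(pz[i] - pz[j]);
        double r2 = dx * dx + dy * dy + dz * dz;
        bool mm = (sp[i] <= 1 && sp[j] <= 1);
        double rc2 = mm ? ff.rcut_mm2 : ff.rcut_ion2;
        if (r2 >= rc2) continue;
        double inv2 = 1.0 / r2;
        double sr6 = inv2 * inv2 * inv2;
        double fmag = ff.eps * (48.0 * sr6 * sr6 - 24.0 * sr6) * inv2;
        fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
        fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
      }
    }
    // FENE
    for (auto &b : bonds) {
      int i = b[0], j = b[1];
      double dx = min_img(px[i] - px[j]);
      double dy = min_img(py[i] - py[j]);
      double dz = min_img(pz[i] - pz[j]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ff.R02)
        Rcpp::stop("FENE bond overstretched during MD (r = %g >= R0 = %g)",
                   std::sqrt(r2), ff.R0);
      double fmag = -ff.K / (1.0 - r2 / ff.R02);
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
    // short-range Coulomb
    if (ff.coulomb == COUL_EWALD) {
      for (size_t p = 0; p < cr_i.size(); p++) {
        int i = cr_i[p], j = cr_j[p];
        double dx = min_img(px[i] - px[j]);
        double dy = min_img(py[i] - py[j]);
        double dz = min_img(pz[i] - pz[j]);
        double r2 = dx * dx + dy * dy + dz * dz;
        double r = std::sqrt(r2);
        if (r >= ew.rcut) continue;
        double qq = q_of(i) * q_of(j);
        double fmag = ff.lambdaB * qq *
          (std::erfc(ew.alpha * r) / r +
           2.0 * ew.alpha / std::sqrt(M_PI) * std::exp(-ew.alpha * ew.alpha * r2)) / r2;
        fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
        fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
      }
      // reciprocal part
      int nk = ew.n_kvec();
      std::vector<cd> S;
      compute_Sk(S);
      KPhase ph;
      for (int ci = 0; ci < (int)charged_idx.size(); ci++) {
        int i = charged_idx[ci];
        double qi = q_of(i);
        ph.build(px[i], py[i], pz[i], L, ew.kmax);
        double fxi = 0, fyi = 0, fzi = 0;
        for (int k = 0; k < nk; k++) {
          double re, im;
          kfac(ph, k, re, im);
          // Im(conj(e) S) = Re(e) Im(S) - Im(e) Re(S)
          double fac = -2.0 * ew.coef[k] *
                       (re * S[k].imag() - im * S[k].real());
          fxi += fac * ew.gx[k]; fyi += fac * ew.gy[k]; fzi += fac * ew.gz[k];
        }
        fx[i] += qi * fxi; fy[i] += qi * fyi; fz[i] += qi * fzi;
      }
    } else if (ff.coulomb == COUL_DH) {
      double invLD = std::isfinite(ff.lambdaD) ? 1.0 / ff.lambdaD : 0.0;
      for (size_t p = 0; p < cr_i.size(); p++) {
        int i = cr_i[p], j = cr_j[p];
        double dx = min_img(px[i] - px[j]);
        double dy = min_img(py[i] - py[j]);
        double dz = min_img(pz[i] - pz[j]);
        double r2 = dx * dx + dy * dy + dz * dz;
        double r = std::sqrt(r2);
        if (r >= ff.dh_rcut) continue;
        double qq = q_of(i) * q_of(j);
        double fmag = ff.lambdaB * qq * std::exp(-r * invLD) *
                      (1.0 / r2 + invLD / r) / r;
        fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
        fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
      }
    }
  }

  double kinetic_energy() const {
    double ke = 0.0;
    for (int i = 0; i < n(); i++)
      ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return ke;
  }

  // BAOAB Langevin integrator; friction = 0 reduces to velocity Verlet
  void md_steps(int nsteps, double dt, double friction) {
    if (nsteps < 1) return;
    build_lists();
    compute_forces();
    double c1 = std::exp(-friction * dt);
    double c2 = std::sqrt((1.0 - c1 * c1) * temperature);
    int N = n();
    for (int step = 0; step < nsteps; step++) {
      for (int i = 0; i < N; i++) {
        vx[i] += 0.5 * dt * fx[i];
        vy[i] += 0.5 * dt * fy[i];
        vz[i] += 0.5 * dt * fz[i];
        px[i] += 0.5 * dt * vx[i];
        py[i] += 0.5 * dt * vy[i];
        pz[i] += 0.5 * dt * vz[i];
      }
      if (friction > 0.0) {
        for (int i = 0; i < N; i++) {
          vx[i] = c1 * vx[i] + c2 * rng.norm();
          vy[i] = c1 * vy[i] + c2 * rng.norm();
          vz[i] = c1 * vz[i] + c2 * rng.norm();
        }
      }
      for (int i = 0; i < N; i++) {
        px[i] += 0.5 * dt * vx[i];
        py[i] += 0.5 * dt * vy[i];
        pz[i] += 0.5 * dt * vz[i];
      }
      wrap_step();
      if (need_rebuild()) build_lists();
      compute_forces();
      for (int i = 0; i < N; i++) {
        vx[i] += 0.5 * dt * fx[i];
        vy[i] += 0.5 * dt * fy[i];
        vz[i] += 0.5 * dt * fz[i];
      }
    }
  }

  // ---------- observables ----------
  void unwrap_monomers(std::vector<double> &ux, std::vector<double> &uy,
                       std::vector<double> &uz) const {
    ux.assign(nmono, 0); uy.assign(nmono, 0); uz.assign(nmono, 0);
    if (nmono == 0) return;
    std::vector<int> seen(nmono, 0), queue;
    queue.push_back(0); seen[0] = 1;
    ux[0] = px[0]; uy[0] = py[0]; uz[0] = pz[0];
    size_t head = 0;
    while (head < queue.size()) {
      int i = queue[head++];
      for (int j : adj[i]) {
        if (seen[j]) continue;
        seen[j] = 1;
        ux[j] = ux[i] + min_img(px[j] - px[i]);
        uy[j] = uy[i] + min_img(py[j] - py[i]);
        uz[j] = uz[i] + min_img(pz[j] - pz[i]);
        queue.push_back(j);
      }
    }
  }

  double radius_of_gyration() const {
    if (nmono == 0) return NA_REAL;
    std::vector<double> ux, uy, uz;
    unwrap_monomers(ux, uy, uz);
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < nmono; i++) { cx += ux[i]; cy += uy[i]; cz += uz[i]; }
    cx /= nmono; cy /= nmono; cz /= nmono;
    double s = 0;
    for (int i = 0; i < nmono; i++) {
      double dx = ux[i] - cx, dy = uy[i] - cy, dz = uz[i] - cz;
      s += dx * dx + dy * dy + dz * dz;
    }
    return std::sqrt(s / nmono);
  }
};
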