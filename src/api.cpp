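#include <Rcpp.h>
#include "sim.h"
#include <chrono>
using namespace Rcpp;

static FF ff_from_list(const List &ffl) {
  FF ff;
  ff.eps = as<double>(ffl["epsilon"]);
  ff.rcut_mm = as<double>(ffl["rcut_mm"]);
  ff.rcut_ion = as<double>(ffl["rcut_ion"]);
  ff.K = as<double>(ffl["K"]);
  ff.R0 = as<double>(ffl["R0"]);
  ff.lambdaB = as<double>(ffl["lambda_B"]);
  ff.coulomb = as<int>(ffl["coulomb_mode"]);  // 0 none, 1 ewald, 2 dh
  ff.ew_accuracy = as<double>(ffl["ewald_accuracy"]);
  ff.ew_rcut = as<double>(ffl["ewald_rcut"]);
  ff.lambdaD = as<double>(ffl["lambda_D"]);
  ff.dh_rcut = as<double>(ffl["dh_rcut"]);
  ff.lj_on = as<bool>(ffl["lj_on"]);
  ff.finalize();
  return ff;
}

static void sim_init(Sim &sim, const NumericMatrix &pos,
                     const NumericMatrix &vel, const IntegerVector &species,
                     double box, const IntegerMatrix &bonds, const List &ffl,
                     double temperature) {
  int N = pos.nrow();
  if (species.size() != N) stop("species length must match number of rows in positions");
  if (vel.nrow() != N) stop("velocities must match positions in size");
  sim.L = box; sim.V = box * box * box;
  sim.temperature = temperature;
  sim.ff = ff_from_list(ffl);
  sim.px.resize(N); sim.py.resize(N); sim.pz.resize(N);
  sim.vx.resize(N); sim.vy.resize(N); sim.vz.resize(N);
  sim.sp.resize(N);
  for (int i = 0; i < N; i++) {
    sim.px[i] = pos(i, 0); sim.py[i] = pos(i, 1); sim.pz[i] = pos(i, 2);
    sim.vx[i] = vel(i, 0); sim.vy[i] = vel(i, 1); sim.vz[i] = vel(i, 2);
    int s = species[i] - 1;
    if (s < 0 || s >= N_SPECIES) stop("unknown species code %d", species[i]);
    sim.sp[i] = s;
  }
  sim.wrap_all();
  sim.tally_counts();
  // monomers must occupy the leading slots (they are never inserted/deleted)
  sim.nmono = 0;
  for (int i = 0; i < N; i++) if (sim.sp[i] <= 1) sim.nmono++;
  for (int i = 0; i < sim.nmono; i++)
    if (sim.sp[i] > 1) stop("monomer beads must precede all ions in the state");
  sim.bonds.clear();
  for (int b = 0; b < bonds.nrow(); b++) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    if (i < 0 || j < 0 || i >= sim.nmono || j >= sim.nmono)
      stop("bond indices must refer to monomer beads");
    sim.bonds.push_back({i, j});
  }
  sim.build_adj();
  if (sim.ff.coulomb == COUL_EWALD) {
    if (sim.ff.ew_rcut >= box / 2.0)
      stop("Ewald real-space cutoff (%g) must be < box/2 (%g)",
           sim.ff.ew_rcut, box / 2.0);
    double q = sim.net_charge();
    if (std::fabs(q) > 1e-9)
      stop("Ewald summation requires an electroneutral system (net charge %g)", q);
    sim.ew.setup(box, sim.ff.lambdaB, sim.ff.ew_accuracy, sim.ff.ew_rcut);
    sim.use_ewald = true;
  } else {
    sim.use_ewald = false;
  }
  sim.refresh_caches();
}

// [[Rcpp::export]]
List cpp_ewald_setup(double box, double lambda_B, double accuracy, double rcut) {
  Ewald ew;
  ew.setup(box, lambda_B, accuracy, rcut);
  return List::create(_["alpha"] = ew.alpha, _["kmax"] = ew.kmax,
                      _["n_kvec"] = ew.n_kvec());
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, IntegerVector species, double box,
                IntegerMatrix bonds, List ff, double temperature = 1.0) {
  Sim sim(1);
  NumericMatrix vel(pos.nrow(), 3);
  sim_init(sim, pos, vel, species, box, bonds, ff, temperature);
  double elj, efene, ecoul;
  sim.full_energy(elj, efene, ecoul);
  return List::create(_["lj"] = elj, _["fene"] = efene, _["coulomb"] = ecoul,
                      _["total"] = elj + efene + ecoul);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector species, double box,
                         IntegerMatrix bonds, List ff) {
  Sim sim(1);
  NumericMatrix vel(pos.nrow(), 3);
  sim_init(sim, pos, vel, species, box, bonds, ff, 1.0);
  sim.build_lists();
  sim.compute_forces();
  NumericMatrix out(pos.nrow(), 3);
  for (int i = 0; i < pos.nrow(); i++) {
    out(i, 0) = sim.fx[i]; out(i, 1) = sim.fy[i]; out(i, 2) = sim.fz[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                double box, IntegerMatrix bonds, List ff, double dt,
                double friction, double temperature, int nsteps, int seed,
                int sample_every = 0, bool sample_bond = false) {
  Sim sim((uint64_t)seed);
  sim_init(sim, pos, vel, species, box, bonds, ff, temperature);
  std::vector<double> ke_samples, bond_samples;
  if (sample_every > 0) {
    int nchunk = nsteps / sample_every;
    for (int c = 0; c < nchunk; c++) {
      sim.md_steps(sample_every, dt, friction);
      ke_samples.push_back(sim.kinetic_energy());
      if (sample_bond && !sim.bonds.empty())
        bond_samples.push_back(std::sqrt(sim.dist2(sim.bonds[0][0], sim.bonds[0][1])));
    }
    int rem = nsteps - nchunk * sample_every;
    if (rem > 0) sim.md_steps(rem, dt, friction);
  } else {
    sim.md_steps(nsteps, dt, friction);
  }
  int N = sim.n();
  NumericMatrix opos(N, 3), ovel(N, 3);
  for (int i = 0; i < N; i++) {
    opos(i, 0) = sim.px[i]; opos(i, 1) = sim.py[i]; opos(i, 2) = sim.pz[i];
    ovel(i, 0) = sim.vx[i]; ovel(i, 1) = sim.vy[i]; ovel(i, 2) = sim.vz[i];
  }
  return List::create(
    _["positions"] = opos, _["velocities"] = ovel,
    _["kinetic_energy"] = sim.kinetic_energy(),
    _["total_energy"] = sim.full_energy_total() + sim.kinetic_energy(),
    _["potential_energy"] = sim.full_energy_total(),
    _["ke_samples"] = NumericVector(ke_samples.begin(), ke_samples.end()),
    _["bond_samples"] = NumericVector(bond_samples.begin(), bond_samples.end()));
}

// [[Rcpp::export]]
List cpp_run_hybrid(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                    double box, IntegerMatrix bonds, List ff,
                    double mu_rxn, bool rxmc_on, bool implicit_titration,
                    bool salt_on, IntegerVector salt_species, NumericVector salt_mu,
                    bool koh_on, NumericVector koh_mu,
                    int n_rxmc, int n_gcmc, int n_anneal, int md_steps,
                    int n_sweeps, double dt, double friction, double temperature,
                    int seed, int audit_every = 1) {
  Sim sim((uint64_t)seed);
  sim_init(sim, pos, vel, species, box, bonds, ff, temperature);
  if (salt_on && (salt_species.size() != 2 || salt_mu.size() != 2))
    stop("salt unit needs two species and two chemical potentials");
  int s1 = salt_on ? salt_species[0] - 1 : -1;
  int s2 = salt_on ? salt_species[1] - 1 : -1;

  int nmove = n_rxmc + n_gcmc + n_anneal;
  std::vector<int> seq;
  seq.reserve(nmove);

  int ncol = 10;
  NumericMatrix series(n_sweeps, ncol);
  colnames(series) = CharacterVector::create(
    "sweep", "f", "rg", "n_na", "n_cl", "n_k", "n_oh", "n_mg", "n_so4", "energy");

  for (int sweep = 0; sweep < n_sweeps; sweep++) {
    // assemble and shuffle the per-sweep move sequence
    seq.clear();
    for (int i = 0; i < n_rxmc; i++) seq.push_back(0);
    for (int i = 0; i < n_gcmc; i++) seq.push_back(1);
    for (int i = 0; i < n_anneal; i++) seq.push_back(2);
    for (int i = (int)seq.size() - 1; i > 0; i--)
      std::swap(seq[i], seq[sim.rng.unif_int(i + 1)]);
    for (int m : seq) {
      if (m == 0 && rxmc_on) {
        if (implicit_titration) sim.move_rxmc_implicit(mu_rxn);
        else sim.move_rxmc(mu_rxn);
      } else if (m == 1) {
        bool do_salt;
        if (salt_on && koh_on) do_salt = sim.rng.unif() < 0.5;
        else if (salt_on) do_salt = true;
        else if (koh_on) do_salt = false;
        else continue;
        if (do_salt) sim.move_gcmc(s1, s2, salt_mu[0], salt_mu[1], false);
        else sim.move_gcmc(4, 5, koh_mu[0], koh_mu[1], true);
      } else if (m == 2) {
        sim.move_anneal();
      }
    }
    // incremental-energy audit against a full recomputation
    if (audit_every > 0 && (sweep % audit_every) == 0) {
      double ufull = sim.full_energy_total();
      double drift = std::fabs(ufull - sim.Utot);
      if (drift > sim.max_drift) sim.max_drift = drift;
      sim.Utot = ufull;
      if (sim.use_ewald) sim.compute_Sk(sim.Sk);
    }
    if (md_steps > 0) {
      sim.md_steps(md_steps, dt, friction);
      sim.refresh_caches();
    }
    if (sim.use_ewald) {
      double qnet = sim.net_charge();
      if (std::fabs(qnet) > 1e-9)
        stop("electroneutrality violated after sweep %d (net charge %g)",
             sweep + 1, qnet);
    }
    series(sweep, 0) = sweep + 1;
    series(sweep, 1) = sim.nmono > 0 ? (double)sim.counts[1] / sim.nmono : NA_REAL;
    series(sweep, 2) = sim.radius_of_gyration();
    series(sweep, 3) = sim.counts[2];
    series(sweep, 4) = sim.counts[3];
    series(sweep, 5) = sim.counts[4];
    series(sweep, 6) = sim.counts[5];
    series(sweep, 7) = sim.counts[6];
    series(sweep, 8) = sim.counts[7];
    series(sweep, 9) = sim.Utot;
    if ((sweep & 63) == 0) Rcpp::checkUserInterrupt();
  }

  int N = sim.n();
  NumericMatrix opos(N, 3), ovel(N, 3);
  IntegerVector osp(N);
  for (int i = 0; i < N; i++) {
    opos(i, 0) = sim.px[i]; opos(i, 1) = sim.py[i]; opos(i, 2) = sim.pz[i];
    ovel(i, 0) = sim.vx[i]; ovel(i, 1) = sim.vy[i]; ovel(i, 2) = sim.vz[i];
    osp[i] = sim.sp[i] + 1;
  }
  NumericVector att = NumericVector::create(
    _["rxmc"] = (double)sim.stats.att_rxmc,
    _["gcmc_salt"] = (double)sim.stats.att_gcmc_salt,
    _["gcmc_koh"] = (double)sim.stats.att_gcmc_koh,
    _["anneal"] = (double)sim.stats.att_anneal);
  NumericVector acc = NumericVector::create(
    _["rxmc"] = (double)sim.stats.acc_rxmc,
    _["gcmc_salt"] = (double)sim.stats.acc_gcmc_salt,
    _["gcmc_koh"] = (double)sim.stats.acc_gcmc_koh,
    _["anneal"] = (double)sim.stats.acc_anneal);
  return List::create(
    _["positions"] = opos, _["velocities"] = ovel, _["species"] = osp,
    _["series"] = series, _["attempts"] = att, _["accepts"] = acc,
    _["max_audit_drift"] = sim.max_drift,
    _["energy"] = sim.Utot);
}

// [[Rcpp::export]]
List cpp_profile(NumericMatrix pos, IntegerVector species, double box,
                 IntegerMatrix bonds, List ff, int reps = 200) {
  Sim sim(1);
  NumericMatrix vel(pos.nrow(), 3);
  sim_init(sim, pos, vel, species, box, bonds, ff, 1.0);
  sim.build_lists();
  auto tic = [] { return std::chrono::steady_clock::now(); };
  auto ms = [](std::chrono::steady_clock::time_point a,
               std::chrono::steady_clock::time_point b, int n) {
    return std::chrono::duration<double>(b - a).count() / n * 1e3;
  };
  auto t0 = tic();
  for (int r = 0; r < reps; r++) sim.build_lists();
  auto t1 = tic();
  for (int r = 0; r < reps; r++) sim.compute_forces();
  auto t2 = tic();
  std::vector<cd> S;
  for (int r = 0; r < reps; r++) sim.compute_Sk(S);
  auto t3 = tic();
  double e = 0;
  for (int r = 0; r < reps; r++) e += sim.full_energy_total();
  auto t4 = tic();
  return List::create(_["build_lists_ms"] = ms(t0, t1, reps),
                      _["forces_ms"] = ms(t1, t2, reps),
                      _["Sk_ms"] = ms(t2, t3, reps),
                      _["energy_ms"] = ms(t3, t4, reps),
                      _["n_lj"] = (double)sim.lj_i.size(),
                      _["n_cr"] = (double)sim.cr_i.size(),
                      _["n_kvec"] = (double)(sim.use_ewald ? sim.ew.n_kvec() : 0),
                      _["junk"] = e);
}
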