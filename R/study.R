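# Scaled-down study presets: the production experiment designs (titration
# of a single chain or star against salt and base reservoirs) at reduced
# system size, used by the validation suite and the reproduction script.
# Problem sizes are chosen so a study runs on one CPU core in minutes: a
# 61-monomer polymer in a (32 sigma)^3 box with a 0.01 M KOH reservoir
# keeps the hydroxide occupancy per titratable monomer comparable to the
# production cell (121 monomers, (64.6 sigma)^3, 0.002 M).

#' Titration study of one polymer in explicit salt
#'
#' The full production workflow at reduced scale: calibrate the salt
#' reservoir chemical potential to the target bulk concentration by
#' pure-salt GCMC (the divalent unit associates strongly, so the
#' calibrated \eqn{\mu} lies well below the ideal-gas mapping), build the
#' polymer and initial ion content, run the hybrid MC/MD loop, and report
#' block-averaged charge fraction and radius of gyration together with
#' the realized salt concentration and its Debye length.
#'
#' @param salt `"nacl"` or `"mgso4"`.
#' @param target_conc Target bulk salt concentration in mol/L.
#' @param mu Charging chemical potential \eqn{\ln 10\,(pH - pK_a)}.
#' @param architecture `"linear"` or `"star"` (10 arms).
#' @param n_monomers Number of titratable beads (star: must be
#'   `10 * arm + 1`).
#' @param box Box edge in \eqn{\sigma}.
#' @param koh_conc KOH reservoir concentration in mol/L.
#' @param n_sweeps Hybrid sweeps (30 MC moves and one MD batch each).
#' @param md_steps MD steps per sweep.
#' @param ewald_accuracy Ewald force accuracy for the study.
#' @param seed Integer seed.
#' @param equilibration Fraction of sweeps discarded in averages.
#' @return List: `f`, `f_se`, `rg`, `rg_se`, `realized_conc`, `lambda_D`,
#'   `mu_salt`, `n_mc_moves`, `run`.
#' @export
run_titration_study <- function(salt = c("nacl", "mgso4"), target_conc,
                                mu = 5, architecture = c("linear", "star"),
                                n_monomers = 61, box = 32, koh_conc = 0.01,
                                n_sweeps = 3600, md_steps = 50,
                                ewald_accuracy = 1e-3, seed = 1,
                                equilibration = 0.5) {
  salt <- match.arg(salt)
  architecture <- match.arg(architecture)
  ff <- forcefield_for_box(make_forcefield(ewald_accuracy = ewald_accuracy), box)
  cal <- calibrate_mu_for_concentration(target_conc, salt, box = box, ff = ff,
                                        n_sweeps = 1500, seed = seed + 1000)
  topo <- if (architecture == "linear") build_linear(n_monomers)
          else build_star(10, (n_monomers - 1) %/% 10)
  state <- initial_configuration(topo, box, seed = seed)
  nk <- max(1L, round(concentration_to_count(koh_conc, box)))
  ns <- max(1L, round(concentration_to_count(target_conc, box)))
  pair <- if (salt == "nacl") c("Na+", "Cl-") else c("Mg2+", "SO4--")
  ions <- c("K+" = nk, "OH-" = nk)
  ions[pair] <- ns
  state <- place_ions(state, ions, seed = seed + 1)
  chem <- make_chemostats(mu = mu, koh_conc = koh_conc, salt = salt,
                          salt_conc = target_conc,
                          mu_salt = c(cal$mu, cal$mu))
  sched <- make_schedule(30, md_steps_per_sweep = md_steps, audit_every = 1)
  run <- run_hybrid(state, ff, chem, topo, sched, md_params(),
                    n_sweeps = n_sweeps, seed = seed + 2)
  fb <- block_average(run$series$f, equilibration)
  rgb <- block_average(run$series$rg, equilibration)
  ccol <- if (salt == "nacl") "n_na" else "n_mg"
  realized <- count_to_concentration(
    block_average(run$series[[ccol]], equilibration)$mean, box)
  list(f = fb$mean, f_se = fb$se, rg = rgb$mean, rg_se = rgb$se,
       realized_conc = realized,
       lambda_D = debye_length(realized, salt, ff$lambda_B),
       mu_salt = cal$mu, n_mc_moves = 30 * n_sweeps, run = run)
}

#' Charging scan over mu in the implicit screened-electrostatics mode
#'
#' Sweeps the charging chemical potential for one topology with
#' Debye-Hueckel monomer-monomer interactions (no explicit ions, implicit
#' titration moves).  Each mu point is warm-started from the previous
#' final state (annealed scan), which suppresses hysteresis near the
#' coil-globule transition.  Used for the topology-dependence checks,
#' where the cheap implicit mode makes a two-topology scan a matter of
#' seconds.
#'
#' @param architecture `"linear"` or `"star"`.
#' @param lambda_D Debye screening length in \eqn{\sigma}.
#' @param mus Vector of charging chemical potentials (scanned ascending).
#' @param n_monomers,box,n_sweeps,md_steps,seed,equilibration As in
#'   [run_titration_study()].
#' @return A tibble: `mu`, `f`, `f_se`, `rg`, `rg_se`.
#' @export
dh_mu_scan <- function(architecture = c("linear", "star"), lambda_D = 10,
                       mus = 3:7, n_monomers = 61, box = 32,
                       n_sweeps = 1500, md_steps = 50, seed = 1,
                       equilibration = 0.5) {
  architecture <- match.arg(architecture)
  topo <- if (architecture == "linear") build_linear(n_monomers)
          else build_star(10, (n_monomers - 1) %/% 10)
  ff <- make_forcefield(electrostatics = "dh", lambda_D = lambda_D)
  sched <- make_schedule(30, c(rxmc = 15, gcmc = 0, anneal = 15),
                         md_steps_per_sweep = md_steps, audit_every = 1)
  state <- initial_configuration(topo, box, seed = seed)
  rows <- list()
  for (mu in sort(mus)) {
    chem <- make_chemostats(mu = mu, koh_conc = 0, salt = "none", mu_OH = 0)
    r <- run_hybrid(state, ff, chem, topo, sched, md_params(),
                    n_sweeps = n_sweeps, seed = seed + round(10 * mu),
                    titration = "implicit")
    state <- r$state
    fb <- block_average(r$series$f, equilibration)
    rgb <- block_average(r$series$rg, equilibration)
    rows[[length(rows) + 1]] <- tibble::tibble(
      mu = mu, f = fb$mean, f_se = fb$se, rg = rgb$mean, rg_se = rgb$se)
  }
  do.call(rbind, rows)
}

#' Sharpness of a charging curve
#'
#' Largest single-step increase of f across a mu scan, as a fraction of
#' the total f range: a first-order-like jump concentrates the range in
#' one step (value toward 1), a gradual transition spreads it evenly
#' (value toward 1/(points - 1)).
#'
#' @param scan A tibble from [dh_mu_scan()] (columns `mu`, `f`).
#' @return Scalar in (0, 1\].
#' @export
charging_sharpness <- function(scan) {
  scan <- scan[order(scan$mu), ]
  max(diff(scan$f)) / (max(scan$f) - min(scan$f))
}
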