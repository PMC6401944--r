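# Monte Carlo engine: reaction-ensemble titration, charge annealing,
# multi-species grand-canonical salt/base exchange, and the hybrid MC/MD
# scheduler.

#' Chemostat set: reaction and grand-canonical chemical potentials
#'
#' The charging chemical potential follows the convention
#' \eqn{\mu = \ln 10\,(pH - pK_a)}; the reaction chemical potential entering
#' the titration acceptance rules is \eqn{\mu_{rxn} = \mu - \mu_{OH^-}}.
#' Chemical potentials of the reservoir species default to the ideal-gas
#' mapping \eqn{\mu_i = \ln(\rho_i \Lambda^3)} at the requested bulk
#' concentrations (with \eqn{\Lambda = 1\sigma}); with interacting ions the
#' realized box concentration at fixed \eqn{\mu_i} is measured by
#' [calibrate_salt()].  The base reservoir is KOH (default 0.002 M, i.e.
#' pOH \eqn{\approx} 2.7); the salt reservoir is a charge-neutral NaCl or
#' MgSO4 unit.
#'
#' @param mu Charging chemical potential \eqn{\ln 10\,(pH - pK_a)} in
#'   \eqn{k_BT}.
#' @param koh_conc Bulk KOH concentration in mol/L (0 disables the base
#'   chemostat).
#' @param salt `"nacl"`, `"mgso4"` or `"none"`.
#' @param salt_conc Bulk salt concentration in mol/L.
#' @param sigma_nm Length of \eqn{\sigma} in nm.
#' @param lambda3 \eqn{\Lambda^3} in \eqn{\sigma^3}.
#' @param mu_OH,mu_salt Optional overrides of the ideal-gas mapping:
#'   `mu_OH` a scalar, `mu_salt` a length-2 vector of per-species chemical
#'   potentials for the salt unit.
#' @return An object of class `wpe_chemostats` with fields `mu`, `mu_OH`,
#'   `mu_rxn`, `mu_salt`, `salt`, `salt_species`, `koh_mu`, `koh_on`,
#'   `salt_on`.
#' @export
#' @examples
#' ch <- make_chemostats(mu = 5, koh_conc = 0.002, salt = "nacl",
#'                       salt_conc = 0.1)
#' ch$mu_rxn  # mu - mu_OH
make_chemostats <- function(mu, koh_conc = 0.002,
                            salt = c("nacl", "mgso4", "none"),
                            salt_conc = 0, sigma_nm = 0.25, lambda3 = 1,
                            mu_OH = NULL, mu_salt = NULL) {
  salt <- match.arg(salt)
  koh_on <- koh_conc > 0 || !is.null(mu_OH)
  if (is.null(mu_OH)) {
    mu_OH <- if (koh_on) log(concentration_to_density(koh_conc, sigma_nm) * lambda3)
             else -Inf
  }
  salt_species <- switch(salt, nacl = c(3L, 4L), mgso4 = c(7L, 8L), none = integer(0))
  salt_on <- salt != "none" && (salt_conc > 0 || !is.null(mu_salt))
  if (is.null(mu_salt)) {
    mu_salt <- if (salt_on)
      rep(log(concentration_to_density(salt_conc, sigma_nm) * lambda3), 2)
    else c(-Inf, -Inf)
  }
  structure(
    list(mu = mu, mu_OH = mu_OH, mu_rxn = mu - mu_OH,
         mu_salt = mu_salt, salt = salt, salt_species = salt_species,
         koh_mu = c(mu_OH, mu_OH), koh_on = koh_on, salt_on = salt_on,
         lambda3 = lambda3, sigma_nm = sigma_nm,
         koh_conc = koh_conc, salt_conc = salt_conc),
    class = "wpe_chemostats"
  )
}

#' @export
print.wpe_chemostats <- function(x, ...) {
  cat("<wpe_chemostats> mu =", x$mu, "(pH - pKa =", round(x$mu / log(10), 3),
      ") | mu_OH =", round(x$mu_OH, 3), "| mu_rxn =", round(x$mu_rxn, 3), "\n")
  if (x$salt_on)
    cat("  salt:", x$salt, "at", x$salt_conc, "M, per-species mu =",
        round(x$mu_salt[1], 3), "\n")
  invisible(x)
}

#' Charging chemical potential from pH - pKa
#'
#' \eqn{\mu = \ln 10\,(pH - pK_a)}; [ph_minus_pka()] is the inverse.
#'
#' @param ph_minus_pka pH minus pKa.
#' @return \eqn{\mu} in \eqn{k_BT}.
#' @export
#' @examples
#' mu_from_ph(1.302)  # ~ 3
#' ph_minus_pka(7)    # ~ 3.040
mu_from_ph <- function(ph_minus_pka) log(10) * ph_minus_pka

#' @rdname mu_from_ph
#' @param mu Charging chemical potential in \eqn{k_BT}.
#' @export
ph_minus_pka <- function(mu) mu / log(10)

# ---------------------------------------------------------------------------
# acceptance probabilities (the formulas, exposed for direct testing)

#' Reaction-ensemble acceptance probability
#'
#' Deprotonation (`MH -> M-` plus removal of one `OH-`):
#' \deqn{P = \min\{1, \frac{\Lambda^3}{V}\,\frac{N_{MH} N_{OH}}{N_{M^-}+1}
#'   \,e^{-\beta\Delta U + \beta\mu_{rxn}}\}}
#' Protonation (`M- -> MH` plus insertion of one `OH-`):
#' \deqn{P = \min\{1, \frac{V}{\Lambda^3}\,\frac{N_{M^-}}{(N_{MH}+1)(N_{OH}+1)}
#'   \,e^{-\beta\Delta U - \beta\mu_{rxn}}\}}
#' The mass-ratio factor of the reaction ensemble is kept as an explicit
#' argument; it is 1 because all species masses are 1 in reduced units.
#'
#' @param direction `"deprotonate"` or `"protonate"`.
#' @param n_MH,n_M,n_OH Current particle numbers (before the move).
#' @param V Box volume in \eqn{\sigma^3}.
#' @param delta_U Potential-energy change in \eqn{k_BT}.
#' @param mu_rxn Reaction chemical potential in \eqn{k_BT}.
#' @param lambda3 \eqn{\Lambda^3}.
#' @param mass_factor Mass-ratio prefactor (1 in reduced units).
#' @return Acceptance probability in \[0, 1\].
#' @export
#' @examples
#' # ideal deprotonation in the production box
#' rxmc_acceptance("deprotonate", n_MH = 121, n_M = 0, n_OH = 5,
#'                 V = 64.6^3, delta_U = 0, mu_rxn = 5)
rxmc_acceptance <- function(direction = c("deprotonate", "protonate"),
                            n_MH, n_M, n_OH, V, delta_U, mu_rxn,
                            lambda3 = 1, mass_factor = 1) {
  direction <- match.arg(direction)
  a <- if (direction == "deprotonate") {
    if (n_MH < 1 || n_OH < 1) 0
    else mass_factor * (lambda3 / V) * n_MH * n_OH / (n_M + 1) *
      exp(-delta_U + mu_rxn)
  } else {
    if (n_M < 1) 0
    else (1 / mass_factor) * (V / lambda3) * n_M / ((n_MH + 1) * (n_OH + 1)) *
      exp(-delta_U - mu_rxn)
  }
  min(1, a)
}

#' Multi-species grand-canonical acceptance probability
#'
#' Insertion of a charge-neutral unit of k species:
#' \deqn{P = \min\{1, \prod_i \frac{V}{\Lambda^3 (N_i+1)} e^{\beta\mu_i}
#'   \, e^{-\beta\Delta U}\}}
#' and deletion:
#' \deqn{P = \min\{1, \prod_j \frac{\Lambda^3 N_j}{V} e^{-\beta\mu_j}
#'   \, e^{-\beta\Delta U}\}.}
#'
#' @param type `"insertion"` or `"deletion"`.
#' @param n Vector of current particle numbers of the unit's species.
#' @param mu Vector of per-species chemical potentials in \eqn{k_BT}.
#' @param V Box volume in \eqn{\sigma^3}.
#' @param delta_U Potential-energy change in \eqn{k_BT}.
#' @param lambda3 \eqn{\Lambda^3}.
#' @return Acceptance probability in \[0, 1\].
#' @export
gcmc_acceptance <- function(type = c("insertion", "deletion"), n, mu, V,
                            delta_U, lambda3 = 1) {
  type <- match.arg(type)
  a <- if (type == "insertion") {
    prod(V / (lambda3 * (n + 1))) * exp(sum(mu)) * exp(-delta_U)
  } else {
    if (any(n < 1)) 0
    else prod(lambda3 * n / V) * exp(-sum(mu)) * exp(-delta_U)
  }
  min(1, a)
}

# ---------------------------------------------------------------------------
# reference (R-level) single moves: full-energy Delta-U, used by the unit
# and detailed-balance tests; the production path is the compiled scheduler

#' @noRd
.pick_index <- function(idx) idx[sample.int(length(idx), 1L)]

#' @noRd
.state_replace_species <- function(state, i, code) {
  state$species[i] <- as.integer(code)
  state
}

#' @noRd
.state_add <- function(state, pos, code, velocity = NULL) {
  if (is.null(velocity)) velocity <- rnorm(3)
  make_state(rbind(state$positions, pos),
             c(state$species, as.integer(code)), state$box,
             rbind(state$velocities, velocity))
}

#' @noRd
.state_remove <- function(state, i) {
  make_state(state$positions[-i, , drop = FALSE], state$species[-i],
             state$box, state$velocities[-i, , drop = FALSE])
}

#' Single reaction-ensemble deprotonation attempt
#'
#' Picks a random neutral monomer and a random hydroxide, proposes the
#' identity change `MH -> M-` with removal of the `OH-`, and accepts with
#' the reaction-ensemble probability (see [rxmc_acceptance()]).  Uses R's
#' RNG stream; seed with `set.seed()`.  This is the reference
#' implementation with full-energy evaluation; the compiled scheduler in
#' [run_hybrid()] performs the same move incrementally.
#'
#' @param state A `wpe_state`.
#' @param chem A `wpe_chemostats`.
#' @param ff A `wpe_forcefield`.
#' @param topology Optional `wpe_topology`.
#' @return List with `state`, `accepted`, `prob`, `delta_U`.
#' @export
rxmc_deprotonate <- function(state, chem, ff, topology = NULL) {
  counts <- species_counts(state)
  n_MH <- counts[["MH"]]; n_M <- counts[["Mminus"]]; n_OH <- counts[["OH-"]]
  if (n_MH < 1 || n_OH < 1)
    return(list(state = state, accepted = FALSE, prob = 0, delta_U = NA_real_))
  i <- .pick_index(which(state$species == 1L))
  j <- .pick_index(which(state$species == 6L))
  proposal <- .state_remove(.state_replace_species(state, i, 2L), j)
  du <- total_energy(proposal, ff, topology) - total_energy(state, ff, topology)
  p <- rxmc_acceptance("deprotonate", n_MH, n_M, n_OH, state$box^3, du,
                       chem$mu_rxn, chem$lambda3)
  if (runif(1) < p) list(state = proposal, accepted = TRUE, prob = p, delta_U = du)
  else list(state = state, accepted = FALSE, prob = p, delta_U = du)
}

#' Single reaction-ensemble protonation attempt
#'
#' The reverse of [rxmc_deprotonate()]: a random charged monomer becomes
#' neutral and one `OH-` is inserted at a uniform random position.
#'
#' @inheritParams rxmc_deprotonate
#' @return List with `state`, `accepted`, `prob`, `delta_U`.
#' @export
rxmc_protonate <- function(state, chem, ff, topology = NULL) {
  counts <- species_counts(state)
  n_MH <- counts[["MH"]]; n_M <- counts[["Mminus"]]; n_OH <- counts[["OH-"]]
  if (n_M < 1)
    return(list(state = state, accepted = FALSE, prob = 0, delta_U = NA_real_))
  i <- .pick_index(which(state$species == 2L))
  pos <- runif(3, 0, state$box)
  proposal <- .state_add(.state_replace_species(state, i, 1L), pos, 6L)
  du <- total_energy(proposal, ff, topology) - total_energy(state, ff, topology)
  p <- rxmc_acceptance("protonate", n_MH, n_M, n_OH, state$box^3, du,
                       chem$mu_rxn, chem$lambda3)
  if (runif(1) < p) list(state = proposal, accepted = TRUE, prob = p, delta_U = du)
  else list(state = state, accepted = FALSE, prob = p, delta_U = du)
}

#' Single charge-annealing swap attempt
#'
#' Exchanges the identities of a random (`MH`, `M-`) monomer pair with the
#' standard Metropolis probability \eqn{\min\{1, e^{-\beta\Delta U}\}}.
#' All species counts are unchanged; only the location of a charge on the
#' polymer moves.
#'
#' @inheritParams rxmc_deprotonate
#' @return List with `state`, `accepted`, `prob`, `delta_U`.
#' @export
charge_anneal_swap <- function(state, ff, topology = NULL) {
  if (!any(state$species == 1L) || !any(state$species == 2L))
    return(list(state = state, accepted = FALSE, prob = 0, delta_U = NA_real_))
  i <- .pick_index(which(state$species == 2L))
  j <- .pick_index(which(state$species == 1L))
  proposal <- .state_replace_species(.state_replace_species(state, i, 1L), j, 2L)
  du <- total_energy(proposal, ff, topology) - total_energy(state, ff, topology)
  p <- min(1, exp(-du))
  if (runif(1) < p) list(state = proposal, accepted = TRUE, prob = p, delta_U = du)
  else list(state = state, accepted = FALSE, prob = p, delta_U = du)
}

#' @noRd
.gcmc_unit <- function(chem, unit) {
  if (unit == "salt") {
    if (!chem$salt_on) stop("no salt reservoir configured")
    list(species = chem$salt_species, mu = chem$mu_salt)
  } else {
    if (!chem$koh_on) stop("no KOH reservoir configured")
    list(species = c(5L, 6L), mu = chem$koh_mu)
  }
}

#' Grand-canonical insertion of a charge-neutral unit
#'
#' Inserts one unit (`Na+ + Cl-`, `Mg2+ + SO4--`, or `K+ + OH-`) at
#' independent uniform positions with the multi-species grand-canonical
#' probability (see [gcmc_acceptance()]).  Electroneutrality is preserved
#' because units are neutral.
#'
#' @inheritParams rxmc_deprotonate
#' @param unit `"salt"` or `"koh"`.
#' @return List with `state`, `accepted`, `prob`, `delta_U`.
#' @export
gcmc_insert_unit <- function(state, chem, ff, unit = c("salt", "koh"),
                             topology = NULL) {
  unit <- .gcmc_unit(chem, match.arg(unit))
  n <- species_counts(state)[unit$species]
  proposal <- state
  for (s in unit$species)
    proposal <- .state_add(proposal, runif(3, 0, state$box), s)
  du <- total_energy(proposal, ff, topology) - total_energy(state, ff, topology)
  p <- gcmc_acceptance("insertion", n, unit$mu, state$box^3, du, chem$lambda3)
  if (runif(1) < p) list(state = proposal, accepted = TRUE, prob = p, delta_U = du)
  else list(state = state, accepted = FALSE, prob = p, delta_U = du)
}

#' Grand-canonical deletion of a charge-neutral unit
#'
#' Removes one random particle of each species of the unit; rejected
#' automatically when a species is absent.
#'
#' @inheritParams gcmc_insert_unit
#' @return List with `state`, `accepted`, `prob`, `delta_U`.
#' @export
gcmc_delete_unit <- function(state, chem, ff, unit = c("salt", "koh"),
                             topology = NULL) {
  unit <- .gcmc_unit(chem, match.arg(unit))
  n <- species_counts(state)[unit$species]
  if (any(n < 1))
    return(list(state = state, accepted = FALSE, prob = 0, delta_U = NA_real_))
  drop <- vapply(unit$species,
                 function(s) .pick_index(which(state$species == s)), 1L)
  proposal <- .state_remove(state, drop)
  du <- total_energy(proposal, ff, topology) - total_energy(state, ff, topology)
  p <- gcmc_acceptance("deletion", n, unit$mu, state$box^3, du, chem$lambda3)
  if (runif(1) < p) list(state = proposal, accepted = TRUE, prob = p, delta_U = du)
  else list(state = state, accepted = FALSE, prob = p, delta_U = du)
}

# ---------------------------------------------------------------------------
# hybrid scheduler

#' Hybrid MC/MD move schedule
#'
#' The production schedule attempts 30 MC moves per MD sweep, distributed
#' equally among reaction-ensemble, grand-canonical and charge-annealing
#' moves, followed by one MD sweep of 1000 steps.  Within each sweep the
#' move order is shuffled; each GCMC slot picks salt vs. KOH and insertion
#' vs. deletion by fair coin, and each reaction slot picks deprotonation
#' vs. protonation by fair coin, so detailed balance is maintained.
#'
#' @param mc_moves_per_sweep Total MC attempts per sweep.
#' @param partition Named integer vector `c(rxmc=, gcmc=, anneal=)`; must
#'   sum to `mc_moves_per_sweep`.  Defaults to equal thirds.
#' @param md_steps_per_sweep MD steps after each MC batch (0 = MC only).
#' @param audit_every Full-energy audit cadence in sweeps (0 disables);
#'   the running incremental energy is compared against a complete
#'   recomputation and re-synced.
#' @return A list of class `wpe_schedule`.
#' @export
make_schedule <- function(mc_moves_per_sweep = 30, partition = NULL,
                          md_steps_per_sweep = 1000, audit_every = 1) {
  if (is.null(partition)) {
    third <- mc_moves_per_sweep %/% 3
    partition <- c(rxmc = third, gcmc = third,
                   anneal = mc_moves_per_sweep - 2 * third)
  }
  if (!all(c("rxmc", "gcmc", "anneal") %in% names(partition)))
    stop("partition needs entries rxmc, gcmc, anneal")
  if (sum(partition) != mc_moves_per_sweep)
    stop("partition must sum to mc_moves_per_sweep")
  structure(list(mc_moves_per_sweep = as.integer(mc_moves_per_sweep),
                 partition = partition,
                 md_steps_per_sweep = as.integer(md_steps_per_sweep),
                 audit_every = as.integer(audit_every)),
            class = "wpe_schedule")
}

#' Run the hybrid MC/MD loop
#'
#' The production engine: for each sweep, the scheduled MC moves (shuffled)
#' are attempted with incremental energy evaluation, the incremental total
#' is audited against a full recomputation, and an MD sweep relaxes the
#' configuration.  Electroneutrality is asserted after every sweep.  All
#' randomness derives from `seed`.
#'
#' @param state Initial `wpe_state`.
#' @param ff A `wpe_forcefield` (adapted to the box via
#'   [forcefield_for_box()]).
#' @param chem A `wpe_chemostats`.
#' @param topology Optional `wpe_topology` (NULL for salt-only boxes).
#' @param schedule A `wpe_schedule`.
#' @param md A `wpe_md_params`.
#' @param n_sweeps Number of sweeps.
#' @param seed Integer seed.
#' @param titration `"explicit"` (reaction moves exchange hydroxide with the
#'   box, the production scheme) or `"implicit"` (bare identity changes
#'   weighted by \eqn{\mu}; the simplification used with the Debye-Hueckel
#'   comparison mode, where no explicit base is represented).
#' @return A list of class `wpe_run`: `state` (final), `series` (tibble of
#'   per-sweep observables: charge fraction `f`, radius of gyration `rg`,
#'   species counts, running energy), `attempts`/`accepts` per move class,
#'   `max_audit_drift` (worst incremental-vs-full energy discrepancy, kT).
#' @export
run_hybrid <- function(state, ff, chem, topology = NULL,
                       schedule = make_schedule(), md = md_params(),
                       n_sweeps, seed,
                       titration = c("explicit", "implicit")) {
  stopifnot(inherits(state, "wpe_state"), inherits(ff, "wpe_forcefield"),
            inherits(chem, "wpe_chemostats"), inherits(schedule, "wpe_schedule"))
  titration <- match.arg(titration)
  ff <- forcefield_for_box(ff, state$box)
  vel <- state$velocities
  if (nrow(vel) > 0 && all(vel == 0))
    vel <- maxwell_boltzmann_velocities(nrow(vel), md$temperature,
                                        seed = seed + 7L)
  a <- .state_cpp_args(state, topology)
  salt_sp <- if (chem$salt_on) chem$salt_species else c(3L, 4L)
  implicit <- titration == "implicit"
  mu_eff <- if (implicit) chem$mu else chem$mu_rxn
  out <- cpp_run_hybrid(
    a$pos, vel, a$species, a$box, a$bonds, unclass(ff),
    mu_eff,
    rxmc_on = schedule$partition[["rxmc"]] > 0 && (implicit || chem$koh_on),
    implicit_titration = implicit,
    salt_on = chem$salt_on, salt_species = salt_sp,
    salt_mu = as.numeric(chem$mu_salt),
    koh_on = chem$koh_on, koh_mu = as.numeric(chem$koh_mu),
    n_rxmc = schedule$partition[["rxmc"]],
    n_gcmc = schedule$partition[["gcmc"]],
    n_anneal = schedule$partition[["anneal"]],
    md_steps = schedule$md_steps_per_sweep,
    n_sweeps = as.integer(n_sweeps), dt = md$dt, friction = md$friction,
    temperature = md$temperature, seed = as.integer(seed),
    audit_every = schedule$audit_every)
  series <- tibble::as_tibble(as.data.frame(out$series))
  final <- make_state(out$positions, out$species, state$box, out$velocities)
  structure(
    list(state = final, series = series, attempts = out$attempts,
         accepts = out$accepts, max_audit_drift = out$max_audit_drift,
         energy = out$energy, ff = ff, chem = chem, schedule = schedule,
         seed = seed),
    class = "wpe_run"
  )
}

#' @export
print.wpe_run <- function(x, ...) {
  n <- nrow(x$series)
  cat("<wpe_run>", n, "sweeps;")
  if (n > 0) {
    last <- x$series[n, ]
    cat(" final f =", round(last$f, 4), "rg =", round(last$rg, 3))
  }
  cat("\n  acceptance:",
      paste(sprintf("%s %.3f", names(x$attempts),
                    ifelse(x$attempts > 0, x$accepts / x$attempts, NA)),
            collapse = ", "), "\n")
  invisible(x)
}

#' One hybrid step (MC batch + one MD sweep)
#'
#' Convenience wrapper over [run_hybrid()] with `n_sweeps = 1`.
#'
#' @inheritParams run_hybrid
#' @return A `wpe_run` of length one.
#' @export
hybrid_step <- function(state, ff, chem, topology = NULL,
                        schedule = make_schedule(), md = md_params(), seed) {
  run_hybrid(state, ff, chem, topology, schedule, md, n_sweeps = 1, seed = seed)
}
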