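# Langevin-thermostatted molecular dynamics relaxation sweeps.

#' MD integration parameters
#'
#' Defaults follow the production schedule: timestep \eqn{\delta t =
#' 0.01\tau}, 1000 velocity-Verlet/Langevin (BAOAB) steps per sweep,
#' temperature 1 \eqn{k_BT} and friction \eqn{1/\tau}.  The friction sets
#' kinetics only; equilibrium averages are independent of it.  With
#' `friction = 0` the integrator reduces to plain velocity Verlet
#' (symplectic, used by the energy-conservation checks).
#'
#' @param dt Timestep in \eqn{\tau}.
#' @param steps_per_sweep Steps in one MD sweep.
#' @param temperature Thermostat temperature in \eqn{k_BT}.
#' @param friction Langevin damping rate in \eqn{1/\tau}.
#' @return A list of class `wpe_md_params`.
#' @export
md_params <- function(dt = 0.01, steps_per_sweep = 1000, temperature = 1.0,
                      friction = 1.0) {
  stopifnot(dt > 0, steps_per_sweep >= 0, temperature > 0, friction >= 0)
  structure(list(dt = dt, steps_per_sweep = as.integer(steps_per_sweep),
                 temperature = temperature, friction = friction),
            class = "wpe_md_params")
}

#' Maxwell-Boltzmann velocities
#'
#' @param n Number of particles.
#' @param temperature Temperature in \eqn{k_BT} (unit mass).
#' @param seed Optional seed.
#' @return n x 3 matrix of velocities.
#' @export
maxwell_boltzmann_velocities <- function(n, temperature = 1.0, seed = NULL) {
  .with_seed(seed, matrix(rnorm(3 * n, sd = sqrt(temperature)), n, 3))
}

#' Run MD sweeps on a state
#'
#' Applies `nsteps` Langevin BAOAB steps (velocity Verlet with an
#' Ornstein-Uhlenbeck velocity kick) to the state.  Species identities and
#' counts are untouched; positions stay wrapped in the periodic cell.
#' Velocities are drawn fresh from Maxwell-Boltzmann when the state carries
#' none (all-zero).  A FENE bond stretched to \eqn{R_0} aborts with a
#' diagnostic.
#'
#' @param state A `wpe_state`.
#' @param ff A `wpe_forcefield`.
#' @param topology Optional `wpe_topology` (FENE bonds).
#' @param params A `wpe_md_params`.
#' @param nsteps Number of steps (defaults to `params$steps_per_sweep`).
#' @param seed Integer seed for the thermostat noise.
#' @param sample_every If positive, record kinetic energy (and the first
#'   bond length) every this many steps.
#' @return The updated `wpe_state`, with attributes `kinetic_energy`,
#'   `potential_energy`, and (if sampled) `ke_samples`, `bond_samples`.
#' @export
md_sweep <- function(state, ff, topology = NULL, params = md_params(),
                     nsteps = params$steps_per_sweep, seed = 1,
                     sample_every = 0) {
  stopifnot(inherits(state, "wpe_state"), inherits(ff, "wpe_forcefield"))
  if (nsteps == 0) return(state)
  vel <- state$velocities
  if (all(vel == 0) && nrow(vel) > 0)
    vel <- maxwell_boltzmann_velocities(nrow(vel), params$temperature,
                                        seed = seed + 1L)
  a <- .state_cpp_args(state, topology)
  out <- cpp_md_run(a$pos, vel, a$species, a$box, a$bonds, unclass(ff),
                    params$dt, params$friction, params$temperature,
                    as.integer(nsteps), as.integer(seed),
                    as.integer(sample_every), sample_every > 0)
  new <- make_state(out$positions, state$species, state$box, out$velocities)
  attr(new, "kinetic_energy") <- out$kinetic_energy
  attr(new, "potential_energy") <- out$potential_energy
  if (sample_every > 0) {
    attr(new, "ke_samples") <- out$ke_samples
    attr(new, "bond_samples") <- out$bond_samples
  }
  new
}
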