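# Deterministic generators for validation systems: ideal titration boxes,
# pure-salt boxes, rock-salt lattices.  Every fixture is charge-neutral and
# bit-reproducible per seed; no external data are involved.

#' Ideal titration box (Henderson-Hasselbalch limit)
#'
#' Non-interacting titratable monomers on a cubic grid, coupled to an
#' ideal KOH reservoir.  With all pair interactions disabled the reaction
#' and exchange moves sample the exact grand-canonical ideal gas, so the
#' stationary charged fraction must satisfy
#' \eqn{f = 10^{pH - pK_a} / (1 + 10^{pH - pK_a})} independent of the
#' hydroxide concentration.
#'
#' @param n_monomers Number of titratable beads.
#' @param mu Charging chemical potential \eqn{\ln 10 (pH - pK_a)}.
#' @param koh_conc KOH reservoir concentration in mol/L.
#' @param box Box edge in \eqn{\sigma}.
#' @param seed Integer seed for the initial ion placement.
#' @return List with `state`, `chem` (`wpe_chemostats`), `ff` (interactions
#'   off) and `schedule` (RxMC + GCMC only, no MD).
#' @export
make_ideal_titration_box <- function(n_monomers, mu, koh_conc = 0.002,
                                     box = 64.6, seed = 1) {
  stopifnot(n_monomers >= 1, box > 0)
  side <- ceiling(n_monomers^(1 / 3))
  spacing <- box / side
  idx <- seq_len(n_monomers) - 1L
  pos <- cbind((idx %% side), (idx %/% side) %% side, idx %/% side^2) * spacing +
    spacing / 2
  state <- make_state(pos, rep(1L, n_monomers), box)
  n_koh <- max(1L, round(concentration_to_count(koh_conc, box)))
  state <- place_ions(state, c("K+" = n_koh, "OH-" = n_koh), seed = seed,
                      min_sep = 0)
  list(state = state,
       chem = make_chemostats(mu = mu, koh_conc = koh_conc, salt = "none"),
       ff = ideal_forcefield(),
       schedule = make_schedule(30, c(rxmc = 15, gcmc = 15, anneal = 0),
                                md_steps_per_sweep = 0, audit_every = 0))
}

#' Pure-salt box for reservoir calibration
#'
#' An initially empty periodic box coupled to a salt reservoir at the given
#' per-species chemical potential; GCMC fills it to the equilibrium
#' occupancy.  With `ideal = TRUE` interactions are disabled and the mean
#' occupancy per species is exactly \eqn{e^{\beta\mu} V / \Lambda^3}.
#'
#' @param salt `"nacl"` or `"mgso4"`.
#' @param mu Per-species chemical potential in \eqn{k_BT}.
#' @param box Box edge in \eqn{\sigma}.
#' @param ideal Disable interactions.
#' @param seed Integer seed.
#' @return List with `state`, `chem`, `ff`, `schedule`.
#' @export
make_salt_box <- function(salt = c("nacl", "mgso4"), mu, box = 64.6,
                          ideal = FALSE, seed = 1) {
  salt <- match.arg(salt)
  state <- make_state(matrix(numeric(0), 0, 3), integer(0), box)
  chem <- make_chemostats(mu = 0, koh_conc = 0, salt = salt, salt_conc = 1,
                          mu_salt = c(mu, mu))
  ff <- if (ideal) ideal_forcefield() else forcefield_for_box(make_forcefield(), box)
  list(state = state, chem = chem, ff = ff,
       schedule = make_schedule(30, c(rxmc = 0, gcmc = 30, anneal = 0),
                                md_steps_per_sweep = 0,
                                audit_every = if (ideal) 0L else 10L))
}

#' Rock-salt lattice of alternating unit charges
#'
#' `8 * n_cells^3` alternating +1/-1 charges (Na+/Cl- identities) on a
#' cubic lattice with the given spacing, in a periodic box of edge
#' `2 * n_cells * spacing`.  The Ewald Coulomb energy per ion of this
#' configuration must equal \eqn{-M \lambda_B / a} with M the Madelung
#' constant of the NaCl structure (1.747565), which makes the lattice the
#' standard oracle for the electrostatics solver.
#'
#' @param n_cells Number of conventional (8-ion) cells per dimension.
#' @param spacing Nearest-neighbor distance a in \eqn{\sigma}.
#' @return A `wpe_state`.
#' @export
make_nacl_lattice <- function(n_cells = 2, spacing = 1) {
  stopifnot(n_cells >= 1, spacing > 0)
  m <- 2L * n_cells
  g <- expand.grid(x = 0:(m - 1), y = 0:(m - 1), z = 0:(m - 1))
  parity <- (g$x + g$y + g$z) %% 2
  pos <- as.matrix(g) * spacing
  species <- ifelse(parity == 0, 3L, 4L)  # Na+ on even, Cl- on odd sites
  make_state(pos, species, box = m * spacing)
}
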