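# Force-field parameters and energy/force evaluation: truncated-shifted
# Lennard-Jones, FENE bonds, Ewald-summed Coulomb, and the optional
# Debye-Hueckel screened mode.

#' Construct a force field
#'
#' Defaults reproduce the production model: an adhesive monomer-monomer
#' Lennard-Jones well truncated and shifted at \eqn{2.5\sigma}, purely
#' repulsive (WCA) ion-ion and monomer-ion interactions cut at
#' \eqn{2^{1/6}\sigma}, \eqn{\epsilon = 1\,k_BT} for every pair, FENE bonds
#' with \eqn{K = 7\,\epsilon/\sigma^2} and \eqn{R_0 = 2\sigma}, and Coulomb
#' interactions at Bjerrum length \eqn{\lambda_B = 2.8\sigma} evaluated by
#' Ewald summation with real-space cutoff \eqn{18\sigma} and dimensionless
#' force accuracy \eqn{10^{-5}}.  Charged and neutral monomers share one LJ
#' identity, and bonded pairs also interact through the full LJ term
#' (Kremer-Grest convention, no intra-bond exclusion).
#'
#' `electrostatics = "dh"` activates an implicit-salt Debye-Hueckel mode
#' (screened pairwise Coulomb, shifted to zero at `dh_rcut`); it is an
#' experimental comparison mode, not the production path.
#' `electrostatics = "none"` with `lj_on = FALSE` turns all pair
#' interactions off (ideal-gas limit used by the statistical-mechanics
#' oracles).
#'
#' @param epsilon LJ well depth in \eqn{k_BT}.
#' @param rcut_mm Monomer-monomer LJ cutoff in \eqn{\sigma}.
#' @param rcut_ion Ion-ion and monomer-ion LJ cutoff in \eqn{\sigma}.
#' @param K FENE spring constant in \eqn{\epsilon/\sigma^2}.
#' @param R0 FENE maximum extension in \eqn{\sigma}.
#' @param lambda_B Bjerrum length in \eqn{\sigma}.
#' @param electrostatics `"ewald"`, `"dh"` or `"none"`.
#' @param ewald_accuracy Dimensionless force accuracy of the Ewald sum.
#' @param ewald_rcut Real-space Ewald cutoff in \eqn{\sigma} (must be less
#'   than half the box edge; see [forcefield_for_box()]).
#' @param lambda_D Debye length for the `"dh"` mode, in \eqn{\sigma}.
#' @param dh_rcut Cutoff of the screened interaction; defaults to
#'   \eqn{4\lambda_D} (capped at 20).
#' @param lj_on Evaluate LJ interactions at all.
#' @return An object of class `wpe_forcefield`.
#' @export
make_forcefield <- function(epsilon = 1, rcut_mm = 2.5,
                            rcut_ion = 2^(1 / 6), K = 7, R0 = 2,
                            lambda_B = 2.8,
                            electrostatics = c("ewald", "dh", "none"),
                            ewald_accuracy = 1e-5, ewald_rcut = 18,
                            lambda_D = Inf, dh_rcut = NULL, lj_on = TRUE) {
  electrostatics <- match.arg(electrostatics)
  stopifnot(epsilon >= 0, rcut_mm > 0, rcut_ion > 0, K > 0, R0 > 0,
            lambda_B > 0, ewald_accuracy > 0, ewald_rcut > 0, lambda_D > 0)
  if (is.null(dh_rcut))
    dh_rcut <- if (is.finite(lambda_D)) min(4 * lambda_D, 20) else 20
  structure(
    list(epsilon = epsilon, rcut_mm = rcut_mm, rcut_ion = rcut_ion,
         K = K, R0 = R0, lambda_B = lambda_B,
         electrostatics = electrostatics,
         coulomb_mode = match(electrostatics, c("none", "ewald", "dh")) - 1L,
         ewald_accuracy = ewald_accuracy, ewald_rcut = ewald_rcut,
         lambda_D = lambda_D, dh_rcut = dh_rcut, lj_on = lj_on),
    class = "wpe_forcefield"
  )
}

#' @export
print.wpe_forcefield <- function(x, ...) {
  cat("<wpe_forcefield> eps =", x$epsilon,
      "| rcut mm/ion =", x$rcut_mm, "/", round(x$rcut_ion, 4),
      "| FENE K =", x$K, "R0 =", x$R0,
      "| lambda_B =", x$lambda_B,
      "| electrostatics =", x$electrostatics, "\n")
  invisible(x)
}

#' Ideal-gas (non-interacting) force field
#'
#' Convenience wrapper used by the titration and chemostat oracles: no LJ,
#' no electrostatics, FENE bonds retained only if requested.
#'
#' @param keep_bonds Unused placeholder for symmetry; bonds are evaluated
#'   whenever the topology defines them.
#' @return A `wpe_forcefield`.
#' @export
ideal_forcefield <- function(keep_bonds = TRUE) {
  make_forcefield(electrostatics = "none", lj_on = FALSE)
}

#' Adapt a force field to a finite box
#'
#' The Ewald real-space cutoff must satisfy `ewald_rcut < box/2`; for boxes
#' smaller than the production cell the cutoff is reduced to `0.44 * box`
#' (the splitting parameter and reciprocal cutoff are rechosen accordingly,
#' so the target accuracy is preserved).
#'
#' @param ff A `wpe_forcefield`.
#' @param box Box edge in \eqn{\sigma}.
#' @return A `wpe_forcefield` valid for the box.
#' @export
forcefield_for_box <- function(ff, box) {
  stopifnot(inherits(ff, "wpe_forcefield"))
  if (ff$electrostatics == "ewald" && ff$ewald_rcut >= box / 2)
    ff$ewald_rcut <- 0.44 * box
  if (ff$electrostatics == "dh" && ff$dh_rcut >= box / 2)
    ff$dh_rcut <- 0.44 * box
  ff
}

#' Truncated-shifted Lennard-Jones pair energy
#'
#' \eqn{U(r) = U_{LJ}(r) - U_{LJ}(r_{cut})} for \eqn{r < r_{cut}}, zero
#' beyond, with \eqn{U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} -
#' (\sigma/r)^6]}.  Continuous at the cutoff.
#'
#' @param r Pair separation(s) in \eqn{\sigma}; must be positive.
#' @param r_cut Cutoff in \eqn{\sigma}.
#' @param epsilon Well depth in \eqn{k_BT}.
#' @param sigma Length scale (1 in reduced units).
#' @return Energy in \eqn{k_BT}.
#' @export
#' @examples
#' lj_pair_energy(2^(1 / 6), r_cut = 2.5)  # adhesive minimum, ~ -0.9837 kT
lj_pair_energy <- function(r, r_cut, epsilon = 1, sigma = 1) {
  if (any(r <= 0)) stop("lj_pair_energy diverges at r = 0; r must be > 0")
  raw <- function(x) { s6 <- (sigma / x)^6; 4 * epsilon * (s6^2 - s6) }
  ifelse(r < r_cut, raw(r) - raw(r_cut), 0)
}

#' FENE bond energy
#'
#' \eqn{U(r) = -\frac{1}{2} K R_0^2 \ln[1 - (r/R_0)^2]}: zero at \eqn{r=0},
#' monotone increasing, divergent as \eqn{r \to R_0}.  Separations at or
#' beyond \eqn{R_0} return `Inf`, the infinite-energy signal that rejects
#' Monte Carlo moves and aborts MD integration.
#'
#' @param r Bond length(s) in \eqn{\sigma}.
#' @param K Spring constant in \eqn{\epsilon/\sigma^2}.
#' @param R0 Maximum extension in \eqn{\sigma}.
#' @return Energy in \eqn{k_BT}.
#' @export
#' @examples
#' fene_energy(1)  # 14 log(4/3) ~ 4.0275 kT
fene_energy <- function(r, K = 7, R0 = 2) {
  if (any(r < 0)) stop("bond length must be >= 0")
  ifelse(r >= R0, Inf, -0.5 * K * R0^2 * log(1 - (r / R0)^2))
}

#' Debye-Hueckel screened pair energy
#'
#' \eqn{U(r) = k_BT\,\lambda_B q_i q_j \exp(-r/\lambda_D)/r}, truncated at
#' `r_cut` (and optionally shifted to zero there, the convention the MD
#' engine uses so that the potential is continuous).  In the
#' \eqn{\lambda_D \to \infty} limit this is the bare Coulomb interaction.
#'
#' @param r Separation(s) in \eqn{\sigma}.
#' @param q_i,q_j Integer valences.
#' @param lambda_D Debye screening length in \eqn{\sigma}.
#' @param lambda_B Bjerrum length in \eqn{\sigma}.
#' @param r_cut Cutoff (default `Inf`, no truncation).
#' @param shift Shift the potential to zero at `r_cut`.
#' @return Energy in \eqn{k_BT}.
#' @export
dh_pair_energy <- function(r, q_i, q_j, lambda_D, lambda_B = 2.8,
                           r_cut = Inf, shift = FALSE) {
  if (any(r <= 0)) stop("dh_pair_energy diverges at r = 0; r must be > 0")
  if (any(lambda_D <= 0)) stop("lambda_D must be > 0")
  kernel <- function(x)
    ifelse(is.finite(lambda_D), exp(-x / lambda_D) / x, 1 / x)
  sh <- if (shift && is.finite(r_cut)) kernel(r_cut) else 0
  ifelse(r < r_cut, lambda_B * q_i * q_j * (kernel(r) - sh), 0)
}

#' @noRd
.state_cpp_args <- function(state, topology = NULL) {
  bonds <- if (is.null(topology)) matrix(integer(0), 0, 2) else topology$bonds
  list(pos = state$positions, species = as.integer(state$species),
       box = state$box, bonds = bonds)
}

#' Total potential energy of a state
#'
#' \eqn{U = U_{LJ} + U_{FENE} + U_{coul}}, with the Coulomb part evaluated
#' by Ewald summation (real + reciprocal + self) for
#' `electrostatics = "ewald"`, by the screened pair sum for `"dh"`, or
#' omitted for `"none"`.  The Ewald path requires an electroneutral state.
#'
#' @param state A `wpe_state`.
#' @param ff A `wpe_forcefield`.
#' @param topology Optional `wpe_topology` supplying the FENE bond list.
#' @param components Return the per-term breakdown instead of the total.
#' @return Energy in \eqn{k_BT}, or a list with `lj`, `fene`, `coulomb`,
#'   `total` when `components = TRUE`.
#' @export
total_energy <- function(state, ff, topology = NULL, components = FALSE) {
  stopifnot(inherits(state, "wpe_state"), inherits(ff, "wpe_forcefield"))
  a <- .state_cpp_args(state, topology)
  e <- cpp_energy(a$pos, a$species, a$box, a$bonds, unclass(ff))
  if (components) e else e$total
}

#' Coulomb energy of a state
#'
#' @inheritParams total_energy
#' @return Electrostatic energy in \eqn{k_BT}.
#' @export
coulomb_energy <- function(state, ff) {
  total_energy(state, ff, NULL, components = TRUE)$coulomb
}

#' Forces on all particles
#'
#' Exact negative gradients of [total_energy()] (validated against finite
#' differences in the test suite).
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces in \eqn{k_BT/\sigma}.
#' @export
forces <- function(state, ff, topology = NULL) {
  stopifnot(inherits(state, "wpe_state"), inherits(ff, "wpe_forcefield"))
  a <- .state_cpp_args(state, topology)
  cpp_forces(a$pos, a$species, a$box, a$bonds, unclass(ff))
}

#' Ewald parameters chosen for a box and accuracy
#'
#' The splitting parameter is set from the standard real-space error
#' estimate \eqn{\alpha = (1.35 - 0.15 \ln \epsilon)/r_{cut}} and the
#' reciprocal cutoff so the Gaussian tail matches the same accuracy.
#'
#' @param box Box edge in \eqn{\sigma}.
#' @param lambda_B Bjerrum length.
#' @param accuracy Dimensionless force accuracy.
#' @param rcut Real-space cutoff in \eqn{\sigma}.
#' @return List with `alpha`, `kmax`, `n_kvec`.
#' @export
ewald_params <- function(box, lambda_B = 2.8, accuracy = 1e-5, rcut = 18) {
  stopifnot(rcut < box / 2)
  cpp_ewald_setup(box, lambda_B, accuracy, rcut)
}
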