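# Reduced-unit system, species registry, simulation state and unit
# conversions between reduced and molar quantities.

#' @noRd
.avogadro <- 6.02214076e23

#' Reduced-unit conventions
#'
#' Returns the unit system used throughout the simulator.  Energies are in
#' \eqn{k_BT} (\eqn{\equiv 1}), masses in \eqn{m_0} (\eqn{\equiv 1}), lengths
#' in \eqn{\sigma} and times in \eqn{\tau = \sigma\sqrt{m_0/\epsilon}}
#' (\eqn{\equiv 1}).  The length scale maps to physical units through
#' `sigma_nm`, the bead diameter in nanometres (default 0.25 nm, the repeat
#' unit length of a polyethylene backbone).  The thermal de Broglie
#' wavelength enters every insertion/deletion and reaction acceptance rule;
#' it is fixed at \eqn{\Lambda = 1\sigma} for all species, which leaves all
#' physical observables unchanged as long as the same value is used in the
#' reservoir calibration (see the package vignette).
#'
#' @param sigma_nm Physical length of one reduced unit, in nm.
#' @param lambda_debroglie Thermal de Broglie wavelength in \eqn{\sigma}.
#' @return A list with fields `sigma_nm`, `kT`, `m0`, `tau`,
#'   `lambda_debroglie`.
#' @export
#' @examples
#' wpe_units()
wpe_units <- function(sigma_nm = 0.25, lambda_debroglie = 1) {
  stopifnot(sigma_nm > 0, lambda_debroglie > 0)
  list(sigma_nm = sigma_nm, kT = 1, m0 = 1, tau = 1,
       lambda_debroglie = lambda_debroglie)
}

#' Species registry
#'
#' The eight species of the model: titratable monomer beads in their neutral
#' (`MH`) and deprotonated (`Mminus`) states, the monovalent salt pair
#' `Na+`/`Cl-`, the base pair `K+`/`OH-` and the divalent pair
#' `Mg2+`/`SO4--`.  `K+` and `Na+` have identical interactions but are
#' tracked as independent entities.  Monomers are never exchanged with a
#' reservoir; ions are never titrated.
#'
#' @return A data frame with columns `name`, `code`, `valence`, `mobile`,
#'   `titratable`.
#' @export
species_table <- function() {
  data.frame(
    name = c("MH", "Mminus", "Na+", "Cl-", "K+", "OH-", "Mg2+", "SO4--"),
    code = 1:8,
    valence = c(0L, -1L, 1L, -1L, 1L, -1L, 2L, -2L),
    mobile = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    titratable = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @noRd
.species_valence <- c(0L, -1L, 1L, -1L, 1L, -1L, 2L, -2L)

#' @noRd
.species_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(x < 1L | x > 8L)) stop("species codes must be in 1..8")
    return(x)
  }
  tab <- species_table()
  idx <- match(x, tab$name)
  if (anyNA(idx)) stop("unknown species name: ", paste(x[is.na(idx)], collapse = ", "))
  idx
}

#' Construct a simulation state
#'
#' A state is the single mutable object all Monte Carlo and molecular
#' dynamics moves act on: particle positions (wrapped into the periodic
#' cube), velocities, species identities, and the box edge length.
#'
#' @param positions N x 3 matrix of coordinates in \eqn{\sigma}.
#' @param species Integer codes (1..8) or species names; see
#'   [species_table()].  Monomer beads (`MH`, `Mminus`) must precede all
#'   ions.
#' @param box Edge length of the periodic cube in \eqn{\sigma}.
#' @param velocities Optional N x 3 matrix; defaults to zeros.
#' @return An object of class `wpe_state`.
#' @export
make_state <- function(positions, species, box, velocities = NULL) {
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(numeric(0), 0, 3)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  species <- .species_code(species)
  if (length(species) != nrow(positions))
    stop("species must have one entry per particle")
  if (!is.numeric(box) || length(box) != 1 || box <= 0)
    stop("box must be a positive scalar edge length")
  mono <- species <= 2L
  if (any(mono) && any(diff(mono) > 0))
    stop("monomer beads must precede all ions in the state")
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  if (length(velocities) == 0) velocities <- matrix(numeric(0), 0, 3)
  if (!all(dim(velocities) == dim(positions)))
    stop("velocities must match positions in shape")
  positions <- positions - box * floor(positions / box)
  structure(
    list(box = box, positions = positions, velocities = velocities,
         species = species),
    class = "wpe_state"
  )
}

#' @export
print.wpe_state <- function(x, ...) {
  tab <- table(factor(species_table()$name[x$species],
                      levels = species_table()$name))
  cat("<wpe_state>", nrow(x$positions), "particles in a",
      sprintf("(%.4g sigma)^3", x$box), "box\n")
  cat("  counts:", paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
                         collapse = " "), "\n")
  cat("  net charge:", net_charge(x), "\n")
  invisible(x)
}

#' Per-species particle counts
#'
#' @param state A `wpe_state`.
#' @return Named integer vector over all eight species.
#' @export
species_counts <- function(state) {
  tab <- tabulate(state$species, nbins = 8L)
  setNames(as.integer(tab), species_table()$name)
}

#' Net charge of a state
#'
#' Sum of valences over all particles.  Electroneutrality (net charge zero)
#' is required by the Ewald sum and is preserved exactly by every Monte
#' Carlo move; this function is the guard used in tests.
#'
#' @param state A `wpe_state`.
#' @return Integer total charge.
#' @export
net_charge <- function(state) {
  sum(.species_valence[state$species])
}

#' Convert a molar concentration to an expected particle number
#'
#' Realizes a bulk concentration in the reduced-unit periodic box:
#' `conc_molar * N_A * (box_length * sigma_nm)^3` with the box volume
#' expressed in litres.
#'
#' @param conc_molar Concentration in mol/L.
#' @param box_length Box edge in \eqn{\sigma}.
#' @param sigma_nm Length of \eqn{\sigma} in nm.
#' @return Expected particle number (real-valued).
#' @export
#' @examples
#' concentration_to_count(0.1, 64.6)    # ~253.7 particles per species
#' concentration_to_count(0.002, 64.6)  # ~5.07 hydroxide ions
concentration_to_count <- function(conc_molar, box_length, sigma_nm = 0.25) {
  if (any(conc_molar < 0)) stop("conc_molar must be >= 0")
  if (any(box_length <= 0)) stop("box_length must be > 0")
  vol_l <- (box_length * sigma_nm * 1e-9)^3 * 1e3  # m^3 -> L
  conc_molar * .avogadro * vol_l
}

#' Convert a particle number to a molar concentration
#'
#' Exact inverse of [concentration_to_count()].
#'
#' @inheritParams concentration_to_count
#' @param count Particle number.
#' @return Concentration in mol/L.
#' @export
count_to_concentration <- function(count, box_length, sigma_nm = 0.25) {
  if (any(count < 0)) stop("count must be >= 0")
  if (any(box_length <= 0)) stop("box_length must be > 0")
  vol_l <- (box_length * sigma_nm * 1e-9)^3 * 1e3
  count / (.avogadro * vol_l)
}

#' Reduced number density for a molar concentration
#'
#' @inheritParams concentration_to_count
#' @return Particles per \eqn{\sigma^3}.
#' @export
concentration_to_density <- function(conc_molar, sigma_nm = 0.25) {
  if (any(conc_molar < 0)) stop("conc_molar must be >= 0")
  conc_molar * .avogadro * 1e3 * (sigma_nm * 1e-9)^3
}

#' @rdname concentration_to_density
#' @param density Particles per \eqn{\sigma^3}.
#' @export
density_to_concentration <- function(density, sigma_nm = 0.25) {
  density / (.avogadro * 1e3 * (sigma_nm * 1e-9)^3)
}

# run expr with a locally seeded RNG, restoring the caller's stream
#' @noRd
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
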