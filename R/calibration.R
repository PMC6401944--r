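# Reservoir calibration: map chemical potentials to bulk concentrations by
# pure-salt GCMC, and convert concentrations to Debye screening lengths.

#' Ideal-gas chemical potential for a target concentration
#'
#' \eqn{\mu = \ln(\rho \Lambda^3)} with \eqn{\rho} the reduced number
#' density.  This is the exact mapping for a non-interacting reservoir and
#' the starting point for calibrating interacting ones.
#'
#' @param conc_molar Concentration in mol/L.
#' @param sigma_nm Length of \eqn{\sigma} in nm.
#' @param lambda3 \eqn{\Lambda^3} in \eqn{\sigma^3}.
#' @return Chemical potential in \eqn{k_BT}.
#' @export
ideal_mu <- function(conc_molar, sigma_nm = 0.25, lambda3 = 1) {
  if (any(conc_molar <= 0)) stop("conc_molar must be > 0")
  log(concentration_to_density(conc_molar, sigma_nm) * lambda3)
}

#' @rdname ideal_mu
#' @param mu Chemical potential in \eqn{k_BT}.
#' @export
ideal_concentration <- function(mu, sigma_nm = 0.25, lambda3 = 1) {
  density_to_concentration(exp(mu) / lambda3, sigma_nm)
}

#' Measure the bulk concentration at a chemical potential
#'
#' Runs a polymer-free GCMC simulation of the pure salt at per-species
#' chemical potential `mu`, with the same force field as production, and
#' converts the average occupancy of the box to mol/L.  The mean is block
#' averaged after discarding the equilibration fraction; a first-half vs.
#' second-half trend test flags non-converged occupancies.
#'
#' @param mu Per-species chemical potential in \eqn{k_BT}.
#' @param salt `"nacl"`, `"mgso4"` or `"koh"`.
#' @param box Box edge in \eqn{\sigma} (defaults to the production cell).
#' @param ff Force field; defaults to the production WCA + Ewald model.
#'   Use [ideal_forcefield()] for the exact ideal-gas check.
#' @param n_sweeps GCMC sweeps (30 attempted exchanges each).
#' @param seed Integer seed.
#' @param equilibration Fraction of sweeps discarded.
#' @param sigma_nm Length of \eqn{\sigma} in nm.
#' @return List: `concentration` (mol/L), `se`, `mean_count`, `mu`,
#'   `converged` (trend test), `series`.
#' @export
calibrate_salt <- function(mu, salt = c("nacl", "mgso4", "koh"), box = 64.6,
                           ff = make_forcefield(), n_sweeps = 400, seed = 1,
                           equilibration = 0.5, sigma_nm = 0.25) {
  salt <- match.arg(salt)
  ff <- forcefield_for_box(ff, box)
  chem <- if (salt == "koh") {
    make_chemostats(mu = 0, koh_conc = 0, salt = "none", mu_OH = mu,
                    sigma_nm = sigma_nm)
  } else {
    make_chemostats(mu = 0, koh_conc = 0, salt = salt, salt_conc = 1,
                    mu_salt = c(mu, mu), sigma_nm = sigma_nm)
  }
  chem$koh_on <- salt == "koh"
  chem$salt_on <- salt != "koh"
  empty <- make_state(matrix(numeric(0), 0, 3), integer(0), box)
  sched <- make_schedule(30, c(rxmc = 0, gcmc = 30, anneal = 0),
                         md_steps_per_sweep = 0, audit_every = 10)
  run <- run_hybrid(empty, ff, chem, NULL, sched, md_params(), n_sweeps, seed)
  col <- switch(salt, nacl = "n_na", mgso4 = "n_mg", koh = "n_oh")
  counts <- run$series[[col]]
  ba <- block_average(counts, equilibration = equilibration, blocks = 10)
  kept <- counts[-seq_len(floor(equilibration * length(counts)))]
  half <- length(kept) %/% 2
  m1 <- mean(kept[seq_len(half)]); m2 <- mean(kept[-seq_len(half)])
  converged <- abs(m2 - m1) <= 3 * max(ba$se, .Machine$double.eps) * sqrt(2)
  conc <- count_to_concentration(ba$mean, box, sigma_nm)
  list(concentration = conc,
       se = count_to_concentration(ba$se, box, sigma_nm),
       mean_count = ba$mean, mu = mu, converged = converged,
       series = counts)
}

#' Find the chemical potential that realizes a target concentration
#'
#' Bisection on `mu` around the ideal-gas value using [calibrate_salt()];
#' stops when the measured concentration is within `tol_se` standard
#' errors of the target.
#'
#' @inheritParams calibrate_salt
#' @param target_conc Target bulk concentration in mol/L.
#' @param max_iter Bisection iterations.
#' @param tol_se Convergence tolerance in standard errors.
#' @return List: `mu`, `concentration`, `se`, `iterations`.
#' @export
calibrate_mu_for_concentration <- function(target_conc,
                                           salt = c("nacl", "mgso4", "koh"),
                                           box = 64.6, ff = make_forcefield(),
                                           n_sweeps = 400, seed = 1,
                                           max_iter = 12, tol_se = 2,
                                           sigma_nm = 0.25) {
  salt <- match.arg(salt)
  # at Bjerrum coupling 2.8 ion association raises the occupancy above the
  # ideal value, so the calibrated mu sits below the ideal mapping; the
  # divalent pair associates far more strongly, hence the wider bracket
  mu0 <- ideal_mu(target_conc, sigma_nm)
  lo <- mu0 - (if (salt == "mgso4") 5 else 2.5)
  hi <- mu0 + 1.5
  res <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    res <- calibrate_salt(mid, salt, box, ff, n_sweeps, seed + it, sigma_nm = sigma_nm)
    if (abs(res$concentration - target_conc) <= tol_se * res$se) {
      return(list(mu = mid, concentration = res$concentration, se = res$se,
                  iterations = it))
    }
    if (res$concentration > target_conc) hi <- mid else lo <- mid
  }
  list(mu = (lo + hi) / 2, concentration = res$concentration, se = res$se,
       iterations = max_iter)
}

#' Debye screening length of a salt reservoir
#'
#' \eqn{\lambda_D = (8\pi\lambda_B I_n)^{-1/2}} with \eqn{I_n =
#' \frac{1}{2}\sum_i \rho_i z_i^2} the ionic strength as a reduced number
#' density.  For a 1:1 salt at molar concentration c the molar ionic
#' strength is c; for a 2:2 salt it is 4c, so equal ionic strengths give
#' identical screening lengths.  The KOH buffer is not included (axes are
#' labelled by the salt reservoir alone).
#'
#' @param concentration Salt concentration in mol/L.
#' @param salt `"nacl"` (1:1) or `"mgso4"` (2:2).
#' @param lambda_B Bjerrum length in \eqn{\sigma}.
#' @param sigma_nm Length of \eqn{\sigma} in nm.
#' @return \eqn{\lambda_D} in \eqn{\sigma} (`Inf` at zero concentration).
#' @export
#' @examples
#' debye_length(0.1, "nacl")  # ~ 3.89 sigma
debye_length <- function(concentration, salt = c("nacl", "mgso4"),
                         lambda_B = 2.8, sigma_nm = 0.25) {
  salt <- match.arg(salt)
  if (any(concentration < 0)) stop("concentration must be >= 0")
  i_molar <- switch(salt, nacl = concentration, mgso4 = 4 * concentration)
  i_n <- concentration_to_density(i_molar, sigma_nm)
  ifelse(i_n == 0, Inf, 1 / sqrt(8 * pi * lambda_B * i_n))
}

#' @rdname debye_length
#' @param lambda_D Target Debye length in \eqn{\sigma}.
#' @export
concentration_for_debye <- function(lambda_D, salt = c("nacl", "mgso4"),
                                    lambda_B = 2.8, sigma_nm = 0.25) {
  salt <- match.arg(salt)
  if (any(lambda_D <= 0)) stop("lambda_D must be > 0")
  i_n <- 1 / (8 * pi * lambda_B * lambda_D^2)
  i_molar <- density_to_concentration(i_n, sigma_nm)
  switch(salt, nacl = i_molar, mgso4 = i_molar / 4)
}

#' Calibration curve over a set of chemical potentials
#'
#' @inheritParams calibrate_salt
#' @param mus Vector of per-species chemical potentials.
#' @return A tibble with columns `mu`, `concentration`, `se`, `lambda_D`.
#' @export
calibration_curve <- function(mus, salt = c("nacl", "mgso4"), box = 64.6,
                              ff = make_forcefield(), n_sweeps = 400,
                              seed = 1, sigma_nm = 0.25) {
  salt <- match.arg(salt)
  rows <- lapply(seq_along(mus), function(k) {
    r <- calibrate_salt(mus[k], salt, box, ff, n_sweeps, seed + k,
                        sigma_nm = sigma_nm)
    tibble::tibble(mu = mus[k], concentration = r$concentration, se = r$se,
                   lambda_D = debye_length(r$concentration, salt,
                                           ff$lambda_B, sigma_nm))
  })
  do.call(rbind, rows)
}
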