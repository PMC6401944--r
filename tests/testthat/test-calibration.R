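test_that("ideal-gas mapping between mu and concentration is exact", {
  for (conc in c(0.002, 0.05, 0.5)) {
    expect_equal(ideal_concentration(ideal_mu(conc)), conc, tolerance = 1e-12)
  }
  # mu -> -Inf limit empties the reservoir
  expect_lt(ideal_concentration(-40), 1e-12)
  expect_error(ideal_mu(0), "must be > 0")
})

test_that("ideal pure-salt GCMC hits the closed-form occupancy exactly", {
  mu <- log(60 / 8000)   # 60 particles per species in a 20^3 box
  res <- calibrate_salt(mu, "nacl", box = 20, ff = ideal_forcefield(),
                        n_sweeps = 1200, seed = 4)
  expect_lt(abs(res$mean_count - 60), 3 * res$se / count_to_concentration(1, 20) + 3)
  expect_equal(res$concentration, count_to_concentration(60, 20),
               tolerance = 0.1)
  expect_true(res$converged)
})

test_that("interacting 1:1 salt departs from the ideal occupancy as coupled physics dictates", {
  mu <- log(60 / 8000)
  # pure WCA (charges off): excluded volume alone depresses the occupancy
  ff_wca <- make_forcefield(electrostatics = "none")
  res_wca <- calibrate_salt(mu, "nacl", box = 20, ff = ff_wca,
                            n_sweeps = 1200, seed = 5)
  expect_lt(res_wca$mean_count, 60 + 3 * res_wca$se /
              count_to_concentration(1, 20))
  # with Coulomb at Bjerrum length 2.8, ion-pair association wins and the
  # occupancy rises well above ideal
  res_coul <- calibrate_salt(mu, "nacl", box = 20,
                             ff = forcefield_for_box(make_forcefield(), 20),
                             n_sweeps = 1200, seed = 6)
  expect_gt(res_coul$mean_count, res_wca$mean_count)
  expect_gt(res_coul$mean_count, 60)
})

test_that("bisection reproduces a target concentration within 2 SE", {
  target <- count_to_concentration(40, 20)
  res <- calibrate_mu_for_concentration(target, "nacl", box = 20,
                                        ff = ideal_forcefield(),
                                        n_sweeps = 800, seed = 2)
  expect_lt(abs(res$concentration - target), 2.5 * res$se)
})

test_that("Debye length follows the ionic-strength formula", {
  # 0.1 M 1:1 salt at lambda_B = 2.8, sigma = 0.25 nm
  expect_equal(debye_length(0.1, "nacl"), 3.886, tolerance = 1e-3)
  expect_equal(debye_length(0, "nacl"), Inf)
  # matched ionic strength gives identical screening: I(2:2 at c) = I(1:1 at 4c)
  expect_equal(debye_length(0.025, "mgso4"), debye_length(0.1, "nacl"),
               tolerance = 1e-12)
  # 2:2 at equal concentration screens twice as hard
  expect_equal(debye_length(0.1, "mgso4"), debye_length(0.1, "nacl") / 2,
               tolerance = 1e-12)
  expect_equal(concentration_for_debye(debye_length(0.07, "mgso4"), "mgso4"),
               0.07, tolerance = 1e-10)
})

test_that("calibration curves are monotone in mu", {
  mus <- log(c(10, 40, 160) / 8000)
  curve <- calibration_curve(mus, "nacl", box = 20, ff = ideal_forcefield(),
                             n_sweeps = 600, seed = 8)
  expect_true(all(diff(curve$concentration) > 0))
  expect_true(all(diff(curve$lambda_D) < 0))
})
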