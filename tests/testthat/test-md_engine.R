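test_that("zero steps leave the state untouched", {
  st <- make_state(matrix(c(5, 5, 5), 1), "Na+", 20,
                   matrix(c(1, 0, 0), 1))
  out <- md_sweep(st, ideal_forcefield(), params = md_params(), nsteps = 0)
  expect_identical(out, st)
})

test_that("force-free frictionless motion is ballistic", {
  st <- make_state(matrix(c(5, 5, 5), 1), "Na+", 20,
                   matrix(c(0.3, -0.1, 0.2), 1))
  out <- md_sweep(st, ideal_forcefield(), params = md_params(friction = 0),
                  nsteps = 250, seed = 1)
  expect_equal(out$positions[1, ], c(5, 5, 5) + 250 * 0.01 * c(0.3, -0.1, 0.2),
               tolerance = 1e-10)
})

test_that("velocity Verlet conserves energy without the thermostat", {
  topo <- build_linear(2)
  st <- make_state(rbind(c(5, 5, 5), c(5, 5, 6.05)), c(1L, 1L), 20,
                   maxwell_boltzmann_velocities(2, 1, seed = 4))
  ff <- make_forcefield(electrostatics = "none")
  e0 <- total_energy(st, ff, topo) + 0.5 * sum(st$velocities^2)
  out <- md_sweep(st, ff, topo, md_params(friction = 0), nsteps = 10000, seed = 1)
  e1 <- attr(out, "potential_energy") + attr(out, "kinetic_energy")
  expect_lt(abs(e1 - e0), 1e-3)
})

test_that("the Langevin thermostat equilibrates kinetic energy to 3/2 N kT", {
  topo <- build_linear(2)
  st <- make_state(rbind(c(5, 5, 5), c(5, 5, 6.05)), c(1L, 1L), 20,
                   maxwell_boltzmann_velocities(2, 1, seed = 4))
  ff <- make_forcefield(electrostatics = "none")
  out <- md_sweep(st, ff, topo, md_params(friction = 1), nsteps = 60000,
                  seed = 2, sample_every = 50)
  ke <- attr(out, "ke_samples")
  se <- se_blocked(ke, 10)
  expect_lt(abs(mean(ke) - 3), 3 * se + 0.02)  # 3/2 * N * kT with N = 2
})

test_that("MD preserves species, counts, and wrapping", {
  sys <- small_mixed_state()
  st <- sys$state
  st$velocities <- maxwell_boltzmann_velocities(nrow(st$positions), 1, seed = 5)
  ff <- forcefield_for_box(make_forcefield(), st$box)
  out <- md_sweep(st, ff, sys$topology, md_params(), nsteps = 300, seed = 6)
  expect_identical(out$species, st$species)
  expect_true(all(out$positions >= 0 & out$positions < st$box))
  expect_equal(net_charge(out), 0)
})

test_that("FENE overstretch aborts with a diagnostic", {
  topo <- build_linear(2)
  st <- make_state(rbind(c(5, 5, 5), c(5, 5, 6)), c(1L, 1L), 20,
                   matrix(c(0, 0, -40, 0, 0, 40), 2, 3, byrow = TRUE))
  ff <- make_forcefield(electrostatics = "none")
  expect_error(md_sweep(st, ff, topo, md_params(friction = 0), nsteps = 100,
                        seed = 1),
               "overstretched")
})

test_that("dimer bond-length distribution matches the quadrature oracle", {
  topo <- build_linear(2)
  st <- make_state(rbind(c(5, 5, 5), c(5, 5, 6)), c(1L, 1L), 20,
                   maxwell_boltzmann_velocities(2, 1, seed = 1))
  ff <- make_forcefield(electrostatics = "none")
  out <- md_sweep(st, ff, topo, md_params(friction = 1), nsteps = 150000,
                  seed = 3, sample_every = 25)
  r <- attr(out, "bond_samples")
  q <- dimer_bond_quadrature()
  se <- se_blocked(r, 10)
  expect_lt(abs(mean(r) - q$mean), 3 * se + 0.005)
  # spread and quartiles agree with the Boltzmann density
  expect_equal(sd(r), q$sd, tolerance = 0.08)
  for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(quantile(r, p)), q$r[which.min(abs(q$cdf - p))],
                 tolerance = 0.03)
  }
})
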