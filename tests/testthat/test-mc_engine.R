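test_that("chemostat set ties mu_rxn to mu - mu_OH and builds neutral units", {
  ch <- make_chemostats(mu = 5, koh_conc = 0.002, salt = "nacl",
                        salt_conc = 0.1)
  expect_equal(ch$mu_rxn, ch$mu - ch$mu_OH)
  expect_equal(ch$mu_OH, log(concentration_to_density(0.002)))
  expect_equal(ch$salt_species, c(3L, 4L))
  v <- species_table()$valence
  expect_equal(sum(v[ch$salt_species]), 0L)
  ch2 <- make_chemostats(mu = 4, salt = "mgso4", salt_conc = 0.05)
  expect_equal(sum(v[ch2$salt_species]), 0L)
  # mu <-> pH - pKa convention
  expect_equal(mu_from_ph(ph_minus_pka(3)), 3)
})

test_that("reaction-ensemble acceptance matches the direct plug-in values", {
  # ideal deprotonation in the production box: (121*5/64.6^3) * e^5
  expect_equal(rxmc_acceptance("deprotonate", n_MH = 121, n_M = 0, n_OH = 5,
                               V = 64.6^3, delta_U = 0, mu_rxn = 5),
               121 * 5 / 64.6^3 * exp(5), tolerance = 1e-12)
  expect_equal(rxmc_acceptance("deprotonate", 121, 0, 5, 64.6^3, 0, 5),
               0.333, tolerance = 1e-3)
  # combinatorial zeroes
  expect_equal(rxmc_acceptance("deprotonate", 121, 0, 0, 64.6^3, 0, 5), 0)
  expect_equal(rxmc_acceptance("protonate", 121, 0, 5, 64.6^3, 0, 5), 0)
  # mu_rxn -> +Inf kills protonation
  expect_equal(rxmc_acceptance("protonate", 1, 100, 5, 1e3, 0, 1e4), 0)
})

test_that("forward and reverse raw acceptance factors are reciprocal", {
  # reaction pair: deprotonation from (n_MH, n_M, n_OH) against protonation
  # evaluated in the post-move composition, at opposite energy change
  raw_dep <- function(n_MH, n_M, n_OH, V, du, mu)
    n_MH * n_OH / (V * (n_M + 1)) * exp(mu - du)
  raw_pro <- function(n_MH, n_M, n_OH, V, du, mu)
    V * n_M / ((n_MH + 1) * (n_OH + 1)) * exp(-mu - du)
  set.seed(1)
  for (k in 1:20) {
    n_MH <- sample(1:120, 1); n_M <- sample(0:50, 1); n_OH <- sample(1:20, 1)
    du <- rnorm(1); mu <- rnorm(1, 0, 3); V <- runif(1, 100, 1e5)
    f <- raw_dep(n_MH, n_M, n_OH, V, du, mu)
    r <- raw_pro(n_MH - 1, n_M + 1, n_OH - 1, V, -du, mu)
    expect_equal(f * r, 1, tolerance = 1e-10)
    expect_equal(rxmc_acceptance("deprotonate", n_MH, n_M, n_OH, V, du, mu),
                 min(1, f), tolerance = 1e-12)
    expect_equal(rxmc_acceptance("protonate", n_MH - 1, n_M + 1, n_OH - 1, V,
                                 -du, mu),
                 min(1, r), tolerance = 1e-12)
  }
  # grand-canonical pair: insertion vs deletion in the post-move composition
  for (k in 1:20) {
    n <- sample(0:80, 2); mu <- rnorm(2); du <- rnorm(1); V <- runif(1, 50, 5e4)
    ins <- prod(V / (n + 1)) * exp(sum(mu)) * exp(-du)
    del <- prod((n + 1) / V) * exp(-sum(mu)) * exp(du)
    expect_equal(ins * del, 1, tolerance = 1e-10)
    expect_equal(gcmc_acceptance("insertion", n, mu, V, du), min(1, ins),
                 tolerance = 1e-12)
    expect_equal(gcmc_acceptance("deletion", n + 1, mu, V, -du), min(1, del),
                 tolerance = 1e-12)
  }
  expect_equal(gcmc_acceptance("deletion", c(0, 3), c(0, 0), 100, 0), 0)
})

test_that("reference moves preserve electroneutrality and preconditions", {
  set.seed(11)
  fx <- make_ideal_titration_box(10, mu = 0, koh_conc = 0.05, box = 15, seed = 1)
  st <- fx$state
  # no hydroxide: deprotonation impossible
  no_oh <- make_state(st$positions[st$species != 6L, , drop = FALSE],
                      st$species[st$species != 6L], st$box)
  r <- rxmc_deprotonate(no_oh, fx$chem, fx$ff)
  expect_false(r$accepted); expect_equal(r$prob, 0)
  # no charged monomer: protonation impossible
  r2 <- rxmc_protonate(st, fx$chem, fx$ff)
  expect_false(r2$accepted)
  # no (MH, M-) pair: annealing impossible
  r3 <- charge_anneal_swap(st, fx$ff)
  expect_false(r3$accepted)
  # deletion from an empty box is rejected
  empty <- make_state(matrix(numeric(0), 0, 3), integer(0), 15)
  chem <- make_chemostats(mu = 0, koh_conc = 0, salt = "nacl", salt_conc = 0.1)
  r4 <- gcmc_delete_unit(empty, chem, fx$ff, unit = "salt")
  expect_false(r4$accepted)
  # a chain of accepted moves keeps the box neutral
  state <- st
  for (k in 1:200) {
    mv <- switch(1 + k %% 4,
                 rxmc_deprotonate(state, fx$chem, fx$ff),
                 rxmc_protonate(state, fx$chem, fx$ff),
                 gcmc_insert_unit(state, fx$chem, fx$ff, unit = "koh"),
                 gcmc_delete_unit(state, fx$chem, fx$ff, unit = "koh"))
    state <- mv$state
    expect_equal(net_charge(state), 0)
  }
  # the identity changes actually happened
  expect_gt(sum(state$species == 2L), 0)
})

test_that("charge annealing samples the exact 3-state Boltzmann weights", {
  # three fixed monomers at different distances from one fixed counterion;
  # the single charge relocates by swap moves only, so the long-run location
  # distribution is the 3-state partition function of the screened energies
  pos <- rbind(c(4, 5, 5), c(6.2, 5, 5), c(8, 5, 5), c(5, 5, 5))
  lamD <- 3
  ff <- make_forcefield(electrostatics = "dh", lambda_D = lamD, dh_rcut = 6,
                        lj_on = FALSE)
  st <- make_state(pos, c(2L, 1L, 1L, 3L), 20)
  # oracle: pair energies by hand (only the charged monomer-ion pair counts)
  r_ion <- c(1, 1.2, 3)
  e <- -2.8 * (exp(-r_ion / lamD) / r_ion - exp(-6 / lamD) / 6)
  w <- exp(-e) / sum(exp(-e))
  set.seed(42)
  counts <- c(0, 0, 0)
  state <- st
  for (k in 1:4000) {
    state <- charge_anneal_swap(state, ff)$state
    counts[which(state$species[1:3] == 2L)] <- counts[which(state$species[1:3] == 2L)] + 1
  }
  expect_lt(max(abs(counts / sum(counts) - w)), 0.05)
})

test_that("the compiled scheduler books attempts exactly and is deterministic", {
  fx <- make_ideal_titration_box(20, mu = 0, koh_conc = 1, box = 15, seed = 3)
  sched <- make_schedule(30, c(rxmc = 10, gcmc = 10, anneal = 10),
                         md_steps_per_sweep = 0, audit_every = 0)
  r1 <- run_hybrid(fx$state, fx$ff, fx$chem, NULL, sched, md_params(),
                   n_sweeps = 25, seed = 9)
  expect_equal(unname(r1$attempts[c("rxmc", "anneal")]), c(250, 250))
  expect_equal(unname(r1$attempts[["gcmc_salt"]] + r1$attempts[["gcmc_koh"]]), 250)
  r2 <- run_hybrid(fx$state, fx$ff, fx$chem, NULL, sched, md_params(),
                   n_sweeps = 25, seed = 9)
  expect_identical(r1$series, r2$series)
  r3 <- run_hybrid(fx$state, fx$ff, fx$chem, NULL, sched, md_params(),
                   n_sweeps = 25, seed = 10)
  expect_false(identical(r1$series, r3$series))
})

test_that("schedule validation and the pure-MD degenerate schedule work", {
  expect_error(make_schedule(30, c(rxmc = 10, gcmc = 10, anneal = 5)),
               "must sum")
  expect_error(make_schedule(9, c(rxmc = 3, gcmc = 3)), "partition needs")
  sys <- small_mixed_state()
  sched <- make_schedule(0, c(rxmc = 0, gcmc = 0, anneal = 0),
                         md_steps_per_sweep = 20)
  ff <- forcefield_for_box(make_forcefield(), sys$state$box)
  chem <- make_chemostats(mu = 5, koh_conc = 0.002, salt = "nacl",
                          salt_conc = 0.01)
  r <- run_hybrid(sys$state, ff, chem, sys$topology, sched, md_params(),
                  n_sweeps = 5, seed = 2)
  expect_equal(sum(r$attempts), 0)
  expect_identical(r$state$species, sys$state$species)
})

test_that("incremental energies agree with full recomputation during runs", {
  sys <- small_mixed_state(seed = 4, box = 14)
  ff <- forcefield_for_box(make_forcefield(), 14)
  chem <- make_chemostats(mu = 5, koh_conc = 0.02, salt = "nacl",
                          salt_conc = 0.05)
  st <- place_ions(sys$state, c("K+" = 2, "OH-" = 2), seed = 5)
  sched <- make_schedule(30, md_steps_per_sweep = 10, audit_every = 1)
  r <- run_hybrid(st, ff, chem, sys$topology, sched, md_params(),
                  n_sweeps = 60, seed = 3)
  expect_gt(sum(r$accepts), 0)
  expect_lt(r$max_audit_drift, 1e-6)
  expect_equal(net_charge(r$state), 0)
})
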