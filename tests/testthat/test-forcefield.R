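test_that("truncated-shifted LJ matches closed forms and is continuous", {
  expect_equal(lj_pair_energy(3, r_cut = 2.5), 0)
  expect_equal(lj_pair_energy(2^(1 / 6), r_cut = 2^(1 / 6)), 0)  # WCA minimum
  # adhesive minimum with the 2.5 sigma cutoff: -1 - U_LJ(2.5)
  shift <- 4 * (2.5^-12 - 2.5^-6)
  expect_equal(lj_pair_energy(2^(1 / 6), r_cut = 2.5), -1 - shift,
               tolerance = 1e-12)
  expect_equal(lj_pair_energy(2^(1 / 6), r_cut = 2.5), -0.98368,
               tolerance = 1e-4)
  eps <- 1e-9
  jump <- lj_pair_energy(2.5 - eps, r_cut = 2.5) - lj_pair_energy(2.5 + eps, r_cut = 2.5)
  expect_lt(abs(jump), 1e-7)
  expect_error(lj_pair_energy(0, r_cut = 2.5), "diverges")
})

test_that("FENE energy is confining: zero at r=0, divergent at R0", {
  expect_equal(fene_energy(0), 0)
  expect_equal(fene_energy(1), 14 * log(4 / 3), tolerance = 1e-12)
  expect_equal(fene_energy(2), Inf)
  expect_equal(fene_energy(2.5), Inf)
  r <- seq(0, 1.99, by = 0.01)
  expect_true(all(diff(fene_energy(r)) > 0))
  expect_true(all(fene_energy(r) >= 0))
})

test_that("Debye-Hueckel pair energy has the right limits", {
  expect_equal(dh_pair_energy(1.4, 1, -1, lambda_D = Inf),
               -2.8 / 1.4)  # bare Coulomb limit
  expect_equal(dh_pair_energy(2, 1, 0, lambda_D = 3), 0)
  expect_equal(dh_pair_energy(2.8, -1, 1, lambda_D = 2.8, lambda_B = 2.8),
               -exp(-1), tolerance = 1e-12)
  expect_equal(dh_pair_energy(5, 1, -1, lambda_D = 2, r_cut = 4), 0)
})

test_that("Ewald Coulomb reproduces an isolated pair and the Madelung sum", {
  st <- make_state(rbind(c(10, 10, 10), c(10, 10, 12.8)), c("Na+", "Cl-"), 60)
  ff <- make_forcefield(ewald_rcut = 25)
  expect_equal(coulomb_energy(st, ff), -1, tolerance = 1e-3)
  lat <- make_nacl_lattice(2, 1)
  ffl <- forcefield_for_box(make_forcefield(), lat$box)
  e <- coulomb_energy(lat, ffl)
  madelung <- -2 * e / (nrow(lat$positions) * 2.8)
  expect_equal(madelung, 1.747565, tolerance = 1e-4)
})

test_that("Ewald energy is invariant under translation and permutation", {
  sys <- small_mixed_state()
  ff <- forcefield_for_box(make_forcefield(), sys$state$box)
  e0 <- coulomb_energy(sys$state, ff)
  shifted <- sys$state
  shifted$positions <- sweep(shifted$positions, 2, c(1.3, -2.1, 0.7))
  shifted <- make_state(shifted$positions, shifted$species, shifted$box)
  expect_equal(coulomb_energy(shifted, ff), e0, tolerance = 1e-9)
  # permute the ions (monomers must stay in front)
  set.seed(1)
  ion_idx <- 5:8
  perm <- sys$state
  shuffle <- c(1:4, sample(ion_idx))
  perm <- make_state(perm$positions[shuffle, ], perm$species[shuffle], perm$box)
  expect_equal(coulomb_energy(perm, ff), e0, tolerance = 1e-9)
})

test_that("Ewald agrees with a direct minimum-image sum for tight dipoles", {
  # four +/- contact pairs far apart: periodic corrections are tiny, so the
  # plain minimum-image sum is an adequate oracle at the 1% level
  set.seed(9)
  centers <- matrix(c(5, 5, 5, 25, 8, 12, 12, 28, 24, 30, 30, 9), 4, 3, byrow = TRUE)
  pos <- NULL
  for (k in 1:4) pos <- rbind(pos, centers[k, ], centers[k, ] + c(1, 0, 0))
  st <- make_state(pos, rep(c("Na+", "Cl-"), 4), 40)
  ff <- forcefield_for_box(make_forcefield(), 40)
  expect_equal(coulomb_energy(st, ff), direct_coulomb(st),
               tolerance = 0.01)
})

test_that("forces are exact negative gradients of the total energy", {
  sys <- small_mixed_state()
  for (ff in list(forcefield_for_box(make_forcefield(ewald_accuracy = 1e-6),
                                     sys$state$box),
                  make_forcefield(electrostatics = "dh", lambda_D = 3,
                                  dh_rcut = 5),
                  make_forcefield(electrostatics = "none"))) {
    F <- forces(sys$state, ff, sys$topology)
    h <- 1e-6
    num <- F * 0
    for (i in seq_len(nrow(F))) {
      for (d in 1:3) {
        sp <- sys$state; sp$positions[i, d] <- sp$positions[i, d] + h
        sm <- sys$state; sm$positions[i, d] <- sm$positions[i, d] - h
        num[i, d] <- -(total_energy(sp, ff, sys$topology) -
                         total_energy(sm, ff, sys$topology)) / (2 * h)
      }
    }
    expect_lt(max(abs(F - num)) / max(abs(F)), 1e-6)
  }
})

test_that("total energy decomposes into LJ + FENE + Coulomb", {
  # neutral FENE dimer at r = 1: LJ(1; 2.5 cut) + 14 log(4/3)
  topo <- build_linear(2)
  st <- make_state(rbind(c(5, 5, 5), c(5, 5, 6)), c(1L, 1L), 20)
  ff <- make_forcefield(electrostatics = "none")
  e <- total_energy(st, ff, topo, components = TRUE)
  expect_equal(e$fene, 14 * log(4 / 3), tolerance = 1e-10)
  expect_equal(e$lj, lj_pair_energy(1, r_cut = 2.5), tolerance = 1e-10)
  expect_equal(e$coulomb, 0)
  expect_equal(e$total, e$lj + e$fene)
  # two neutral beads beyond the 2.5 cutoff interact not at all
  st3 <- make_state(rbind(c(5, 5, 5), c(5, 5, 8)), c(1L, 1L), 20)
  expect_equal(total_energy(st3, ff), 0)
})

test_that("Ewald path demands electroneutrality and a fitting cutoff", {
  st <- make_state(matrix(c(5, 5, 5), 1), "Na+", 20)
  ff <- forcefield_for_box(make_forcefield(), 20)
  expect_error(total_energy(st, ff), "electroneutral")
  st2 <- make_state(rbind(c(1, 1, 1), c(3, 3, 3)), c("Na+", "Cl-"), 20)
  expect_error(total_energy(st2, make_forcefield(ewald_rcut = 18)), "box/2")
})

test_that("ewald parameter choice hits the requested accuracy scale", {
  p <- ewald_params(64.6, 2.8, 1e-5, 18)
  expect_gt(p$alpha, 0)
  expect_gt(p$n_kvec, 100)
  # tighter accuracy means more reciprocal vectors
  p2 <- ewald_params(64.6, 2.8, 1e-7, 18)
  expect_gt(p2$n_kvec, p$n_kvec)
})
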