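test_that("linear chains are path graphs with N-1 bonds", {
  expect_error(build_linear(1), "n >= 2")
  t2 <- build_linear(2)
  expect_equal(t2$bonds, matrix(c(1L, 2L), 1))
  t121 <- build_linear(121)
  expect_equal(nrow(t121$bonds), 120)
  expect_equal(max(bond_degrees(t121)), 2)
  for (n in c(2, 7, 40)) {
    tn <- build_linear(n)
    expect_equal(nrow(tn$bonds), n - 1)
    expect_equal(sort(bond_degrees(tn)), c(1L, 1L, rep(2L, n - 2)))
  }
})

test_that("stars have a central bead of degree n_arms and N = arms*len + 1", {
  expect_error(build_star(1, 5), "n_arms >= 2")
  expect_error(build_star(5, 0), "arm_length")
  s <- build_star(10, 12)
  expect_equal(s$n_monomers, 121L)
  expect_equal(nrow(s$bonds), 120)
  deg <- bond_degrees(s)
  expect_equal(deg[1], 10)
  expect_equal(sum(deg == 1), 10)   # arm tips
  # 5-arm star of equal molecular weight
  s5 <- build_star(5, 24)
  expect_equal(s5$n_monomers, 121L)
  # degenerate star = linear trimer
  s2 <- build_star(2, 1)
  expect_equal(s2$n_monomers, 3L)
  expect_equal(sort(bond_degrees(s2)), c(1L, 1L, 2L))
})

test_that("initial configurations respect bonds, overlaps, and the seed", {
  for (topo in list(build_linear(30), build_star(10, 12))) {
    st <- initial_configuration(topo, 40, seed = 7)
    d <- st$positions[topo$bonds[, 1], ] - st$positions[topo$bonds[, 2], ]
    d <- d - 40 * round(d / 40)
    blen <- sqrt(rowSums(d^2))
    expect_true(all(blen < 2))              # every FENE bond below R0
    expect_true(all(is.finite(fene_energy(blen))))
    dm <- as.matrix(dist(st$positions))
    expect_true(min(dm[dm > 0]) >= 0.8)     # no hard overlaps
  }
  a <- initial_configuration(build_linear(15), 30, seed = 3)
  b <- initial_configuration(build_linear(15), 30, seed = 3)
  expect_identical(a$positions, b$positions)
  c2 <- initial_configuration(build_linear(15), 30, seed = 4)
  expect_false(identical(a$positions, c2$positions))
})

test_that("place_ions rejects monomers and respects min separation", {
  st <- initial_configuration(build_linear(5), 20, seed = 1)
  expect_error(place_ions(st, c("MH" = 2), seed = 1), "mobile ions")
  st2 <- place_ions(st, c("Na+" = 10, "Cl-" = 10), seed = 2, min_sep = 0.9)
  expect_equal(nrow(st2$positions), 25)
  dm <- as.matrix(dist(st2$positions))
  expect_true(min(dm[dm > 0]) >= 0.8)  # interior distances (no wrap pairs closer)
  expect_equal(net_charge(st2), 0)
})
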