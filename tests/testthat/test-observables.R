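test_that("charge fraction counts deprotonated monomers", {
  st <- make_state(matrix(runif(121 * 3, 0, 20), ncol = 3),
                   c(rep(2L, 42), rep(1L, 79)), 20)
  # neutralize with counterions so the state is a legal construction elsewhere
  expect_equal(charge_fraction(st), 42 / 121)
  st_all <- make_state(matrix(runif(9, 0, 20), 3), rep(1L, 3), 20)
  expect_equal(charge_fraction(st_all), 0)
  st_m <- make_state(matrix(runif(9, 0, 20), 3), rep(2L, 3), 20)
  expect_equal(charge_fraction(st_m), 1)
  empty <- make_state(matrix(numeric(0), 0, 3), integer(0), 20)
  expect_error(charge_fraction(empty), "no monomers")
})

test_that("radius of gyration matches closed forms and survives wrapping", {
  # two beads at separation d: Rg = d/2
  topo2 <- build_linear(2)
  st2 <- make_state(rbind(c(5, 5, 5), c(5, 5, 6.4)), c(1L, 1L), 20)
  expect_equal(radius_of_gyration(st2, topo2), 0.7, tolerance = 1e-12)
  # collinear rod of N beads, spacing b: Rg = b sqrt((N^2-1)/12)
  n <- 9; b <- 0.9
  topo <- build_linear(n)
  pos <- cbind(3 + b * (0:(n - 1)), 5, 5)
  st <- make_state(pos, rep(1L, n), 30)
  expect_equal(radius_of_gyration(st, topo), rod_rg(n, b), tolerance = 1e-12)
  # the rod straddling the periodic boundary gives the same Rg
  pos_wrapped <- cbind(27 + b * (0:(n - 1)), 5, 5)  # crosses x = 30
  stw <- make_state(pos_wrapped, rep(1L, n), 30)
  expect_true(any(stw$positions[, 1] < 5))          # wrapping happened
  expect_equal(radius_of_gyration(stw, topo), rod_rg(n, b), tolerance = 1e-12)
  # coincident beads
  st0 <- make_state(matrix(5, 4, 3), rep(1L, 4), 30)
  expect_equal(radius_of_gyration(st0, build_linear(4)), 0)
})

test_that("broken molecules are detected during unwrapping", {
  topo <- build_linear(3)
  st <- make_state(rbind(c(1, 5, 5), c(2, 5, 5), c(9, 5, 5)), rep(1L, 3), 20)
  expect_error(unwrap_polymer(st, topo), "broken molecule")
})

test_that("shell histograms count ions around the polymer center of mass", {
  topo <- build_linear(2)
  st <- make_state(rbind(c(10, 10, 10), c(10, 10, 11)), c(1L, 1L), 24)
  # CM at (10,10,10.5); one sodium 1.5 sigma away
  st <- make_state(rbind(st$positions, c(10, 11.5, 10.5)), c(1L, 1L, 3L), 24)
  h <- shell_histogram(st, topo, bin_width = 1, r_max = 10)
  na <- h[h$species == "Na+", ]
  expect_equal(sum(na$count), 1)
  expect_equal(na$count[na$r_lo == 1], 1)
  expect_true(all(h$count[h$species == "Mg2+"] == 0))
  expect_error(shell_histogram(st, topo, r_max = 13), "half the box")
  # uniform ideal gas: counts proportional to shell volumes
  set.seed(2)
  ions <- matrix(runif(3 * 4000, 0, 24), ncol = 3)
  stg <- make_state(rbind(st$positions[1:2, ], ions),
                    c(1L, 1L, rep(4L, 4000)), 24)
  hg <- shell_histogram(stg, topo, bin_width = 2, r_max = 10)
  cl <- hg[hg$species == "Cl-", ]
  vols <- (4 / 3) * pi * (cl$r_hi^3 - cl$r_lo^3)
  expected <- 4000 * vols / 24^3
  expect_lt(max(abs(cl$count - expected) / sqrt(expected)), 4)  # Poisson bands
})

test_that("near-polymer summary accumulates counts within the cutoff", {
  topo <- build_linear(2)
  st <- make_state(rbind(c(10, 10, 10), c(10, 10, 11),
                         c(10, 13, 10.5), c(10, 10, 19)),
                   c(1L, 1L, 7L, 7L), 24)
  counts <- near_polymer_count(st, topo, r = 7.5, species = c("Na+", "Mg2+"))
  expect_equal(unname(counts["Mg2+"]), 1L)
  expect_equal(unname(counts["Na+"]), 0L)
})

test_that("block averages report sane means and errors", {
  expect_equal(block_average(rep(2.5, 100), 0.5, 10)$se, 0)
  x <- rep(c(0, 1), 30)
  ba <- block_average(x, equilibration = 0, blocks = 10)
  expect_equal(ba$mean, 0.5)
  expect_equal(ba$se, 0)
  set.seed(3)
  y <- rnorm(4000, mean = 7, sd = 2)
  ba2 <- block_average(y, equilibration = 0.25, blocks = 10)
  n_used <- 3000
  expect_equal(ba2$mean, 7, tolerance = 0.02)
  expect_lt(abs(ba2$se - 2 / sqrt(n_used)), 0.3 * 2 / sqrt(n_used))
  expect_error(block_average(1:5, 0.5, 10), "too short")
})
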