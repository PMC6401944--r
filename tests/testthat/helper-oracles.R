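# Independent oracles used across the suite.  These deliberately avoid the
# package's compiled paths: plain-R arithmetic only.

# direct minimum-image Coulomb sum, U = lambda_B sum_{i<j} q_i q_j / r_ij
direct_coulomb <- function(state, lambda_B = 2.8) {
  q <- c(0, -1, 1, -1, 1, -1, 2, -2)[state$species]
  pos <- state$positions
  box <- state$box
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (q[i] == 0 || q[j] == 0) next
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      e <- e + lambda_B * q[i] * q[j] / sqrt(sum(d^2))
    }
  }
  e
}

# equilibrium bond-length density of an isolated FENE + LJ(2.5 cut) dimer,
# p(r) dr proportional to r^2 exp(-U(r)), by numerical quadrature
dimer_bond_quadrature <- function(K = 7, R0 = 2, r_cut = 2.5,
                                  n_grid = 4000) {
  r <- seq(1e-4, R0 - 1e-4, length.out = n_grid)
  ulj <- function(x) {
    s6 <- x^-6
    ifelse(x < r_cut, 4 * (s6^2 - s6) - (4 * (r_cut^-12 - r_cut^-6)), 0)
  }
  u <- -0.5 * K * R0^2 * log(1 - (r / R0)^2) + ulj(r)
  w <- r^2 * exp(-(u - min(u)))
  w <- w / sum(w)
  list(r = r, p = w,
       mean = sum(r * w),
       sd = sqrt(sum(r^2 * w) - sum(r * w)^2),
       cdf = cumsum(w))
}

# exact stationary distribution of the ideal titration box: N titratable
# sites, KOH chemostat with per-species activity-volume lambda = z V,
# electroneutrality constraint N_K = m + N_OH baked into the reachable
# state space.  Returns the joint P(m, n_OH) on a truncated grid.
ideal_titration_exact <- function(N, mu, lambda, oh_max = 60) {
  m <- 0:N
  no <- 0:oh_max
  logw <- outer(m, no, function(mm, nn)
    lchoose(N, mm) + mu * mm + (mm + nn) * log(lambda) + nn * log(lambda) -
      lfactorial(mm + nn) - lfactorial(nn))
  w <- exp(logw - max(logw))
  w / sum(w)
}

# closed-form radius of gyration of N collinear equally spaced beads
rod_rg <- function(n, spacing) spacing * sqrt((n^2 - 1) / 12)

# standard error from block means of an autocorrelated series
se_blocked <- function(x, blocks = 10) {
  n <- length(x)
  cuts <- floor(seq(0, n, length.out = blocks + 1))
  bm <- vapply(seq_len(blocks), function(b) mean(x[(cuts[b] + 1):cuts[b + 1]]), 0)
  sd(bm) / sqrt(blocks)
}

# small bonded-plus-ions test system, electroneutral
small_mixed_state <- function(seed = 2, box = 12) {
  topo <- build_linear(4)
  st <- initial_configuration(topo, box, seed = seed)
  st$species[c(2, 4)] <- 2L
  st <- place_ions(st, c("Na+" = 3, "Cl-" = 1), seed = seed + 1)
  list(state = st, topology = topo)
}
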