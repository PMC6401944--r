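---
title: "Constant-pH simulation of weak polyelectrolytes in explicit salt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant-pH simulation of weak polyelectrolytes in explicit salt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpesim)
```

## The model

`wpesim` simulates the titration and coil–globule transition (CGT) of a
single weak polyacid — a linear chain or an n-arm star of $N$ titratable
beads — in a periodic box of explicit mono- or divalent salt.  The model
is a restricted-primitive-model electrolyte extended to polymers: all
particles are beads of diameter $\sigma$ with unit mass, at thermal energy
$k_BT = 1$.

The potential energy is
$$U = U_{LJ} + U_{FENE} + U_{coul}.$$

* **Lennard-Jones**, truncated and shifted, $\epsilon = 1\,k_BT$ for every
  pair.  Monomer–monomer interactions keep the attractive well (cutoff
  $2.5\sigma$), modelling the hydrophobic/hydrogen-bond adhesion of poorly
  solvated backbones such as PAA or P2VP; all ion pairs are purely
  repulsive (WCA, cutoff $2^{1/6}\sigma$).  Bonded monomers interact
  through the full LJ term as well (Kremer–Grest convention, no intra-bond
  exclusion).
* **FENE bonds**, $U(r) = -\tfrac12 K R_0^2 \ln[1-(r/R_0)^2]$ with
  $K = 7\,\epsilon/\sigma^2$, $R_0 = 2\sigma$.  The confining (negative-log)
  form is used; it is the standard convention of the bead–spring
  literature and the only bounded-from-below choice.
* **Coulomb**, $U_{ij} = k_BT\,\lambda_B q_i q_j / r_{ij}$ with Bjerrum
  length $\lambda_B = 2.8\sigma$ (aqueous media with $\sigma$ mapped to
  0.25 nm, i.e. coupling $\Gamma = 2.8$), evaluated by Ewald summation.

## Chemical equilibria

Titration follows the reaction $M^- \rightleftharpoons MH + OH^-$ sampled
by reaction-ensemble Monte Carlo (RxMC): a deprotonation turns a random
neutral bead into a charged one *and removes one hydroxide*, with
acceptance

$$P_{acc} = \min\!\left\{1,\;
  \frac{\Lambda^3}{V}\frac{N_{MH} N_{OH^-}}{N_{M^-}+1}
  e^{-\beta\Delta U + \beta\mu_{rxn}}\right\},$$

and protonation is the exact reverse (insertion of a hydroxide at a
uniform random position).  The reaction chemical potential is tied to
experimental conditions through
$\mu_{rxn} = \ln 10\,(pH - pK_a) - \mu_{OH^-}$, and all results are
reported against the charging chemical potential
$\mu = \ln 10\,(pH-pK_a)$.  The forward and reverse factors are exact
reciprocals (verified numerically in the test suite), so the pair is in
detailed balance; combined with hydroxide exchange the stationary
per-site charging odds in the ideal limit are $e^{\mu}$, i.e.
Henderson–Hasselbalch.

Two further move families complete the sampler:

* **Charge annealing** — Metropolis identity swaps of a random
  $(MH, M^-)$ pair, relocating charge along the backbone at fixed
  composition.
* **Grand-canonical exchange** of charge-neutral units — NaCl or MgSO4
  (the "divalent salt" differs *only* in valence) and the KOH buffer —
  with the standard multi-species insertion/deletion probabilities.
  Salt and base are independent unit types; each GCMC slot chooses unit
  and direction by fair coin.

The mass-ratio prefactor of the reaction ensemble is an explicit argument
that evaluates to 1 (all masses are 1).  The thermal de Broglie wavelength
is set to $\Lambda = 1\sigma$ for every species; because the same
$\Lambda$ enters the reaction moves, the GCMC moves and the reservoir
calibration, equilibrium observables are independent of the choice.

### Electroneutrality and the reservoir limit

Every move conserves the box's net charge exactly, which constrains the
reachable state space: the number of potassium counterions always equals
$N_{M^-} + N_{OH^-}$.  In a finite box with few KOH units this constraint
*suppresses* charging below the Henderson–Hasselbalch curve — the exact
stationary distribution is the product-form grand-canonical measure
conditioned on neutrality, which the engine reproduces to within
statistical error (the test suite enumerates it exactly for a 3-site
toy).  HH behaviour emerges only in the reservoir limit
$z_{KOH} V \gg N f$; the ideal-titration fixture therefore uses a
concentrated ideal base when HH itself is the oracle.  In production-like
boxes the finite hydroxide content is part of the physics: the buffer
concentration (0.002 M at production scale) is deliberately high for a
pH ≈ 11.3 solution to keep hydroxide available for reaction moves.

## Hybrid MC/MD schedule

Monte Carlo alone relaxes composition but not conformation.  Between MC
batches the configuration is relaxed by Langevin dynamics (BAOAB
velocity-Verlet splitting, $\delta t = 0.01\tau$, friction $1/\tau$ —
the damping affects kinetics only, and with zero friction the integrator
reduces to plain velocity Verlet, which the energy-conservation test
exercises).  The production schedule attempts 30 MC moves per sweep,
split equally among RxMC, GCMC and annealing, followed by 1000 MD steps;
particles inserted by GCMC get fresh Maxwell–Boltzmann velocities.

Move proposals use incremental energy differences: single-particle
short-range sums plus an incremental update of the cached Ewald structure
factor.  Once per sweep the running total is audited against a full
recomputation and re-synced; the worst discrepancy is reported as
`max_audit_drift` (typically $10^{-13}\,k_BT$; the suite requires
$<10^{-6}$).

## Electrostatics

The Ewald splitting parameter follows the standard real-space error
estimate $\alpha = (1.35 - 0.15\ln\epsilon)/r_c$ and the reciprocal
cutoff is chosen so the Gaussian tail matches the same accuracy
$\epsilon$; defaults are $r_c = 18\sigma$, $\epsilon = 10^{-5}$, and the
real-space cutoff is reduced to $0.44\,L$ in boxes smaller than $2 r_c$.
Correctness anchors: the rock-salt Madelung constant to $10^{-6}$
relative, an isolated ion pair at $r = \lambda_B$, invariance under
translation and index permutation, and force–gradient consistency to
$10^{-6}$ relative against finite differences.

An **implicit-salt Debye–Hückel mode** (`electrostatics = "dh"`) replaces
ions with a screened monomer–monomer interaction
$\lambda_B q_i q_j e^{-r/\lambda_D}/r$ (shifted to zero at its cutoff)
and simplifies titration to a bare identity change weighted by $e^{\mu}$
(no explicit base).  It exists for comparison with the explicit
representation and for cheap topology scans; it is flagged experimental
and screens *all* charged pairs it is given.

## Reservoir calibration

With interacting ions the box concentration at fixed chemical potential
is not the ideal value: at $\Gamma = 2.8$ the +/− contact energy is
$-2.8\,k_BT$ and ion-pair association *raises* the occupancy above ideal
(excluded volume alone would lower it slightly — both directions are
asserted in the tests).  The divalent pair (contact $-11.2\,k_BT$)
associates far more strongly.  `calibrate_salt()` therefore measures the
mean occupancy of a polymer-free box at the production force field, and
`calibrate_mu_for_concentration()` bisects to the chemical potential that
realizes a target bulk concentration — the same procedure used at
production scale.  Salt conditions are reported as the Debye length of
the reservoir, $\lambda_D = (8\pi\lambda_B I)^{-1/2}$ with
$I = \tfrac12\sum_i \rho_i z_i^2$ (so $I = c$ for 1:1 and $4c$ for 2:2
salts); the KOH buffer is not folded into the reported $\lambda_D$.

## Scaled-down study design

Full production runs ($N = 121$, $(64.6\sigma)^3$, $2\times10^7$ MD
steps) are not desk-scale.  The packaged studies
(`run_titration_study()`, `dh_mu_scan()`) use conditions chosen once and
documented here:

* linear 61-mer (star: 10 arms of 6) in a $(32\sigma)^3$ box;
* KOH at 0.01 M, which keeps $z_{KOH}V \approx 3$ hydroxides in the box —
  the same reservoir availability per monomer as the production cell;
* Ewald accuracy $10^{-3}$ for the study runs (defaults remain
  $10^{-5}$);
* 3600 sweeps of 30 MC moves + 50 MD steps, i.e. $1.08\times10^5$ MC
  moves and $1.8\times10^5$ MD steps per study;
* salt chemical potentials calibrated to the target concentration before
  each study.

At this scale the explicit-ion results are trend-level: the charge
fraction stays above the ~10% floor across salt conditions, the high-NaCl
state ($\lambda_D \approx 3\sigma$) sits on the $f \sim 0.35$ scale with
a partially swollen chain, and swapping to the divalent reservoir at the
same target concentration raises $f$ to ≈ 0.75 while the chain stays at
globule size — counterion condensation collapses what it charges.
Exact figure-level values are a property of the full production size
only.

The topology comparison (monotone charging in $\mu$; sharp,
first-order-like CGT for the chain versus a gradual transition for the
10-arm star) is run in the implicit screened mode at $\lambda_D = 6\sigma$
with an annealed (warm-started) ascending $\mu$ scan.  A two-topology,
five-$\mu$ explicit-ion scan would multiply the study cost tenfold while
the qualitative topology effect — entropy-limited swelling of the star —
is shared by both representations; the sharpness statistic
(`charging_sharpness()`: largest single-step rise of $f$ as a fraction of
the scan range) is what the packaged checks compare.

## Observables

* charge fraction $f = N_{M^-}/N$;
* radius of gyration over monomers only, computed from coordinates
  unwrapped along the bond tree (wrap-invariant; a bond longer than $R_0$
  after unwrapping raises a broken-molecule error);
* ion counts in concentric shells around the polymer centre of mass
  (default bins $0.5\sigma$ to $20\sigma$), with the cumulative count
  inside $7.5\sigma$ as the counterion-condensation summary;
* block averages: discard the first half of each series (configurable),
  ten blocks, standard error from block means.

## Degenerate inputs and numerical guards

Zero-sweep runs emit valid empty outputs; empty boxes are legal GCMC
starting states; deletion from an empty species and reaction moves
without reactants are counted, rejected attempts.  A FENE bond reaching
$R_0$ anywhere (MC proposal or MD force loop) is an infinite-energy
signal: proposals are rejected, MD aborts with a diagnostic.  Insertion
proposals overlapping an existing particle below $10^{-6}\sigma$ are
rejected outright.  All randomness flows from explicit integer seeds
through a dedicated xoshiro256++ stream per run, so identical
configuration and seed reproduce results bit-for-bit.

## Known limitations

* No chemical specificity beyond valence; no solvent structure,
  hydrogen bonding, dipoles or dielectric gradients.
* Plain Ewald (no mesh); adequate at these particle counts, not for
  much larger boxes.
* The implicit DH mode is a comparison tool; whether screening should
  apply to all pairs or only monomers in mixed setups is left to the
  caller (here it only ever sees monomer systems).
* Single-molecule systems only: no brushes, gels or multi-chain
  complexation.
* The synthetic studies emulate equilibrium titration of one chain at
  moderate coupling; they say nothing about dynamics, hysteresis
  kinetics, or multi-chain effects in real formulations.
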