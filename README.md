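# wpesim

Hybrid Monte Carlo / molecular dynamics simulation of weak polyelectrolyte
titration in explicit salt.

## What this is for

Weak polyacids (poly(acrylic acid), P2VP, …) do not carry a fixed charge:
each monomer protonates or deprotonates in response to the local pH, the
surrounding salt, and the conformation of the chain itself.  For a poorly
solvated chain this couples two transitions — charging and the
coil–globule transition (CGT) — and the outcome depends on salt
concentration, counterion valence and polymer topology in ways that
implicit-screening models miss.  `wpesim` is a research simulator for
exactly this problem: one coarse-grained polyacid (linear chain or n-arm
star) in a periodic box of explicit mono- or divalent salt, held at fixed
pH and bulk salinity by chemostats.

## The model and sampler

Bead–spring polymer in reduced units (σ, k<sub>B</sub>T = 1, m = 1;
σ maps to 0.25 nm):

* U = U<sub>LJ</sub> + U<sub>FENE</sub> + U<sub>coul</sub> — truncated-shifted
  Lennard-Jones (adhesive 2.5σ cutoff between monomers, WCA for all ion
  pairs), FENE bonds (K = 7 ε/σ², R₀ = 2σ), and Coulomb at Bjerrum length
  λ<sub>B</sub> = 2.8σ by Ewald summation.
* Titration by reaction-ensemble Monte Carlo for
  M⁻ ⇌ MH + OH⁻: deprotonation removes a hydroxide, acceptance
  min{1, (Λ³/V)·N<sub>MH</sub>N<sub>OH</sub>/(N<sub>M⁻</sub>+1)·e^(−βΔU+βμ<sub>rxn</sub>)},
  with μ<sub>rxn</sub> = ln10·(pH − pK<sub>a</sub>) − μ<sub>OH</sub>.
  Results are reported against the charging chemical potential
  μ = ln10·(pH − pK<sub>a</sub>).
* Charge-annealing swaps relocate charge along the backbone; multi-species
  grand-canonical moves exchange neutral NaCl / MgSO₄ and KOH units with
  their reservoirs; short Langevin MD sweeps (BAOAB, δt = 0.01τ) relax the
  configuration between MC batches (30 MC moves per sweep, equally split).
* Reservoir chemical potentials are calibrated to bulk concentrations by
  pure-salt GCMC, and salt conditions are reported as the Debye length
  λ<sub>D</sub> = (8πλ<sub>B</sub>I)^(−1/2).

An implicit Debye–Hückel mode (screened monomer pair potential, simplified
titration, no explicit ions) is included as a comparison tool.

## Worked example

A 61-monomer chain at μ = 5 in 0.1 M NaCl with a 0.01 M KOH buffer:

```r
library(wpesim)
topo  <- build_linear(61)
state <- initial_configuration(topo, box = 32, seed = 1)
state <- place_ions(state, c("K+" = 3, "OH-" = 3, "Na+" = 31, "Cl-" = 31), seed = 2)
ff    <- forcefield_for_box(make_forcefield(ewald_accuracy = 1e-3), 32)
chem  <- make_chemostats(mu = 5, koh_conc = 0.01, salt = "nacl", salt_conc = 0.1)
chem
#> <wpe_chemostats> mu = 5 (pH - pKa = 2.171 ) | mu_OH = -9.271 | mu_rxn = 14.271
#>   salt: nacl at 0.1 M, per-species mu = -6.969

run <- run_hybrid(state, ff, chem, topo,
                  make_schedule(30, md_steps_per_sweep = 50),
                  md_params(), n_sweeps = 800, seed = 3)
run
#> <wpe_run> 800 sweeps; final f = 0.541 rg = 7.265
#>   acceptance: rxmc 0.267, gcmc_salt 0.534, gcmc_koh 0.358, anneal 0.325

summarize_run(run)[c("f", "f_se", "rg", "rg_se")]
#> $f: 0.487   $f_se: 0.012   $rg: 7.28   $rg_se: 0.17
```

About half the monomers are charged and the chain is partially swollen
(R<sub>g</sub> ≈ 7σ versus ≈ 2.5σ for the collapsed globule).  The
chemostat print shows the ideal-gas mapping of the reservoirs; for
production-style studies `run_titration_study()` first calibrates the salt
chemical potential against a pure-salt box (at Γ = 2.8 ion pairing makes
the realized concentration exceed the ideal mapping), runs the hybrid
loop, and reports block-averaged f and R<sub>g</sub> with the realized
λ<sub>D</sub>.  `debye_length(0.1, "nacl")` ≈ 3.89σ.

Swapping the reservoir to the divalent salt at the same target
concentration roughly doubles the charge fraction while *collapsing* the
chain — divalent counterions condense on the polymer, neutralizing what
they charge; see the package vignette for the packaged study designs and
their scaled-down run lengths.

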