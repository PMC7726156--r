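# pebridge

Coarse-grained Metropolis Monte Carlo simulation of ion-mediated
interactions between two like-charged polyelectrolytes (PEs), with
explicit mobile ions, chain bending flexibility, and an optional
cylindrical confinement that models a chain inside a hexagonal PE array.

Charged chains such as nucleic acids repel each other through their bare
Coulomb interaction, yet condense into dense arrays in the presence of
multivalent counterions. `pebridge` is for researchers studying this
like-charge attraction: it computes how the effective chain-chain
interaction — the potential of mean force (PMF) — depends on chain
flexibility (parallel rigid, rotatable rigid, bendable with persistence
length P), on trivalent salt concentration, and on array confinement, and
it resolves the microscopic mechanism through bridging-ion statistics.

## Model

Two worm-like bead chains (N = 21 beads of diameter σ = 0.42 nm, charge
−e each, fixed bond length l0 = 1.1σ) sit in a periodic cubic box
(L = 62σ) with neutralising counterions, 20 mM 1:1 buffer salt, and 3:3
salt at 0–5 mM. The Hamiltonian (energies in units of k_B T):

* Coulomb: U_C = l_B z_i z_j / r, with Bjerrum length l_B = 0.714 nm
  (= 1.7σ; water at 300 K), under the minimum-image convention;
* excluded volume: the purely repulsive WCA potential
  U_ex = 4ε(σ¹²/r¹² − σ⁶/r⁶) + ε for r < 2^(1/6)σ, ε = 5/6 k_B T;
* bending: U_b = (P/l0) Σ_i (1 − cos θ_i) over the internal chain angles.

The central bead of each chain is fixed on the x axis at ±x/2. Sampling
uses single-ion translations, rigid rotations about the fixed central
bead (P = ∞ chains), and bond-preserving pivot moves (bendable chains),
with a hard cylindrical confinement of radius R = x per chain when the
array environment is switched on. The mean inter-chain force
F̄ = (F¹ + F²)/2 (repulsion positive) is accumulated in production and
integrated from the outer reference separation x_ref = 8σ to give the
PMF: ΔG(x) = ∫ₓ^{x_ref} ⟨F̄⟩ dx.

Observables: cumulative ion charge fraction f(r) around the chains (and
Δf(r) between contact and reference separations), effective separation
D = ⟨(1/N) Σ_i |r_i¹ − r_i²|⟩, and the number N_b of bridging trivalent
ions within r_c = 1.5σ of both chains.

## A worked example

A desk-scale run at high trivalent salt (5 mM), strongly bendable chains
(P = 2 nm), contact separation x = 2σ, in a reduced L = 44σ box:

```r
library(pebridge)

sys <- build_system("bendable", x = 2, P_nm = 2, c33_mM = 5, L = 44,
                    seed = 201)
moves <- move_spec(sweeps_equil = 1500, sweeps_prod = 3000, seed = 202)
eq <- run_until_equilibrium(sys, moves, window = 500, on_fail = "warn")
run <- run_production(eq)

bridging_ions(run$trajectory)
#> bridging ions (r_c = 1.5 sigma): Nb = 3.14 +/- 1.48, charge fraction 0.224
```

About three trivalent ions bridge the two flexible chains at any moment,
carrying ~22% of the chain charge; the same protocol with parallel rigid
rods gives N_b ≈ 7 (half the chain charge) — bending fluctuations disrupt
the bridging configurations that mediate the like-charge attraction.
A whole condition (force curve over the separation grid, integrated PMF,
observables per separation) is one call to `run_condition()`, and
`run_matrix()` sweeps the full study grid of chain modes × salt ×
confinement; see the methods vignette (`vignettes/pebridge-methods.Rmd`)
for the model, the sampling scheme and the choice of desk-scale sizes.

A thin command-line interface over the same functions is included at
`inst/cli/pebridge.R` (subcommands `run`, `matrix`, `pmf`, `observables`,
`fixture`).

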