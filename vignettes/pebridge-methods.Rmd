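---
title: "Methods: coarse-grained Monte Carlo for ion-mediated polyelectrolyte interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained Monte Carlo for ion-mediated polyelectrolyte interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pebridge` simulates two identical, negatively charged polyelectrolytes
(PEs) — coarse-grained stand-ins for nucleic-acid-like chains — immersed in
a periodic cubic box of mixed 1:1 and 3:3 salt. Each chain is a discrete
worm-like bead chain of N = 21 beads of diameter sigma = 0.42 nm, each
carrying charge −e, with fixed bond length l0 = 1.1 sigma. Ions are
center-charged spheres of the same diameter. The solvent is an implicit
dielectric continuum.

Three energy terms make up the Hamiltonian (lengths in sigma, energies in
kT throughout):

* **Coulomb**: `U_C = lB * zi * zj / r`, with Bjerrum length
  lB = 0.714 nm = 1.7 sigma (water, 300 K). Periodic boundaries are
  handled with the minimum-image convention and *no* Ewald summation: the
  box (L = 62 sigma by default) is kept at least an order of magnitude
  larger than the Debye length of the 20 mM buffer (about 2.2 nm), so the
  neglected periodic images are strongly screened. This is a deliberate
  modelling choice, discussed under "Numerical choices".
* **Excluded volume**: the purely repulsive WCA form
  `4*eps*(r^-12 − r^-6) + eps` for `r < 2^(1/6)`, zero beyond, with
  eps = 5/6 kT. Bonded neighbours (held at fixed l0 = 1.1 sigma, just
  inside the 1.122 sigma cutoff) contribute this and the Coulomb term like
  any other pair; because bond lengths never change, these terms are
  constants that cancel in every Metropolis energy difference.
* **Bending**: `(P/l0) * sum_i (1 − cos theta_i)` over the internal
  angles, with persistence length P. The rigid modes carry no bending
  term.

The central bead of each chain is fixed on the x axis at ±x/2. Four chain
flexibilities are supported: parallel rigid rods (fully static reference
case), rotatable rigid rods (P = infinity; rigid rotations about the fixed
central bead), and bendable chains with P = 10 nm (comparable to the
9.24 nm contour length) or P = 2 nm (much more flexible).

To model a chain inside a hexagonal PE array, each chain can be confined
to a hard cylinder of radius R = x around its own axis — the mean steric
exclusion exerted by the six neighbours at the array spacing x. Removing
the confinement (R = infinity) gives two free chains.

Monovalent counterions (42, one per monomer charge) always neutralise the
chains; a 20 mM 1:1 buffer is always present; and 3:3 salt is added at
0, 0.5 or 5 mM — the low/medium/high regimes for trivalent condensing
agents. Pair counts per species are `round(c * N_A * L^3)`; cations and
anions are added in equal numbers so neutrality is exact by construction.

## Sampling

A Metropolis Monte Carlo sweep attempts one translation per free ion
(uniform in a cube, wrapped by the periodic boundary) plus a number of
chain moves set by the move mix (default ion:pivot = 0.9:0.1). Chain
moves are:

* **rotatable rigid**: a rigid rotation of the whole rod about its fixed
  central bead around a uniformly random axis; positions are rebuilt from
  the rotated unit direction at exact multiples of l0, so the rod stays
  exactly straight with exact bonds for arbitrarily long runs;
* **bendable**: a pivot move — a random bead (excluding the ends) is
  chosen, and the arm on the side away from the fixed central bead is
  rotated rigidly about it (either arm, at random, when pivoting at the
  centre). Pivots change one bending angle, preserve all bond lengths
  exactly, and never touch the fixed bead.

Any chain move that would take a bead outside its confinement cylinder is
rejected outright (an infinite-energy proposal). Parallel rigid chains
have no degrees of freedom left once their centres are fixed and their
orientation is restrained, so only ions move in that mode.

Step sizes (ion displacement, maximum pivot angle) are auto-tuned toward
30–50% acceptance during equilibration only, then frozen, so production
sampling satisfies detailed balance with a fixed proposal distribution.

### Equilibration criterion

The mean force on chain 1 must equal that on chain 2; the run is declared
equilibrated when the two sliding-window force averages agree within 0.5%:
`|<F1> − <F2>| / max(|<Fbar>|, f0) < 0.005`, with a floor
f0 = 0.01 kT/sigma guarding the crossover region where the mean force
itself passes through zero and a purely relative test is ill-posed. The
window is configurable (5000 sweeps for full-size runs).

Two practical notes, both visible in the force traces the engine returns:
the instantaneous per-chain forces fluctuate by several kT/sigma, so at
desk-scale sampling the 0.5% agreement can take arbitrarily long to
trigger even though the observables of interest (bridging counts, mean
forces) are long since stationary; and the slowest mode is a collective
left/right imbalance of the condensed trivalent cloud, which the
symmetrised two-chain average `Fbar = (F1 + F2)/2` cancels to first
order. The condition driver and the acceptance script therefore treat the
criterion as a diagnostic: they equilibrate for a fixed sweep budget,
record whether the criterion was met, and proceed to production either
way. `run_until_equilibrium()` itself errors on non-convergence by
default, with the force trace attached.

## Forces and potentials of mean force

The inter-chain force on a chain sums, over its monomers, the Coulomb
force `lB * zi * zj / r^2` and the WCA force
`4*eps*(12 r^-13 − 6 r^-7)` (the analytic derivative of the pair energy)
from every particle *not* on that chain, projected on the x axis with the
repulsive direction positive. Intra-chain terms are internal forces and
cancel in the chain total by Newton's third law, so they are excluded.
The production estimate is the ensemble average of
`Fbar = (F1 + F2)/2`, with a 20-block standard error.

The potential of mean force is the trapezoidal integral of the mean force
from the outer reference separation x_ref = 8 sigma down the grid
(default x = 2 to 8 sigma in 0.5 sigma steps), so PMF(x_ref) = 0 by
construction and attraction shows as a negative well (its minimum sits
near contact, x ~ 2 sigma, at high trivalent salt).

## Observables

* **Charge fraction f(r)**: every ion is assigned the distance to its
  nearest monomer over both chains; the signed ion valences are binned
  (0.1 sigma bins), cumulated, and normalised by the total chain charge
  N = 42. f is the fraction of the chain charge neutralised within r;
  for any neutral box f reaches exactly 1 at full range — a built-in
  charge-conservation check. The difference
  `delta f(r) = f(x = 2 sigma) − f(x = 8 sigma)` measures how much extra
  ion charge condenses as the chains approach.
* **Effective separation D**: the snapshot average of the mean distance
  between index-matched monomers of the two chains. D = x exactly for
  parallel rods; rotation and bending fluctuations can only increase it.
* **Bridging ions N_b**: trivalent cations within r_c = 1.5 sigma of
  *both* chains, counted per snapshot (mean, standard deviation, and the
  charge fraction 3 N_b / 42). Bridging ions are the microscopic carriers
  of the like-charge attraction; their count anti-correlates with D
  across chain flexibilities.

Snapshots are recorded every 10 sweeps to decorrelate consecutive frames.

## Numerical choices

* **Electrostatics**: minimum-image bare Coulomb, no Ewald. At the 20 mM
  buffer the Debye length is about 5.2 sigma against a 62 sigma box, so
  image contributions are screened by e^(−12) or more; the error this
  neglect introduces is far below the statistical resolution of any
  reported quantity. The same reasoning bounds the box-size requirement
  for scaled-down runs (below).
* **Excluded-volume force**: the analytic derivative of the WCA energy is
  used, keeping energy and force exactly consistent; both vanish
  continuously at the 2^(1/6) sigma cutoff.
* **Fixed bonds**: bonds are hard constraints (no stretching potential is
  part of the model); all chain moves are isometries of the bonded
  geometry, so bond lengths are preserved to floating precision and the
  rigid rod is rebuilt from its orientation vector to avoid any drift.
* **Degenerate inputs**: exact particle overlaps make the energy
  non-finite and are reported as errors in the user-facing energy/force
  functions; as Metropolis proposals they are simply rejected.
* **Accumulation**: total energies and incremental move deltas are
  accumulated in extended precision, keeping the incremental/full-energy
  agreement below 1e-9 kT for physically meaningful configurations.
* **Ion-count rounding**: nearest integer per salt species, pairs added
  whole, so neutrality is never approximate.
* **Tie-breaks**: when a bendable pivot lands on the central bead, the arm
  to rotate is chosen by a fair coin; end beads are excluded as pivots
  (they would move nothing).

## Scaled-down study sizes

Full-size runs (L = 62 sigma, 616 particles at 5 mM 3:3, tens of
thousands of sweeps) reproduce the study conditions but take hours over a
full separation grid. The test suite and examples therefore use reduced
sizes, chosen once on physical grounds:

* For monovalent-only conditions (c33 = 0) a box of L = 30 sigma keeps
  the box more than five Debye lengths wide and preserves the 20 mM
  buffer with 24 salt pairs: finite-size effects stay small.
* For trivalent conditions a subtlety appears: concentrations are
  intensive but the *reservoir* is not. At L = 30 sigma, 5 mM 3:3 salt
  is only 6 trivalent cations (18 charges) against 42 monomer charges —
  condensation empties the bath, and the trivalent-mediated attraction
  physically cannot develop. The smallest box whose trivalent content
  matches the chain charge (3 n_33 >= 42) is L ~ 40 sigma; scaled-down
  trivalent runs therefore use L = 44 sigma (19 trivalent pairs). This
  replaces a uniform-scaling choice that the depletion analysis proved
  wrong.
* Desk-scale sampling (1000–1500 equilibration sweeps, 2500–5000
  production sweeps per grid point) resolves the qualitative orderings
  across chain flexibilities and the bridging-ion counts; quantitative
  PMF depths at full size need the long-run settings
  (`default_config(full = TRUE)`).

What passing desk-scale tests show — and what they do not: the generator
reproduces the model's own statistical mechanics (Boltzmann sampling,
worm-like-chain angle statistics, charge conservation, constraint
preservation) and the qualitative physics (repulsion ordering without
trivalent salt, bridging-driven attraction with it). They do not probe
sequence effects, chain-length dependence, dielectric inhomogeneity or
ion size asymmetry, none of which are part of the model.

## Known limitations

* No Ewald summation: unsuitable for unscreened (salt-free) boxes.
* Bridging counts use a sharp distance cutoff (1.5 sigma); values shift
  with the cutoff, as with any geometric binding definition.
* The confinement cylinder is a mean-field stand-in for explicit
  neighbours in an array; a whole-system (crowding) confinement is a
  different physical situation and out of scope.
* Parallel-rigid mode treats both rods as fully static; torsional or
  sliding degrees of freedom of a real array are not sampled.

## A worked desk-scale example

```{r}
library(pebridge)

sys <- build_system("bendable", x = 2, P_nm = 2, c33_mM = 5, L = 44,
                    seed = 1)
moves <- move_spec(sweeps_equil = 1500, sweeps_prod = 3000, seed = 2)
eq <- run_until_equilibrium(sys, moves, window = 500, on_fail = "warn")
run <- run_production(eq)

mean_force(run)
bridging_ions(run$trajectory)
effective_separation(run$trajectory)
```

A full condition (forces over a separation grid, PMF, observables) is one
call: `run_condition(default_config())`; the grid of the study's
conditions is `run_matrix()`.
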