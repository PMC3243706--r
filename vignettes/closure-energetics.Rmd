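---
title: "Mechanics and methods of the sheet-to-tube closure model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics and methods of the sheet-to-tube closure model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mtzip)
```

## The model

`mtzip` simulates the growth of a 13-protofilament microtubule whose plus
end terminates in an open, outward-curved tubulin sheet. Every monomer is a
point mass of 55 kDa; the lattice potential is the sum of seven harmonic
interactions (½ k Δ²): longitudinal, lateral and diagonal stretching
between neighboring monomers, longitudinal and lateral bending of monomer
triples (measured as the supplementary angle of the triple, so a straight
chain reads zero), and longitudinal and lateral dihedral bending that
penalizes twisting of protofilaments and helical turns against a radial
reference direction. All positions are in nm, forces in nN, masses in kDa;
1 kBT = 4.141×10⁻³ nN·nm at 300 K.

Key assumptions inherited with the interaction set:

- the canonical lattice geometry (4.0 nm longitudinal and 5.2 nm lateral
  intervals) fixes the cylinder radius, helical rise and the two diagonal
  rest lengths (5.9988 and 7.1242 nm) exactly;
- *flat* sheets are the lateral-bending ground state (equilibrium lateral
  angle 0°), so the closed tube stores ≈0.99 nN·nm (≈240 kBT) of lateral
  bending energy per interior triple — this frustration is the energy bank
  of the sheet-to-tube transition;
- the nucleotide state acts purely through the intrinsic longitudinal bend
  angle: 5° per monomer pair for GTP dimers, 18° for GDP. The α-subunit
  N-site nucleotide is non-exchangeable and mechanically inert; both
  monomers of a dimer report the β E-site state;
- no excluded volume, no thermal forces, no bond rupture (depolymerization
  is out of scope).

## Parameters that matter

`mt_params()` collects every constant. The mechanically decisive ones are
the lateral bend stiffness (8.5 nN·nm — drives sheet flattening and hence
the seam opening), the lateral stretch stiffness (14 nN/nm — sets the
closure barrier via the gap of the pair being zipped), and the two
intrinsic curvatures. The diagonal stretch (3 nN/nm) mainly conditions
convergence; the two dihedral constants (0.04, 0.17 nN·nm) are small
empirical regularizers. `lateral_rest_convention` selects whether the
5.2 nm lateral rest length applies to the Euclidean neighbor distance (the
default, the literal reading), to the planar chord, or to the exact
neighbor distance on the derived cylinder ("tube", which makes the closed
lattice stretch-free in the same way the diagonal rest lengths do); the
choice moves closure energetics by only a few percent.

## Relaxation

A conformational perturbation (assembly, closure, hydrolysis) is relaxed by
velocity-Verlet integration at dt = 0.1 with velocities rescaled by a
single scalar. Two thermostat semantics are provided. `verlet_step()` and
`thermostat = "constant"` rescale the average kinetic energy to exactly the
target each step; this also *injects* energy whenever the system is below
target, which inflates transient peaks and leaves a thermal dwell that the
convergence criterion cannot see through. The default for `relax()`
(`thermostat = "cap"`) therefore uses the rescaling only as a kinetic
ceiling: relaxations are purely dissipative, and the recorded energy peak
is the mechanical transient, not thermostat noise. The kinetic target
(default 0.5 kBT per monomer) follows a staged quench — whenever the
potential energy has not improved for `anneal_patience` steps it is halved
— so the termination rule, |RMS(E, last 10) − RMS(E, last 20)| < 10⁻⁴
nN·nm, can fire once the structure has settled. After the Verlet phase an
L-BFGS descent on the analytic gradient (`polish_maxit`, default 25 000
iterations) takes the state to its precise local minimum. The polish
matters: equilibrium energies enter steppings and assembly strains as
*differences* of order a few kBT, while an unpolished quench can carry tens
of kBT of residual soft-mode strain.

Numerical choices worth knowing:

- **Dihedral degeneracy.** A perfectly straight protofilament has no
  measurable twist: the defining plane of its longitudinal dihedral is
  degenerate. Each dihedral term is multiplied by a smooth window
  w = u/(u + 10⁻⁶) per plane, with u the squared sine of the angle between
  the plane's spanning vectors; terms fade out smoothly instead of
  switching off, keeping the landscape C¹ for the integrator and the
  polish. Energies in curved regions (sines of order 0.1) are unaffected.
- **Radial reference.** Dihedral references point away from the tube axis,
  taken as the lab z direction through the conformation's xy centroid.
  Anchoring at the centroid makes the potential exactly translation
  invariant (the gradient correction is a mean-force subtraction), and
  rotations about the tube axis are an exact symmetry; rotations that tilt
  the axis are not, which is inherent to an axial reference convention.
- **Degenerate bends.** At an exactly straight triple with a bent
  equilibrium angle the bending force direction is undefined (a cone
  apex); a deterministic radial-leaning fallback direction is used so
  symmetric starts still break toward the physical flare.
- **Divergence guard.** A relaxation aborts with the worst-force monomer
  named if the energy exceeds `divergence_factor` times its start.

## The standard closure experiment

`standard_sheet_state()` builds the reference structure: 40 monomers per
protofilament (520 total), the top 10 an open GTP sheet, the body GDP. The
initial guess curls each protofilament outward in its radial plane at the
GTP angle; the guess is then form-found (relaxed to equilibrium), and the
relaxed state defines E₀. `close_monomer_pair()` zips the lowest open
cross-seam pair — one lateral stretch, two lateral bend and two lateral
dihedral terms (cross-seam diagonals optional and off by default) — applies
the hydrolysis rule, and relaxes. The barrier is the transient energy peak
over E₀; the stepping is the new equilibrium over E₀. With the default
conditions the model yields a barrier of ≈2.9×10⁴ kBT and a stepping of
≈2650 kBT per monomer pair, both repeating within a few percent over
successive closures in the quasi-static protocol.

Two closure-sequence protocols are exposed because they genuinely differ in
this model. Under `mode = "formfind"` (default) each closure starts from a
freshly form-found equilibrium of the partially zipped structure; the
sequence walks through a self-similar family and successive barriers and
steppings agree to within ten percent. Under `mode = "continue"` each
closure continues from the previous closure's own relaxed end state; the
closure transient kicks the sheet into progressively more flared
conformations (which are genuinely lower minima), and barriers grow several-fold
over the first five closures before roughly saturating. The continuation
drift is a finding about this potential, not a numerical artifact: it
persists under gentler thermostats, different guesses and tighter
convergence.

Known limitation: the absolute barrier scales with the square of the
equilibrium seam gap at the sheet root, and that gap is set by the balance
between lateral-bend flattening of the sheet and its coupling to the closed
body. Our deeply converged form-found sheets open to ≈8.9 nm at the root.
Accordingly the barrier lands at ≈2.9×10⁴ kBT rather than ≈10⁴, the
cap-length sweep rises smoothly toward its long-sheet value instead of
plateauing sharply above four monomers (the derived minimum stable cap
comes out near four rather than two dimer layers), and a tenfold *increase*
of the longitudinal dihedral constant — which penalizes the protofilament
lean that accompanies flattening — reshapes the equilibrium noticeably.
Under-converged relaxations produce tighter sheets and smaller barriers,
so these absolute quantities should be read as form-finding dependent;
the steppings, their regularity, and the remaining insensitivity
properties are robust.

## Events and experiments

Assembly follows an integrated thermodynamic rule: for each candidate
protofilament a GTP dimer is tentatively appended at the tip, the structure
relaxed, and ΔE = strain + ΔG_assoc computed, with ΔG_assoc = −16, −12 or
−8 kBT for gap, side and crest sites (two, one or zero pre-assembled
lateral neighbor dimers). Sites with ΔE ≥ 0 cannot assemble; among the
rest one event per growth step is drawn with probability ∝ exp(−ΔE)
(`policy = "boltzmann"`; an independent per-site Metropolis variant is
config-selectable). All tentative additions are rolled back; topology is
always rebuilt from the monomer table and seam state, so terms cannot
dangle.

Hydrolysis rules: `synchronous_turn` advances a closed-tube surface one
monomer level per closure and hydrolyzes every dimer that has sunk entirely
below it (≈6–7 dimers, i.e. one 13-monomer helical turn per closure, at
dimer granularity); `ordered_cap` keeps only the top k dimer layers GTP;
`random` draws one uniform number per sheet GTP dimer and hydrolyzes above
the threshold. All rules are irreversible.

Experiment presets: `run_closure_sequence()` (multi-closure energetics),
`run_single_closure()` (the variant experiments — curvature, nucleotide
scenarios, constant sensitivity — all compared from a common initial-guess
curl of 5°/monomer so that differences reflect the potential, not the
guess), `run_sheet_length_sweep()` (equal total protofilament length per
condition, one closure each, plateau detection and the minimum-stable-cap
statistic), `run_sensitivity_sweep()` (one constant × factors),
`run_tetris()` (assembly until a 13-dimer layer completes, then a
dimer-length of zipping — two monomer pairs, config-exposed — with stall
detection and a replayable event log).

## What the generator emulates, and what it does not

All inputs are generated internally: the lattice builder is the data
generator, and its defaults are the study conditions (13 protofilaments,
3-monomer pitch, 10-monomer GTP sheet over a hydrolyzed 40-monomer body,
Table-constant stiffnesses). It emulates the mechanics of a sheet-ended
microtubule under the seven-interaction potential. It does not emulate
solvent, thermal fluctuations (temperature enters only through the kinetic
rescaling scale and the kBT conversion), tubulin substructure, lattice
defects other than the seam, or depolymerization; passing tests therefore
validate the mechanochemical bookkeeping and the relative energetics of
closure, not kinetic rates or rupture behavior of real microtubules.

## Problem sizes and budgets used by the tests

The shipped tests form-find 520-monomer standard states (tens of seconds
each), run the ten-condition cap sweep at a reduced relaxation budget
(`max_steps` 6×10⁴, `polish_maxit` 1.2×10⁴), and exercise Tetris growth at
bookkeeping level on a 13×12 lattice with forced acceptance, since full
thermodynamic growth costs thirteen candidate relaxations per event. The
small planar and tube fixtures used by the force/energy oracles carry no
approximations — they are exact instances of the same potential.
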