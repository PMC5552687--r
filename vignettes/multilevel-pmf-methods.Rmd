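---
title: "Methods: multi-level PMF composition with surrogate potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level PMF composition with surrogate potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpmf)
```

## The model

`mlpmf` treats a reactive solute in explicit water with the embedded QM/MM
partition

$$V_{\mathrm{potential}} = V_{\mathrm{qm}} + V_{\mathrm{qm/mm}} + V_{\mathrm{mm}},$$

where $V_{\mathrm{qm}}$ is the solute's internal energy at a theory tier,
$V_{\mathrm{mm}}$ is the SPC/E water-water energy (Lennard-Jones on oxygen
pairs plus Coulomb on all sites), and the coupling $V_{\mathrm{qm/mm}}$ is
electrostatic embedding with van der Waals terms inside a hard cutoff around
the solute and Coulomb against the solute's ESP point charges beyond it.
This additivity is enforced structurally — `compose_energy()` computes the
total as the sum of the three parts — and tested as an identity over
randomized configurations.

The free-energy workflow composes a high-tier potential of mean force from a
cheap-tier one. With $A$ the reactant bead and $B$ any bead of the path,

$$\Delta W^{\mathrm{HIGH}}_{AB} = \Delta W^{\mathrm{ESP}}_{AB}
 + \left(\Delta W^{\mathrm{LOW\leftarrow ESP}}_{BB} - \Delta W^{\mathrm{LOW\leftarrow ESP}}_{AA}\right)
 + \left(\Delta W^{\mathrm{HIGH\leftarrow LOW}}_{BB} - \Delta W^{\mathrm{HIGH\leftarrow LOW}}_{AA}\right),$$

where each fixed-configuration shift is a Zwanzig estimate
$-kT\,\ln\langle e^{-\Delta U/kT}\rangle$ in an ensemble sampled at the
cheaper tier's coupling. Written as differences of per-bead shifts the
composition is an exact thermodynamic cycle: sampling the high tier directly
must agree with the composed profile up to statistical error, which is the
package's primary oracle-equivalence test.

### Why shifts enter as differences

Some renderings of the composition print the two fixed-configuration shift
terms as a sum ($\ldots_{AA} + \ldots_{BB}$). Closure of the thermodynamic
cycle (switch tier at $A$, move $A\to B$ at the cheap tier, switch back at
$B$) requires the *difference* $BB - AA$; a sum is not invariant to adding a
constant to either tier's energy. `compose_pmf()` therefore implements
differences, and a test asserts that bead-independent shifts leave every
barrier unchanged.

## The surrogate solute and its tiers

Real electronic structure is out of scope; the solute is a 7-atom analytic
surrogate (atoms N7, C8, O10, H8, N9, H9, H10, echoing the ring-opening
chemistry it emulates) with one breakable bond, C8–N9:

* **ESP tier** — harmonic bonds, angles and two torsions, plus a Morse term
  ($D_e = 60$ kcal/mol, $a = 2.0$ Å⁻¹, $r_0 = 1.47$ Å) on the breakable
  bond, and the conformational point-charge set described below. This is
  the cheap tier that the solvent sampler sees.
* **LOW tier** — adds a Gaussian product-stabilisation well (depth 38
  kcal/mol, centre 2.9 Å, width 0.35 Å) along the bond coordinate, making
  the stretch a genuine double-well reaction with a reactant minimum near
  1.47 Å, a product minimum near 2.85 Å, and a barrier of roughly 30
  kcal/mol (the 1-D scan oracle `scan_bond_profile()` is the reference).
* **HIGH tier** — the LOW tier plus a bounded additive perturbation
  (amplitude 2.5 kcal/mol, centre 2.25 Å, width 0.35 Å), the same order as
  a DFT-to-coupled-cluster barrier change, so both level-shift terms of the
  composition are nonzero and testable.

A design choice deserves a note. A "pure point-charge" ESP tier with *no*
internal solute energy would make the composed profile's cheap term carry no
chemistry, and the decoupled-solute limit of the sampled PMF could not
reduce to a gas-phase profile. The package therefore gives the ESP tier its
own internal surface (everything except the product well and the HIGH
perturbation) and includes the internal energy change in
$\Delta W^{\mathrm{ESP}}_{AB}$; with the coupling switched off the sampled
profile then collapses *exactly* onto the ESP gas profile, which is tested.

Charges interpolate linearly between a neutral reactant-state set and a
neutral product-state set as a function of the breakable-bond length,
clamped at the end-point geometries — a stand-in for conformation-dependent
ESP fits, which no published parameterisation pins down for this system.
Tiers scale the charge set (ESP 1.00, LOW 1.04, HIGH 1.06) to emulate the
stronger solute polarization of better theory tiers; this gives the level
shifts a genuinely ensemble-dependent part rather than a constant, so the
Zwanzig machinery is exercised for real.

Reactant and product geometries are built by internal-coordinate placement
and then minimised on the LOW tier to gradient norms below $10^{-4}$
kcal/mol/Å; every bonded term's equilibrium value is taken from the built
geometry, so the construction is consistent by design rather than by tuning.

## Explicit water

Water is rigid three-site SPC/E: charges $q_O = -0.8476\,e$,
$q_H = +0.4238\,e$, oxygen Lennard-Jones $\sigma = 3.166$ Å,
$\varepsilon = 0.1553$ kcal/mol, O–H 1.0 Å, H–O–H 109.47°. The Coulomb
constant is pinned at 332.0637 kcal·Å/(mol·e²) for bit-reproducibility. The
reference box is a 37.5 Å cube of 1752 molecules (0.994 g/cm³); the
demo-scale default is 64 molecules in a 12.4 Å cube at the same density, so
the full pipeline runs in minutes.

Box generation is seeded. At dilute packing, molecules are placed by
rejection sampling with a minimum O–O distance of $0.9\sigma$. At
liquid-like packing that sampler jams (random sequential addition stops
near packing fraction 0.38, and the reference box sits at 0.40), so dense
boxes seed the oxygens from a shuffled cubic lattice — simple cubic,
body-centred or face-centred, whichever maximises the nearest-neighbour
distance — with a jitter bounded so the minimum distance still holds
exactly; orientations are uniform random rotations. An $O(n^2)$ test
verifies the constraint exhaustively.

Waters clashing with an inserted solute are removed along the whole swept
reaction path (`carve_box()`), not just at the endpoints, so no bead starts
inside a water.

## Path optimisation

`neb_relax()` implements NEB with the energy-upwinded ("improved") tangent,
spring constant 1 kcal/mol/Å² by default, FIRE relaxation with a per-bead
displacement cap (0.1 Å), and a climbing image switched on for the highest
bead after 50 iterations. Convergence is the per-bead max-norm of the
projected NEB force, default 0.05 kcal/mol/Å; convergence is never declared
while a climbing phase is still pending. Endpoints are never moved;
non-convergence returns the partial path flagged and warns. Ten beads is
the default path resolution.

The solution-phase path is relaxed with the waters *frozen* at an
equilibrated snapshot — a minimum-energy path in a fixed environment, not a
free-energy path. How the original solvated path calculations treated the
solvent degrees of freedom during path relaxation is not documented in the
source material; freezing is this package's choice and is stated as such.

Stationary points are verified by `frequencies()`: central-difference
Hessian of the analytic gradient (step 0.005 Å), symmetrisation,
mass-weighting, projection of the six rigid-body modes for molecular
systems (analytic 2-D surfaces use unit masses, no projection), and
conversion to cm⁻¹ with imaginary modes reported as negative. A first-order
saddle has exactly one imaginary mode; this is asserted on the double well,
the Mueller-Brown saddle, and implicitly via the solute's clean reactant
spectrum (15 positive internal modes).

## Sampling and estimators

The canonical ensemble over rigid waters is sampled by Metropolis Monte
Carlo (the simplest correct choice at this scale): one sweep attempts one
combined translation (±0.14 Å per axis) + rotation (±0.40 rad about the
oxygen) move per molecule, with a hard-wall cube confining the droplet.
All randomness flows through R's RNG, so trajectories are bitwise
reproducible from a seed; per-bead seeds fan out deterministically from one
master seed via `sample.int()`. Successive beads warm-start from the
previous bead's final configuration, which shortens equilibration because
adjacent solute geometries differ little.

Temperature defaults to 298.15 K (the source material states no
temperature; order-of-magnitude rate comparisons are insensitive to
physiological choices, which is tested). Standard errors come from block
averaging with 10 contiguous blocks. The Zwanzig estimator is one-sided and
forward, per the composition's structure; a variance guard
($\mathrm{var}(\Delta U) > 25\,(kT)^2$) rejects poorly overlapping
perturbations with advice to use more beads — with 8 beads the surrogate
system genuinely trips this guard, with the default 10 it does not.

Sampling lengths are the package's production protocol: 500 equilibration
and 2000 production sweeps per bead with a stride of 10 (200 stored frames)
for the oracle-equivalence comparison, and lighter settings for interactive
use (the defaults are 300/1000/10). One-sided exponential averaging carries
a finite-sample bias that block standard errors do not capture, so the
protocol was sized to where composed and directly sampled profiles agree
within their combined errors across seeds, not merely to where errors look
small.

## Decomposition bookkeeping

`decompose_solvent()` reports, per bead: the gas-phase profile (high-tier
internal energy on the same beads, referenced to the reactant bead), the
polarization term (ensemble-average solute–solvent interaction energy, i.e.
the internal QM/MM energy minus the gas-phase energy), the aqueous
contribution (composed PMF minus gas profile), and the solvent-energy
contribution defined by the identity

$$\text{aqueous} = \text{solvent energy} + \text{net polarization},$$

which therefore holds to machine precision and is tested as such. The
worked examples apply the same bookkeeping to the published numbers: a
solvent energy of 6.0 kcal/mol plus a net polarization of −0.7 gives the
5.3 kcal/mol aqueous contribution to the barrier; 27.9 + (−0.8) gives the
27.1 kcal/mol contribution to the reaction energy.

## Thermodynamic cycle and rates

`cycle_compose()` is exact arithmetic on five inputs; solvation free
energies are *inputs* here (continuum-model outputs in the source
workflow), never computed. `tst_rate()` uses
$A = (k_BT/h)(RT/P)$ expressed per molecule in cm³/molecule/s — the
bimolecular standard-state volume factor is kept even for a unimolecular
step because the reference rates are printed in those units — with CODATA
2018 constants pinned in `physical_constants()`. "Nearest power of ten" is
`round(log10 k)`, the comparison used for order-of-magnitude claims;
`rate_ratio_orders()` cancels the prefactor analytically, so it is
independent of the standard-state pressure.

## Geometry module conventions

Torsions follow the IUPAC sign convention with range (−180°, 180°]; cis is
0°, trans 180°; collinear inner atoms raise an explicit error. Differences
of periodic quantities use the minimal wrapped distance, so no comparison
can exceed 180°. Hydrogen bonds use geometric criteria — H···acceptor ≤
3.0 Å and donor–H···acceptor angle ≥ 120°, both configurable — with N–H and
O–H donors (C–H optional) found from covalent connectivity inferred at 1.2
times the summed covalent radii; the published contact distances the
package ships span 1.766–2.812 Å, which motivated the 3.0 Å default.
Structures missing hydrogens yield an empty result with a warning, not an
error. The cutoff boundary in the QM/MM coupling is group-based (a water is
in or out as a whole, by its oxygen's distance to the nearest solute atom)
with the strict tie-break "inside means r < cutoff".

## What the generators emulate — and what they do not

The synthetic system reproduces the *structure* of the multi-level
workflow: a reactive solute with conformational charges, three nested
theory tiers, explicit rigid water, a cutoff-embedded coupling. It does not
reproduce electronic polarization (charges respond only to one internal
coordinate), charge transfer, bond topology changes beyond one breakable
bond, periodic electrostatics (the droplet is non-periodic by default;
minimum-image wrapping exists behind a flag for the water-water term), or
the absolute energetics of any real molecule. Passing tests therefore
demonstrate that the *machinery* — estimators, composition, bookkeeping,
optimizers — is correct at desk scale, not that the package predicts real
ring-opening barriers; the published barriers (19.2, 28.8, 31.6 kcal/mol)
enter only as worked-example inputs.

## Known limitations

* One-sided Zwanzig shifts only; BAR-style two-sided estimation is not
  implemented.
* The frozen-solvent NEB gives a minimum-energy path, not a free-energy
  path; umbrella sampling/WHAM are out of scope.
* The coupling gradient with respect to solute coordinates is obtained by
  central differences (the charges' dependence on the bond length makes the
  analytic form unrewarding); all other gradients are analytic and
  FD-verified.
* Hard truncation without a switching function can make the coupling
  discontinuous when a molecule crosses the cutoff; at the shipped box
  sizes everything is inside the 15 Å cutoff, so this only matters for
  user-supplied large boxes.
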