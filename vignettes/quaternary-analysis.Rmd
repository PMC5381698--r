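---
title: "Methods: quaternary-structure analysis of oligomeric enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quaternary-structure analysis of oligomeric enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatstruct)
```

This vignette documents the models, conventions and numerical choices
behind `quatstruct`. The package targets oligomeric enzymes whose function
depends on quaternary structure — the motivating system is the D4 octamer
of human UDP-glucose pyrophosphorylase (hUGP), where each subunit's
sugar-binding loop is stabilised by an arginine–aspartate contact from the
neighbouring subunit (the *interlock*) and product binding measurably
compacts the assembly — but every component is generic over Cn/Dn
homo-oligomers.

## Coordinate model

A structure is an **assembly**: a tibble with one row per atom (chain,
author residue number, insertion code, residue and atom names, element,
coordinates in Å, occupancy, B-factor, altloc, heteroatom flag) plus
structure-level attributes (identifier, apo/product-bound label, optional
unit cell and space group). Parsing goes through bio3d; only the first
model of multi-model files is kept (crystal structures are single-model),
and alternate locations are collapsed to one conformer per atom — highest
occupancy wins, ties broken by altloc letter — so all downstream geometry
is deterministic. Ligands and waters are retained but flagged, and
excluded from protein selections by default. The inputs carry no
hydrogens, so **every geometric criterion in the package is heavy-atom
based**.

Named functional regions (e.g. the hUGP sugar-binding loop, T286–G293) are
chain-agnostic sets of inclusive residue-number ranges in a declared
numbering scheme. Isoform numbering differences are handled by an explicit
integer offset added to the region bounds: hUGP isoform 1 numbering runs
11 higher than isoform 2, so isoform-1 regions apply to an isoform-2 chain
with offset −11. Residues covered by a region but absent from the
coordinates (disordered loops) are reported as missing, never silently
dropped, and an empty selection is a warning rather than an error so batch
runs survive sparse models.

## Rigid superposition and displacement profiles

Superposition is the classical least-squares (Kabsch) fit: the rotation
minimising RMSD is obtained from the SVD of the cross-covariance matrix
with the determinant sign correction that excludes reflections. Degenerate
(rank-deficient, e.g. collinear) point sets still return a minimising
transform but are flagged. The test suite checks the fit against two
independent references: a brute-force scan over Euler-angle space with
local refinement, and bio3d's own fitting routine.

Displacement profiling between an apo and a product-bound chain separates
two regions:

* the **fit region** — a stable part of the structure whose Cα atoms
  define the superposition frame;
* the **report region** — the functional element whose per-residue Cα and
  maximum side-chain heavy-atom displacements are measured after applying
  the fitted transform.

The choice of fit frame is the single largest sensitivity of displacement
maxima, and published comparisons rarely state it; it is therefore an
explicit parameter (`fit_region` in the pipeline configuration), defaulting
to all residues outside the binding region. Correspondence between states
is by residue number (after offsets) and atom name; atoms present in only
one state are skipped and counted, glycines have no side-chain value, and
no outlier rejection or iterative trimming is applied — reported maxima
are raw, matching how such numbers are usually quoted.

## Point-group detection

`detect_point_group()` identifies the highest-order Cn or Dn group whose
rotations map every chain onto another chain within a Cα-RMSD tolerance:

1. all pairwise chain-to-chain transforms are computed (Kabsch on shared
   residue numbers) and reduced to angle/axis form;
2. the principal axis is estimated from the summed skew parts of the
   near-superposing rotations (`sin θ · u` vectors): in-ring rotations
   accumulate along the ring axis while the perpendicular 2-folds of a
   dihedral group contribute nothing, making the estimate robust; when all
   observed rotations are 2-folds (C2/D2) the axis closest to +z is taken,
   with a deterministic hemisphere convention for reproducibility;
3. candidate groups are validated *constructively*: rotation by 360/n about
   the estimated axis through the assembly centroid must permute the chains
   (bijectively, with cycle length n) within the residual tolerance, and a
   Dn additionally requires a validated 2-fold about a perpendicular axis
   taken from the observed 180° pair rotations.

Candidates are tried in decreasing group order (D(N/2) before CN before
smaller divisors), so a D4 octamer is never reported as the C4 of one of
its rings. If no group validates on the full assembly, the label is C1 and
the detector iteratively drops the least-connected chain until a subgroup
validates on a consistent subset, which is reported alongside — one
displaced chain thus downgrades a D4 to C1 with an intact-C4 subset, rather
than failing. Defaults: angle tolerance 5°, residual tolerance 1.5 Å —
loose enough for crystallographic noise (the motivating structures are at
~3.3 Å resolution with 0.4–0.5 Å coordinate error), strict enough not to
merge distinct conformers. A property test verifies recovery of planted
Cn (n ∈ {2, 3, 4, 6}) under 0.2 Å coordinate noise at residual tolerance
1 Å.

Interfaces are classified per chain pair by counting inter-chain
heavy-atom pairs within 4.5 Å: fewer than 30 pairs is no interface;
otherwise the pair is **end-to-end** when more than half of the contacting
atom pairs fall inside user-named terminal-strand regions on both sides
(the C-terminal β-strand dimer contact of the UGP octamer), else
**side-by-side**. The "face-to-back" (heterologous) ring arrangement is
reported as a boolean: the cyclic generator realises a single n-cycle.

## Typed contacts and the lock/interlock classification

Contact detection is a grid-accelerated neighbour search (cubic cells of
one cutoff edge, 27-cell neighbourhoods) emitting one record per atom pair
and satisfied criterion:

| type | criterion | cutoff |
|---|---|---|
| `hbond` | donor-capable N/O to acceptor-capable N/O | 3.5 Å |
| `salt_bridge` | side-chain N of Arg/Lys/His to side-chain O of Asp/Glu | 4.0 Å |
| `hydrophobic` | side-chain C to side-chain C of apolar residues | 4.5 Å |

Donor/acceptor capability comes from a fixed per-residue atom table, not
computed chemistry — at the resolution regime of interest angular H-bond
criteria are unreliable and hydrogens are absent, so a distance-only
heavy-atom criterion with a 3.5 Å cutoff is the defensible choice. A pair
may satisfy several criteria (an Arg guanidinium N at 2.9 Å from an Asp
carboxylate O is both H-bond and salt bridge). Atom pairs within one
residue are excluded; each unordered pair is emitted once in canonical
order. The grid search is verified against an exhaustive all-pairs oracle
(exact set equality) and is invariant under global rigid motion; raising
any cutoff can only add records. The hydrophobic criterion has no
universally agreed published form; the table above is this package's
declared convention.

`detect_interlock()` restricts contacts to those touching a binding
region and classifies its stabilisation: **interlock** if at least one
stabilising contact is intermolecular, **lock** if an intramolecular
contact with sequence separation ≥ 20 residues stabilises it (tertiary
stabilisation, as opposed to local backbone contacts; the threshold is a
parameter), **both** or **none** otherwise. A region may genuinely be
stabilised both ways; the dominant published narrative is recovered as the
dominant class rather than forced binary. In a symmetric oligomer the same
(region residue, partner residue) pattern should recur in every chain;
chains deviating from the recurring pattern are listed. The in-silico
mutation check truncates a substituted side chain to the atoms shared with
the new residue type (no rotamer building — a geometric plausibility
screen, not energetics) and reports every contact lost; the delta of a
double mutant is exactly the union of its singles.

## Compaction metrics

Extents are measured in the symmetry-aligned frame: z is the principal
axis, x the projection of the first secondary 2-fold (or a deterministic
perpendicular for cyclic groups), y completes the right-handed set. The
frame is computed on the product-bound assembly and reused for the apo
assembly after rigid superposition, making per-axis deltas comparable. The
volume proxy is the frame-aligned bounding box `e_x · e_y · e_z`;
published compaction figures rarely define their volume measure, so the
convention here is declared and parameterised rather than assumed. A
robust variant (1st–99th percentile span of the projections) is available
for sensitivity analysis against stray atoms; raw min/max is the default
since published values are assumed raw. Percent change is
`(V_holo/V_apo − 1)·100` with compaction negative; anisotropic scaling
(s_x, s_y, s_z) reproduces `(s_x·s_y·s_z − 1)·100` exactly, and swapping
the states inverts the ratio. A convex-hull volume would be a natural
second proxy; it is not provided, since no hull backend is among the
package's dependencies and the percentile-extent option covers the
sensitivity role.

## Scalar biophysical models

**Unit cell and Matthews coefficient.** Cell volume uses the triclinic
closed form `abc·√(1 − cos²α − cos²β − cos²γ + 2cosα·cosβ·cosγ)`. The
Matthews coefficient is `V_M = V_cell/(Z·M)` (Å³/Da) and solvent content
`(1 − 1.230/V_M)·100`%, the constant 1.230 Da/Å³ being the reciprocal
protein density for a partial specific volume of 0.74 cm³/g; V_M ≤ 1.230
leaves the solvent fraction undefined and flagged. Chain masses come from
average-isotope residue masses plus one water per chain. Nothing is
rounded inside the computation.

**Kinetics.** Velocities are fitted by Levenberg–Marquardt least squares
to `v = V_max·x/(K_m + x)` or the Hill form `v = V_max·x^H/(K^H + x^H)`
(K reported as K₀.₅). Hill fits are initialisation-sensitive, so a
multi-start is used: V_max₀ = 1.2·max(v), K₀ from the interpolated
half-max concentration, H₀ ∈ {0.5, 1, 2, 4}; the converged start with the
lowest RSS wins, and failure of every start is an error with diagnostics,
never a silent fallback. Since Michaelis–Menten is Hill with H = 1, model
preference uses the extra-sum-of-squares F-test
`F = (RSS_MM − RSS_Hill)/(RSS_Hill/(n − 3))` with Hill preferred at
p < 0.05 — the formal version of judging a substrate-velocity curve
"obviously sigmoidal". Fits are scale-covariant (rescaling velocities
rescales V_max, leaves K and H) and unit-agnostic.

**Melting curves.** Thermofluor data are min-max normalised to [0, 1] and
fitted to the Boltzmann sigmoid `F(T) = 1/(1 + exp((T_m − T)/slope))`;
the inflection point T_m is the melting temperature, constrained to the
measured range. Two normalisation windows are implemented because
published protocols rarely state theirs: `"plateau"` (default) uses the
means of the first and last five points as the pre- and post-transition
baselines, which resists isolated spikes; `"minmax"` uses the global
extrema. Data with no fluorescence rise are rejected as non-sigmoidal.

## The synthetic generator: what it does and does not emulate

Every analysis stage is validated against fixtures with *known* ground
truth, generated in code:

* **subunits** are poly-alanine helices built from ideal internal
  coordinates (φ = −57°, ψ = −47°) by internal-to-Cartesian chain
  extension, giving exact ideal bond lengths and ~3.8 Å Cα spacing —
  geometric objects with just enough residue chemistry for the
  contact-typing tables, no sterics or energetics;
* **assemblies** place n copies around z (and a mirrored second ring for
  Dn) at a radius auto-chosen for ≥ 4 Å clearance, carrying the exact
  placement operators as ground truth; any inter-chain atom pair under
  2.5 Å is an error;
* **planted contacts** turn a region residue of every chain into a toy
  arginine and a partner residue into a toy aspartate, then translate each
  aspartate minimally to put the NH1–OD1 pair at the target distance
  (verified to 0.01 Å); the edit is replicated through the symmetry
  operators, so the point group is preserved exactly and the mutual
  neighbour-pair pattern of the real interlock is reproduced;
* **apo/holo pairs** rotate a region rigidly about a per-chain hinge; the
  expected displacement of every atom is the chord `2r·sin(θ/2)` of its
  distance r from the hinge line, so profile recovery is checked against
  an analytic value, not a re-simulation; an optional isotropic scale
  factor emulates compaction with an exact expected volume change;
* **kinetics/melt simulators** draw Gaussian noise around the closed-form
  models, deterministically per seed.

What the generator deliberately does **not** emulate: real fold topology,
sequence, ligand chemistry, crystallographic disorder, alternate
conformers, or correlated coordinate error. Passing the closure suite
therefore demonstrates that the geometry and fitting machinery is correct
and self-consistent, not that any particular deposited structure will
yield a given number — for real structures the fit-region sensitivity and
the volume-measure convention remain the user's responsibility to probe,
and both are exposed as parameters for exactly that reason.

## Pipeline, reproducibility and problem sizes

`run_quaternary_report()` chains the stages over an apo/holo pair and
emits one JSON report: symmetry per state, interface labels, per-region
displacement maxima, the interlock report and the compaction report, with
the full configuration serialised for provenance, Å values at 3 decimals
and percentages at 1 (matching usual reporting precision), and the
timestamp in a separate field so identical inputs give otherwise identical
bytes. A failing stage is recorded and localised while independent stages
still run.

The test and acceptance workloads are sized for interactive use: 30-residue
subunits (150 atoms) in tetramers and octamers, ~50-atom random assemblies
for the contact oracle, 500 simulated kinetics datasets (7 concentrations,
3% noise, cooperativity 1.7) for the Hill-recovery check and 100 simulated
melt curves (71 points, σ = 0.02, T_m = 55.65 °C) for the melting-point
check; the whole suite runs in well under a minute on one CPU. All
randomness flows from explicit seeds; there is no hidden global state.

## Known limitations

* No interface-area (SASA) or energetic computations; contact counts are
  the interface-size proxy.
* No symmetry-mate generation from crystallographic operators: the
  biological assembly must be supplied as coordinates (or built
  synthetically). Helical/translational symmetry is out of scope.
* The hydrophobic-contact criterion and the melt-normalisation window are
  declared conventions, not community standards; both are parameterised.
* In-silico mutation checks are purely subtractive (shared-atom
  truncation); gained contacts of the new side chain are invisible to
  them.
* Side-chain displacement is undefined for glycine and for residues with
  side-chain atoms missing in either state; such residues are excluded
  from side-chain maxima and listed.
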