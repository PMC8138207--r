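---
title: "Models and methods behind qgadock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qgadock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgadock)
```

`qgadock` predicts the non-covalent binding pose and binding energy of a
drug-like ligand on a graphene or graphene-oxide (GO) carrier. This vignette
documents the models, the tunable parameters, and the design choices — the
things a user should know before trusting a number the package prints.

## Carrier models

Pristine sheets are cut from an ideal honeycomb lattice with C–C bond length
1.42 Å, a hexagon center at the origin, the armchair axis along x, and the
sheet in the z = 0 plane. A circular cut keeps every carbon within the given
radius; carbons left with fewer than two carbon neighbours are dropped
(iteratively), and each remaining two-coordinate edge carbon is terminated
with one in-plane hydrogen at 1.09 Å. Under this convention the 21.760 Å
circle contains 138 carbons and 30 hydrogens — 168 atoms. The convention is
the package's calibration: the lattice origin and the "count atoms within the
radius, then terminate" rule together fix every count the builder produces,
and the edge hydrogens are part of the atom count.

GO ensembles are produced by decorating a sheet with three group types:

* **hydroxyl** — on a basal-plane (interior) carbon, oxygen displaced ±1.43 Å
  along z;
* **epoxy** — an oxygen bridging two adjacent basal carbons, ±1.25 Å above
  the bond midpoint;
* **carboxyl** — substitutes an edge hydrogen, built in-plane
  (C–C 1.50 Å, C=O 1.21 Å, C–O 1.34 Å).

`surface_mode` picks the face (upper/lower/dual) for the basal groups;
`manner` is either seeded random sampling without replacement or a
lexicographic systematic enumeration truncated at `max_models`.

**π bookkeeping.** Each conjugated sp² carbon contributes one π electron.
Every substituted carbon leaves the π system: the hydroxyl carbon and both
epoxy carbons are re-typed sp³ (`C.3`), and the carboxylated edge carbon —
chemically still sp², re-typed `C.2` — is likewise removed from the aromatic
subsystem. A model is accepted only if the remaining π count satisfies
Hückel's 4n + 2 rule *and* the π system is one connected component
(`check_hueckel()`). One (OH, epoxy, COOH) triple therefore removes exactly
4 π carbons, so a sheet that starts at 4n + 2 (138 ≡ 2 mod 4) stays at
4n + 2 at every functionalization level N — which is what makes ensembles of
20 models per level constructible at N = 1..5. Requests whose removal count
is not a multiple of 4 are rejected up front with an explanatory error
rather than after a futile rejection loop.

Duplicate GO models (same chemistry, different orientation or atom order)
are removed by fingerprint equality: a Morgan-style extended-connectivity
fingerprint of radius 5 folded to 2048 bits, computed on the heavy-atom graph
only. Equal fingerprints are treated as duplicates without an exact graph
check; a fold collision can in principle merge two distinct models, which we
accept as part of the fingerprint-equality rule.

## Energy model

The internal force field is a Tripos-style molecular-mechanics model:

| term | form | defaults |
|---|---|---|
| bond stretch | ½ k (r − r₀)² | per-type-pair table; fallback r₀ from covalent radii, k = 1200 kcal/mol/Å², with a warning |
| angle bend | ½ k (θ − θ₀)² | θ₀ 109.5°/120°/180° by center hybridization, k ≈ 0.02 kcal/mol/deg² |
| torsion | V/2 (1 + s cos nφ) | sp³–sp³: V 0.2, n 3; sp²–sp²/aromatic: V 2.0, n 2; mixed: V 0.12, n 6 |
| out-of-plane | k h² | trigonal sp² centers, k = 120 kcal/mol/Å² |
| van der Waals | ε[(R*/r)¹² − 2(R*/r)⁶] | R* = Rᵢ + Rⱼ, ε = √(εᵢεⱼ) |
| electrostatics | 332.0637 qᵢqⱼ / (4 r²) | distance-dependent dielectric ε(r) = 4r |

1-2 and 1-3 pairs are excluded; 1-4 pairs are scaled by 0.5 in both nonbonded
terms, a conventional docking choice (the dielectric and scale factors are
the package's own defaults; they are deliberately simple and there is no
cutoff at desk scale). Charges are Gasteiger-Marsili PEOE with the classic
parameter table, iterated with damping ½ᵏ until the largest per-bond transfer
falls below 10⁻⁸ e; because charge moves pairwise across bonds, the total is
conserved to machine precision and symmetry-equivalent atoms get identical
charges.

One deliberate deviation from the historical Tripos table: carbon uses vdW
R* = 1.90 Å, ε = 0.086 kcal/mol (the values common in modern biomolecular
force fields) rather than 1.70 Å / 0.107. Summed over a whole sheet, the
1.70 Å radius pulls a stacked benzene to ≈3.05 Å — below anything observed —
while 1.90 Å reproduces the physical π-stacking/graphite spacing of ≈3.4 Å.
The embedded parameter table covers the types the builder and fixtures emit;
an atom type without vdW parameters is an error, a missing bonded pair falls
back to documented defaults with a logged warning.

Minimization is a Powell direction-set search over all Cartesian
coordinates: cycle over directions, line-minimize each (bracket by doubling,
then `stats::optimize`), replace the direction of largest gain with the
cycle's net displacement, stop when a cycle gains less than `tol`
(default 10⁻⁴ kcal/mol). It is derivative-free and robust but O(N²) in
practice, intended for small molecules and patches, not for large sheets.

## The quantum genetic algorithm

The ligand pose is a real vector — one torsion per freely rotatable bond
(single, non-ring, non-amide bonds between heavy atoms, excluding rotations
that only permute equivalent terminal atoms such as methyl or hydroxyl), a
translation of the ligand centroid, and a quaternion normalized on decode
(an all-zero quaternion decodes to the identity). Bounds: torsions [−π, π);
translation inside the carrier's xy bounding box expanded by 10 Å and
z ∈ [−8, 8] Å (expressed relative to the reference centroid); quaternion
components [−1, 1]. Each variable is quantized to `bits_per_variable`
(default 16) bits, big-endian, so decode(encode(x)) is within half a
quantization step.

Each bit is a qubit θ with amplitudes (α, β) = (cos θ, sin θ); α² + β² = 1
holds exactly in this representation, for any operator sequence. The
population starts at θ = π/4 (both outcomes equally likely). Measurement
draws u ∈ [0, 1) per qubit and yields bit 1 when u < α². We note the
operational rule and the descriptive "larger α² collapses to |0⟩" convention
found in the QGA literature disagree about polarity; the package implements
the operational rule and exposes `measurement_polarity` to flip it. The
search is polarity-symmetric at initialization, so the choice only matters
when interpreting seeded chromosomes — `seed_population()` honours the
configured polarity.

Per generation: measure → decode → score → update an external archive of the
`top_k` best (ties broken by earliest generation, then lowest chromosome
index) → rotation gate → NOT gate → crossover → stagnation checks. The
rotation gate fires per chromosome with probability `p_qrgo` (default 0.5)
and rotates each qubit by a scheduled Δθ toward a target pole; the shipped
8-row schedule leaves agreeing bits alone, rotates by 0.05π toward the best
chromosome's bit when the chromosome is worse than the best, and reinforces
its own bit by 0.01π otherwise, with the sign taken from the quadrant of
(α, β). The canonical published schedules differ in these magnitudes; ours
sits inside the usual 0.01π–0.05π range and the table is an ordinary data
frame a user can replace. The NOT gate swaps (α, β) per qubit with
probability `p_qngo` (default 0.1) — an involution with fixed point π/4.
Crossover exchanges θ segments after a uniform cut with probability
`p_crossover` (default 0.7).

Stagnation is counted on consecutive generations whose average fitness
changes by less than `convergence_threshold` (default 0.001). After
`stagnation_window` (default 50) such generations the catastrophe operator
resets every qubit to π/4 — the best chromosome survives only in the archive,
never in the population. A separate, longer `convergence_window` (default
100) on the same condition terminates the run when `check_convergence` is
on; `max_generations` always terminates. Earlier cascade layers default to
catastrophe-on/convergence-off (keep producing diverse optima), the final
layer to the reverse (stop once refined) — both switchable.

Fitness is −E_GDDS by default (`fitness_mode = "potential"`), or −E_Δ with
E_Δ = E_GDDS − E_G − E_lig. During a pose search the carrier is rigid and
ligand bond lengths/angles never change, so those bonded terms are constants;
the engine still reports totals consistent with a full evaluation, and
constants cannot change the argmax.

## Cascade and screening

`run_cascade()` runs the layers in order, passing each layer's
`migration_count` (default 10) best bit strings forward. Seeded qubits are
set so measurement reproduces the source bit with probability 1 − ε
(`seeding_bias`, default 0.05): ε = 0 is deterministic, ε = 0.5 collapses to
a fresh π/4 qubit. The small default keeps seeds faithful while leaving room
to explore. Migrated chromosomes are re-scored by the new layer's engine on
arrival rather than inheriting the cheap layer's fitness — the safer choice
when the two energy surfaces disagree. The external-command engine writes
fragments to XYZ (with the summed formal charge and multiplicity 1 — the
package targets closed-shell ground states), substitutes `{input}`/`{output}`
into a command template, parses the energy with a user regular expression and
converts units (e.g. 627.509474 kcal/mol per hartree).

`screen_library()` first filters a library: estimated logP must exceed the
threshold (default 5.0) and the ligand's longest intramolecular distance must
not exceed the carrier diameter — the diameter, not the radius, following the
original size rule even though it is geometrically permissive. The logP is a
deliberately coarse Crippen-style per-atom-type sum standing in for a full
fragment scheme, so absolute filter counts will differ from those of
commercial estimators. Each surviving ligand is docked `repeats` (default 3)
times with seeds S, S+1, S+2, and ranked by the arithmetic mean of the
best-pose binding energies, most negative first, ties broken by ligand id.
Failed ligands are flagged and kept.

## What the fixtures do and do not show

The fixture catalog (benzene, n-butane, biphenyl, methanol, a seven-ring
coronene-like patch, a one-hydroxyl GO patch) is generated from internal
templates, so every test runs offline and bit-deterministically. The docking
tests use rigid, symmetric probes over a small patch: they exercise the
search, the encoding, the energy contracts and the π-stacking geometry, but
they do not probe conformationally flexible drugs, charged ligands, solvent
effects (the internal force field has none; solvation only enters through an
external engine), or carrier relaxation — the carrier is always rigid, since
the chromosome encodes only ligand degrees of freedom. Passing tests
therefore validate the machinery, not the absolute accuracy of predicted
binding energies for real drug/GO systems.

## Problem sizes used in the checks

The automated checks run at sizes chosen to finish quickly while still
leaving the oracles meaningful: the two-variable enumeration oracle uses
8 bits per variable (65,536 genomes) against a 300-generation, population-30
search over 20 seeds; the docking oracle docks rigid benzene over the
36-atom patch with population 40 for 400 generations and compares against a
0.05 Å rigid-body z-scan; the carrier-database check builds the full
101-model ensemble on the 168-atom sheet. Production searches would use the
published layer sizes (5000 × 100, then 500 × 20), which are the package
defaults.

## Known limitations

* The force-field parameter table is minimal by design; exotic atom types
  need user-supplied parameters.
* The Powell minimizer scales poorly past a few hundred atoms.
* Fingerprint deduplication can (rarely) merge distinct models on a fold
  collision, and never splits enantiomers.
* The rotation-angle schedule is a literature-conventional reconstruction;
  users wanting a specific published schedule should supply their own table.
* No protonation/tautomer engine: ligands are docked in the form supplied.
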