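# qgadock

Quantum genetic algorithm (QGA) docking of drug-like molecules on graphene
and graphene-oxide (GO) carriers.

Graphene sheets load hydrophobic drugs by π-stacking with high capacity,
which makes graphene-based drug delivery systems (GDDS) attractive — but
predicting *where* and *how strongly* a given drug adsorbs on a given
carrier usually means expensive quantum-chemistry scans or molecular-dynamics
runs. `qgadock` is a desk-scale toolkit for that prediction problem, aimed at
computational chemists and method developers:

* **Carrier building.** Circular or rectangular honeycomb sheets (C–C 1.42 Å,
  hydrogen-terminated edges), randomly or systematically decorated with
  hydroxyl, epoxy and carboxyl groups into ensembles of GO models. Every
  emitted model must keep an aromatic π system — Hückel's 4n + 2 rule plus
  full π connectivity — and ensembles are deduplicated by a 2048-bit
  extended-connectivity fingerprint (radius 5).
* **Energy model.** A native Tripos-style molecular-mechanics force field
  (harmonic bonds/angles, periodic torsions, 6-12 Lennard-Jones, Coulomb with
  distance-dependent dielectric ε(r) = 4r), Gasteiger partial charges, and a
  Powell direction-set minimizer. External engines (xtb, ORCA, MOPAC, ...)
  plug in through a generic command template.
* **Pose search.** The ligand pose — torsions of freely rotatable bonds,
  translation, quaternion rotation — is quantized to a qubit chromosome
  (α = cos θ, β = sin θ per bit). The population evolves by measurement,
  a quantum rotation gate toward the best chromosome, a quantum NOT gate
  (mutation), single-point crossover, and a catastrophe operator that
  reinitializes a stagnant population. Fitness is −E_GDDS (total potential
  energy) or −E_Δ, where the binding energy is

      E_Δ = E_GDDS − E_G − E_lig   (kcal/mol, more negative = more stable).

* **Cascade protocol.** A cheap QGA/force-field layer with fine parameters
  (5000 generations × population 100) seeds its 10 best chromosomes into a
  coarse, accurate layer (500 × 20) — and optionally a third layer — so the
  expensive engine starts near the optimum.
* **Screening.** Batch ranking of a ligand library against one carrier:
  logP and molecular-size pre-filters, repeated cascade runs, ranking by
  average binding energy.

## Worked example

```r
library(qgadock)

# a seven-ring graphene patch and a benzene probe, typed and charged
patch   <- make_fixture("coronene_patch")
benzene <- make_fixture("benzene")

cfg <- qga_config(population_size = 40, max_generations = 400, seed = 11)
res <- run_qga(patch, benzene, cfg, ff_engine())
res$poses[[1]]$energy
#> <energy_report> E_GDDS = 36.6040 kcal/mol; E_G = 41.2300; E_lig = 3.4313; E_Delta = -8.0574
#>   terms: bond=0.151 angle=0.000 torsion=0.000 oop=0.000 vdw=3.213 elec=0.067 intermolecular=-8.057
```

Benzene binds the patch by about −8.1 kcal/mol (the `intermolecular` term
carries essentially all of it) and stacks 3.40 Å from the plane
(`mean(coords(res$poses[[1]]$ligand)[, 3])` is −3.40; above and below the
sheet are equivalent), the textbook π-stacking distance. A carrier database
is built with

```r
sheet <- build_circular_graphene(21.760)   # 168 atoms: 138 C + 30 H
gos   <- functionalize_graphene(sheet,
           functionalization_spec(3, 3, 3, "upper", "random",
                                  max_models = 20, seed = 1))
length(deduplicate_models(gos))            # 20 unique GO models
```

A thin command-line front end over the same functions ships in
`inst/cli/qgadock` (subcommands `build`, `functionalize`, `minimize`,
`dock`, `fixtures`).

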