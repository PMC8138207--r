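Package: qgadock
Title: Quantum Genetic Algorithm Docking of Drugs on Graphene and Graphene Oxide Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building graphene and graphene-oxide (GO) carrier models
    and predicting how drug-like molecules adsorb on them. Generates circular or
    rectangular graphene sheets, decorates them with hydroxyl, epoxy and
    carboxyl groups into fingerprint-deduplicated GO ensembles, and searches
    for the optimal non-covalent binding pose of a ligand with a quantum
    genetic algorithm (QGA) whose chromosomes are qubit vectors updated by
    rotation-gate, NOT-gate, crossover and catastrophe operators. Pose energies
    come from a natively implemented Tripos-style molecular-mechanics force
    field with Gasteiger charges and Powell minimization, from a mock engine,
    or from any external program driven through a command template. A
    multi-fidelity cascade protocol migrates the best chromosomes from a cheap
    search layer to seed more accurate layers, and a screening driver ranks a
    ligand library by average binding energy over repeated runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
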