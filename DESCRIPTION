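Package: quantavax
Title: Modelling Antigen Interactions for Chimeric Tick-Vaccine Design
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the computational steps of a quantum-vaccinology
    antigen design workflow against cattle ticks: significance-gated
    vaccine-efficacy statistics on tick infestation trials, residue-pair
    protein-protein interaction energies with a sigmoidal
    distance-dependent dielectric averaged over structural snapshots,
    codon-by-codon sequence sonification with cadence segmentation,
    multi-model consensus epitope calling, and GGGS-linked chimeric
    antigen assembly. Includes seeded synthetic-data generators so the
    whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
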