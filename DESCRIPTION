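Package: carbsorb
Title: Isomer-Dependent Physisorption on Carbon Surfaces and Desorption Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the preferential physisorption of cis- and trans-4-methylcyclohexane
    methanol (MCHM) on planar and amorphous carbon surfaces and the downstream
    temperature-driven desorption kinetics that explain contaminant release from
    activated-carbon filter media. Provides a molecular-geometry data model with
    XYZ/PDB input and output, synthetic generators for polycyclic aromatic
    hydrocarbon flakes, hydrogen-capped amorphous carbon slabs and MCHM chair
    conformers, a pairwise van der Waals physisorption engine with rigid-body pose
    minimization and hydrogen-capped cluster carving, an Arrhenius rate-ratio and
    Maxwell-Boltzmann high-energy-fraction kinetics model with enhancement factors
    and isomer-resolved desorption partitioning, and summary statistics for
    binding-energy ensembles and seasonal water-temperature series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
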