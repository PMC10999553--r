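Package: rhizoflux
Title: Constraint-Based Analysis of Rhizobial Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis toolkit for genome-scale metabolic
    models of nitrogen-fixing rhizobia in free-living and symbiotic
    (bacteroid) states. Reads and writes COBRA-JSON and SBML Level 3 FBC
    models, parses and evaluates gene-protein-reaction (GPR) boolean rules,
    applies in silico media, and runs the standard constraint-based
    analyses: flux balance analysis (FBA), flux variability analysis (FVA),
    model quality control (blocked reactions, duplicate metabolites,
    dead-end metabolites), single-gene and single-reaction essentiality
    screens, E-Flux integration of proteome abundance with homolog mapping
    between strains, sole-carbon-source phenotype prediction against
    Biolog-style plates, ferredoxin-module knockout reports, and a
    minimization-of-metabolic-adjustment (MOMA) overexpression scan for
    fixed-ammonia enhancement targets. Ships deterministic generators for
    small benchmark networks with brute-force-verified ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
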