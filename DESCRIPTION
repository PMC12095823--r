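Package: commscreen
Title: Dynamic Flux Balance Screening of Microbial Monocultures and
    Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates batch and fed-batch growth of microbial monocultures
    and multi-species communities that share an extracellular metabolite
    pool, using dynamic flux balance analysis with parsimonious growth
    solutions, Michaelis-Menten substrate uptake kinetics and per-step flux
    variability analysis of product secretion.  On top of the engine it
    provides a screening layer that compares the biosynthetic performance
    of candidate systems: productivity and yield metrics, productivity
    ratios against the best monoculture, six-way ecological interaction
    classification, community viability checks, cross-feeding role tables,
    and inoculum-ratio, carbon-source and uptake-kinetics sensitivity
    scans.  Genome-scale or toy metabolic models are read from SBML (Level
    3 FBC) or a BiGG-style JSON dialect; a deterministic toy-community
    generator makes every stage testable without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
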