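Package: macrep
Title: Regulatory and Metabolic Network Modelling of Macrophage Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the regulatory and metabolic programs that
    distinguish classically (M1) and alternatively (M2) activated macrophages.
    Provides maximum-weight stable-set filtering of redundant enriched gene
    sets on a Jaccard similarity graph, expression-constrained prediction of
    metabolic fluxes with iterative removal of thermodynamically infeasible
    loops, and mixed-integer-programming inference of a parsimonious
    transcription-factor model of a gene signature, including in-silico
    reprogramming of one polarization state into another. Linear and
    mixed-integer programs are solved through the bundled GLPK interface.
    Seeded synthetic-data generators emulate the expression, evidence and
    network inputs of a polarization study so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GLPK (>= 4.65)
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
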