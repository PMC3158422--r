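Package: shapequad
Title: Steric Shape Quadrupole Filters for 3-D Similarity Prescreening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gaussian shape descriptors for small-molecule conformers
    (analytic, monopole and self-overlap volumes; principal-frame steric
    quadrupole moments), shape-Tanimoto similarity with rigid-body
    superposition optimization, and volume-binned quadrupole-difference
    filters that cheaply preclude conformer pairs which cannot reach a
    shape-similarity threshold. Includes filter construction from a
    neighbor-pair corpus with fringe-fill map modification, cascaded
    filter application with confusion-matrix evaluation, a synthetic
    conformer/pair-corpus generator for end-to-end testing, and a
    command-line interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    ChemmineR,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
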